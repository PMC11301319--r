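#' Build an evenly spaced genetic map
#'
#' @param n_chr Number of chromosomes.
#' @param n_markers Markers per chromosome.
#' @param length_cM Chromosome length in centiMorgans.
#' @return A tibble with columns `chrom`, `id`, `pos_cM`, `pos_bp` (physical
#'   positions derived as `pos_cM * 1e4 + 1`, 1-based).
#' @export
genetic_map <- function(n_chr = 5, n_markers = 400, length_cM = 100) {
  stopifnot(n_chr >= 1, n_markers >= 1, length_cM > 0)
  purrr::map_dfr(seq_len(n_chr), function(ch) {
    pos <- seq(0, length_cM, length.out = n_markers)
    tibble(
      chrom = paste0("chr", ch),
      id = sprintf("m%02d_%04d", ch, seq_len(n_markers)),
      pos_cM = pos,
      pos_bp = as.integer(round(pos * 1e4)) + 1L
    )
  })
}

validate_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chrom", "id", "pos_cM") %in% names(map)))
  if (nrow(map) == 0) rlang::abort("genetic map is empty.")
  ok <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(.data$pos_cM >= 0) &&
                       (dplyr::n() == 1 || all(diff(.data$pos_cM) > 0)))
  if (!all(ok$ok)) {
    rlang::abort("map positions must be non-negative and strictly increasing within a chromosome.")
  }
  if (!"pos_bp" %in% names(map)) {
    map$pos_bp <- as.integer(round(map$pos_cM * 1e4)) + 1L
  }
  map
}

# One meiosis for every line at once on one chromosome: a gamete is a Markov
# walk over the parental haplotype pair, switching between haplotypes with the
# Haldane recombination fraction of each marker interval.
meiosis_gametes <- function(H1, H2, rec) {
  m <- nrow(H1); n <- ncol(H1)
  first <- stats::rbinom(n, 1, 0.5)
  if (m == 1) {
    I <- matrix(first, 1, n)
  } else {
    sw <- matrix(stats::rbinom((m - 1) * n, 1, rep(rec, n)), m - 1, n)
    I <- apply(rbind(first, sw), 2, cumsum) %% 2
  }
  H1 * (1 - I) + H2 * I
}

#' Simulate RIL genotypes by repeated selfing
#'
#' Starting from a uniformly heterozygous F1, each line is selfed
#' `n_generations - 1` times. Gametes are formed by a Markov walk along each
#' chromosome with Haldane recombination fractions
#' `r = (1 - exp(-2 d / 100)) / 2` for interval length `d` cM (no
#' interference). Residual heterozygotes are retained and coded 1.
#'
#' @param map Genetic map tibble (see [genetic_map()]).
#' @param n_ril Number of lines (>= 2).
#' @param n_generations Filial generation to report, e.g. 10 for an F10 panel.
#' @param seed Integer seed.
#' @param missing_rate Fraction of genotype calls set to missing (-9).
#' @return A `ril_genotypes` object: list with `G` (integer matrix
#'   RIL x marker; 0 = founder-A homozygote, 2 = founder-B homozygote,
#'   1 = residual heterozygote, -9 = missing), `map`, `ril_ids`.
#' @export
simulate_ril_genotypes <- function(map, n_ril = 100, n_generations = 10,
                                   seed = 1, missing_rate = 0) {
  map <- validate_map(map)
  stopifnot(n_ril >= 2, n_generations >= 2,
            missing_rate >= 0, missing_rate < 1)
  withr::with_seed(seed, {
    chroms <- split(seq_len(nrow(map)), map$chrom)
    chroms <- chroms[unique(map$chrom)]  # keep map order
    G <- matrix(0L, nrow(map), n_ril)
    for (idx in chroms) {
      pos <- map$pos_cM[idx]
      rec <- if (length(pos) > 1) (1 - exp(-2 * diff(pos) / 100)) / 2 else numeric(0)
      H1 <- matrix(0L, length(idx), n_ril)
      H2 <- matrix(1L, length(idx), n_ril)
      for (g in seq_len(n_generations - 1)) {
        nH1 <- meiosis_gametes(H1, H2, rec)
        nH2 <- meiosis_gametes(H1, H2, rec)
        H1 <- nH1; H2 <- nH2
      }
      G[idx, ] <- H1 + H2
    }
    G <- t(G)  # RIL x marker
    if (missing_rate > 0) {
      drop <- which(stats::runif(length(G)) < missing_rate)
      G[drop] <- -9L
    }
    storage.mode(G) <- "integer"
    ril_ids <- sprintf("RIL%03d", seq_len(n_ril))
    dimnames(G) <- list(ril_ids, map$id)
    structure(list(G = G, map = map, ril_ids = ril_ids),
              class = "ril_genotypes")
  })
}

#' @export
print.ril_genotypes <- function(x, ...) {
  cat(sprintf("<ril_genotypes> %d RILs x %d markers on %d chromosome(s)\n",
              nrow(x$G), ncol(x$G), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
tidy.ril_genotypes <- function(x, ...) {
  x$map |>
    dplyr::mutate(
      n_het = colSums(x$G == 1L),
      n_missing = colSums(x$G == -9L),
      freq_B = colMeans(replace(x$G, x$G == -9L, NA) / 2, na.rm = TRUE)
    )
}

#' Describe a planted QTL
#'
#' @param marker Marker id (character) or column index into the genotype
#'   matrix.
#' @param effects Named list keyed by treatment; each element is a named list
#'   with logistic parameter vectors `c(a, b, r)` for genotype codes `"0"` and
#'   `"2"` (and optionally `"1"`; heterozygotes default to the mid-parameter
#'   curve). Treatments not listed keep the baseline curve for all genotypes.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(marker, effects) {
  stopifnot(length(marker) == 1, is.list(effects), length(effects) >= 1)
  if (!all(names(effects) %in% TREATMENTS)) {
    rlang::abort("qtl_spec(): treatments must be among H, L, HH, HL, LH, LL.")
  }
  for (tr in names(effects)) {
    e <- effects[[tr]]
    if (!all(c("0", "2") %in% names(e))) {
      rlang::abort("qtl_spec(): each treatment needs parameter sets for genotypes \"0\" and \"2\".")
    }
    for (g in names(e)) {
      p <- e[[g]]
      if (length(p) != 3 || any(!is.finite(p)) || any(p <= 0)) {
        rlang::abort("qtl_spec(): logistic parameters (a, b, r) must be three positive numbers.")
      }
    }
  }
  structure(list(marker = marker, effects = effects), class = "qtl_spec")
}

#' Default treatment baseline growth parameters
#'
#' Logistic baselines for the six treatments, chosen so that the asymptotic
#' plasticity contrasts reproduce the qualitative pattern of the reciprocal
#' design: parental plasticity of about +7 leaves (L - H), offspring
#' plasticity of about +4 (maternal L) and +2 (maternal H), positive
#' transgenerational plasticity that is stronger under the maternal
#' high-light environment, and maternal plasticity larger in the high-light
#' offspring environment.
#'
#' @return A tibble `treatment`, `a`, `b`, `r`.
#' @export
default_baselines <- function() {
  tibble::tribble(
    ~treatment, ~a,   ~b, ~r,
    "H",  28.0, 20, 0.62,
    "L",  35.0, 22, 0.55,
    "HH", 34.0, 20, 0.65,
    "HL", 36.0, 21, 0.58,
    "LH", 32.5, 21, 0.60,
    "LL", 36.5, 22, 0.56
  )
}

#' Default residual-noise parameters
#'
#' First-order structured-antedependence (SAD(1)) residual parameters per
#' treatment: antedependence coefficient `phi` and innovation variance `nu2`
#' (leaves^2) of an individual plant's trajectory.
#'
#' @return A tibble `treatment`, `phi`, `nu2`.
#' @export
default_noise <- function() {
  tibble(
    treatment = TREATMENTS,
    phi = ifelse(TREATMENTS %in% c("H", "HH", "LH"), 0.78, 0.82),
    nu2 = ifelse(TREATMENTS %in% c("H", "HH", "LH"), 2.5, 3.0)
  )
}

#' Default planted QTLs for the desk-scale fixture
#'
#' Three plasticity QTLs: one altering the low-light parental response (a
#' pWPP QTL), one altering the offspring maternal-H response (an oWPP_H QTL),
#' and one altering both low-light treatments (pWPP and oWPP_L).
#'
#' @param genotypes A `ril_genotypes` object (markers are picked near the
#'   middles of chromosomes 1-3).
#' @return List of [qtl_spec()] objects.
#' @export
default_qtls <- function(genotypes) {
  map <- genotypes$map
  picks <- unique(pmax(1L, ceiling(c(0.25, 0.5, 0.75) * nrow(map))))
  ids <- map$id[picks]
  base <- default_baselines()
  p <- function(tr) {
    b <- base[base$treatment == tr, ]
    c(b$a, b$b, b$r)
  }
  shift <- function(x, da) c(x[1] + da, x[2], x[3])
  specs <- list(
    list(L = list("0" = shift(p("L"), +4), "2" = shift(p("L"), -4))),
    list(HL = list("0" = shift(p("HL"), +3.5), "2" = shift(p("HL"), -3.5))),
    list(L  = list("0" = shift(p("L"), +3),  "2" = shift(p("L"), -3)),
         LL = list("0" = shift(p("LL"), +3), "2" = shift(p("LL"), -3)))
  )
  purrr::map2(ids, specs[seq_along(ids)], qtl_spec)
}

resolve_marker <- function(marker, map) {
  if (is.character(marker)) {
    j <- match(marker, map$id)
    if (is.na(j)) rlang::abort(sprintf("unknown QTL marker id '%s'.", marker))
  } else {
    j <- as.integer(marker)
    if (is.na(j) || j < 1 || j > nrow(map)) {
      rlang::abort("QTL marker index out of range.")
    }
  }
  j
}

# SAD(1) residual trajectories: e_1 = eps_1, e_t = phi * e_{t-1} + eps_t with
# iid N(0, nu2) innovations; rows are independent replicates.
rsad1 <- function(n, T, phi, nu2) {
  E <- matrix(stats::rnorm(n * T, sd = sqrt(nu2)), n, T)
  if (T > 1) for (t in 2:T) E[, t] <- phi * E[, t - 1] + E[, t]
  E
}

#' Simulate six-treatment growth trajectories with planted plasticity QTLs
#'
#' Each replicate trajectory is a logistic mean plus SAD(1)-correlated
#' multivariate normal noise. The mean is the treatment baseline curve plus
#' the summed deviations of every planted QTL whose spec covers that
#' treatment (for a single QTL this reduces to replacing the baseline with
#' the genotype-specific curve). Maternal effects are encoded by the
#' treatment-specific baselines. Missing genotypes at a QTL fall back to the
#' baseline curve.
#'
#' @param genotypes A `ril_genotypes` object.
#' @param qtls List of [qtl_spec()] objects (may be empty).
#' @param baselines Tibble `treatment`, `a`, `b`, `r` (default
#'   [default_baselines()]).
#' @param noise Tibble `treatment`, `phi`, `nu2`; `nu2 = 0` gives noiseless
#'   trajectories.
#' @param weeks Integer measurement weeks (default 1:8).
#' @param n_replicates Replicates per RIL per treatment (default 20).
#' @param treatments Treatments to generate (default: all with a baseline).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Long tibble `ril_id`, `treatment`, `replicate`, `week`,
#'   `leaf_number`.
#' @export
simulate_trajectories <- function(genotypes, qtls = list(),
                                  baselines = default_baselines(),
                                  noise = default_noise(),
                                  weeks = 1:8, n_replicates = 20,
                                  treatments = baselines$treatment,
                                  seed = 1) {
  stopifnot(inherits(genotypes, "ril_genotypes"),
            length(weeks) >= 3, n_replicates >= 1)
  treatments <- match.arg(treatments, TREATMENTS, several.ok = TRUE)
  G <- genotypes$G
  n <- nrow(G)
  T <- length(weeks)
  qtl_idx <- vapply(qtls, function(q) resolve_marker(q$marker, genotypes$map), 1L)

  curve_of <- function(p, tt) p[1] / (1 + p[2] * exp(-p[3] * tt))

  withr::with_seed(seed, {
    out <- vector("list", length(treatments))
    for (k in seq_along(treatments)) {
      tr <- treatments[k]
      b <- baselines[baselines$treatment == tr, ]
      if (nrow(b) != 1) rlang::abort(sprintf("no baseline for treatment %s.", tr))
      base_curve <- curve_of(c(b$a, b$b, b$r), weeks)
      M <- matrix(base_curve, n, T, byrow = TRUE)
      for (qi in seq_along(qtls)) {
        eff <- qtls[[qi]]$effects[[tr]]
        if (is.null(eff)) next
        g <- G[, qtl_idx[qi]]
        c0 <- curve_of(eff[["0"]], weeks)
        c2 <- curve_of(eff[["2"]], weeks)
        c1 <- if (!is.null(eff[["1"]])) curve_of(eff[["1"]], weeks) else (c0 + c2) / 2
        for (code in 0:2) {
          rows <- which(g == code)
          if (length(rows) == 0) next
          cc <- switch(code + 1L, c0, c1, c2)
          M[rows, ] <- M[rows, , drop = FALSE] +
            matrix(cc - base_curve, length(rows), T, byrow = TRUE)
        }
      }
      nz <- noise[noise$treatment == tr, ]
      if (nrow(nz) != 1) rlang::abort(sprintf("no noise spec for treatment %s.", tr))
      stopifnot(abs(nz$phi) < 1, nz$nu2 >= 0)
      nrep_rows <- n * n_replicates
      E <- if (nz$nu2 > 0) rsad1(nrep_rows, T, nz$phi, nz$nu2) else matrix(0, nrep_rows, T)
      # rows ordered (ril1 rep1, ril1 rep2, ..., ril_n rep_R)
      Y <- M[rep(seq_len(n), each = n_replicates), , drop = FALSE] + E
      out[[k]] <- tibble(
        ril_id = rep(genotypes$ril_ids, each = n_replicates * T),
        treatment = tr,
        replicate = rep(rep(seq_len(n_replicates), each = T), times = n),
        week = rep(weeks, times = nrep_rows),
        leaf_number = as.vector(t(Y))
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Write a simulated dataset as plain-text fixture files
#'
#' Emits `genotypes.vcf` (VCF v4.2, GT-only), `phenotypes.csv` (long format)
#' and `truth.yml` (the planted-QTL record) into `dir`.
#'
#' @param genotypes A `ril_genotypes` object.
#' @param phenotypes Long tibble from [simulate_trajectories()].
#' @param dir Output directory (created if needed).
#' @param qtls List of planted [qtl_spec()]s recorded in the truth file.
#' @param baselines,noise Generator settings recorded in the truth file.
#' @return Invisibly, a named list of the three file paths.
#' @export
write_fixture <- function(genotypes, phenotypes, dir, qtls = list(),
                          baselines = NULL, noise = NULL) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create directory '%s'.", dir))
  }
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    csv = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth.yml")
  )
  write_ril_vcf(genotypes, paths$vcf)
  readr::write_csv(phenotypes, paths$csv)
  truth <- list(
    n_ril = nrow(genotypes$G),
    n_marker = ncol(genotypes$G),
    qtls = lapply(qtls, function(q) {
      list(marker = as.character(q$marker),
           effects = lapply(q$effects, function(e) lapply(e, as.numeric)))
    }),
    baselines = if (!is.null(baselines)) as.list(baselines) else NULL,
    noise = if (!is.null(noise)) as.list(noise) else NULL
  )
  yaml::write_yaml(truth, paths$truth)
  invisible(paths)
}

#' Write RIL genotypes as a VCF v4.2 file
#'
#' Homozygotes are written `0/0` and `1/1`, residual heterozygotes `0/1`,
#' missing calls `./.`.
#'
#' @param genotypes A `ril_genotypes` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ril_vcf <- function(genotypes, path) {
  map <- genotypes$map
  G <- genotypes$G
  gt <- matrix("./.", ncol(G), nrow(G))
  codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  tG <- t(G)
  for (code in names(codes)) gt[tG == as.integer(code)] <- codes[[code]]
  contigs <- unique(map$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=plastmap",
    sprintf("##contig=<ID=%s>", contigs),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$ril_ids), collapse = "\t")
  )
  body <- paste(map$chrom, map$pos_bp, map$id, "A", "T", ".", "PASS", ".",
                "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
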