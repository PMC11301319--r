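#' Read RIL genotypes from a VCF file
#'
#' GT calls are recoded `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`,
#' `./. -> -9`. Multi-allelic records are skipped (their count is attached as
#' attribute `n_skipped` and reported). Positions are 1-based as in the VCF;
#' map distances are recovered as `(pos_bp - 1) / 1e4` cM, the inverse of the
#' fixture writer's convention.
#'
#' @param path Path to a VCF (v4.x) file with a GT field.
#' @return A `ril_genotypes` object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) || nrow(v@gt) == 0) {
    rlang::abort("VCF has no genotype (GT) data.")
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, TRUE))) {
    rlang::abort("VCF records lack the GT format field.")
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  n_skipped <- sum(multi)
  if (n_skipped > 0) {
    rlang::inform(sprintf("skipped %d multi-allelic record(s).", n_skipped))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  recode <- function(x) {
    out <- rep(-9L, length(x))
    x <- gsub("|", "/", x, fixed = TRUE)
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    out
  }
  G <- matrix(recode(gt), nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  G <- t(G)  # RIL x marker
  storage.mode(G) <- "integer"
  pos_bp <- as.integer(fix$POS[keep])
  map <- tibble(
    chrom = fix$CHROM[keep],
    id = ifelse(is.na(fix$ID[keep]) | fix$ID[keep] == ".",
                paste0(fix$CHROM[keep], "_", pos_bp), fix$ID[keep]),
    pos_cM = (pos_bp - 1) / 1e4,
    pos_bp = pos_bp
  )
  colnames(G) <- map$id
  out <- structure(list(G = G, map = map, ril_ids = rownames(G)),
                   class = "ril_genotypes")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a long-format phenotype table
#'
#' @param path CSV with columns `ril_id`, `treatment`, `replicate`, `week`,
#'   `leaf_number`.
#' @param weeks Optional grid; rows outside it are rejected.
#' @return Validated long tibble.
#' @export
read_phenotypes <- function(path, weeks = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) rlang::abort("phenotype file is empty.")
  req <- c("ril_id", "treatment", "replicate", "week", "leaf_number")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste("phenotype file lacks columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(raw$treatment), TREATMENTS)
  if (length(bad)) {
    rlang::abort(paste("unknown treatment label(s):",
                       paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(raw[, c("ril_id", "treatment", "replicate", "week")])) {
    rlang::abort("duplicated (ril_id, treatment, replicate, week) rows.")
  }
  if (!is.null(weeks) && !all(raw$week %in% weeks)) {
    rlang::abort("phenotype table contains weeks outside the configured grid.")
  }
  raw
}

default_config <- function() {
  list(
    out_dir = "plastmap_out",
    seed = 1,
    weeks = 1:8,
    contrasts = plasticity_contrasts()$contrast,
    simulate = list(
      n_ril = 100, n_chr = 5, n_markers = 400, chr_length_cM = 100,
      n_generations = 10, n_replicates = 20, use_default_qtls = TRUE
    ),
    input = NULL,  # list(vcf =, phenotypes =) to use files instead
    scan = list(alpha = 0.05, n_perm = 100, n_min = 5),
    cluster = list(L_range = 1:6, order = 4, n_starts = 10, min_snps = 5)
  )
}

#' Validate a pipeline configuration
#'
#' @param config A list (or path to a YAML file) with any of the fields of
#'   `default_config()`; missing fields take defaults.
#' @return The completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  bad <- setdiff(cfg$contrasts, plasticity_contrasts()$contrast)
  if (length(bad)) {
    rlang::abort(paste("config: unknown contrast(s):",
                       paste(bad, collapse = ", ")))
  }
  stopifnot(cfg$scan$alpha > 0, cfg$scan$alpha < 1)
  if (cfg$scan$n_perm > 0) check_perm_settings(cfg$scan$n_perm, cfg$scan$alpha)
  cfg
}

# stage seeds derived from the master seed by fixed offsets
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, scan = 211L, cluster = 307L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full plasticity-mapping pipeline
#'
#' Simulates (or loads) genotypes and six-treatment trajectories, averages
#' replicates, fits treatment mean curves, builds the configured plasticity
#' contrasts, scans each for QTLs with a permutation-calibrated threshold,
#' and clusters each significant QTL set into modules. All outputs are
#' written as TSV/JSON under `config$out_dir`; reruns with the same
#' configuration are byte-identical.
#'
#' @param config See [validate_config()].
#' @return Invisibly, a list with `panels`, `mean_curves`, `scans`,
#'   `modules`, `log`, `paths`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  note <- function(stage, unit_type, unit_id, reason) {
    log_rows[[length(log_rows) + 1]] <<-
      tibble(stage = stage, unit_type = unit_type,
             unit_id = unit_id, reason = reason)
  }

  # ---- inputs ----
  truth_qtls <- list()
  if (!is.null(cfg$input)) {
    geno <- read_genotypes(cfg$input$vcf)
    raw <- read_phenotypes(cfg$input$phenotypes, weeks = cfg$weeks)
  } else {
    sim_seed <- stage_seed(cfg$seed, "simulate")
    map <- genetic_map(cfg$simulate$n_chr, cfg$simulate$n_markers,
                       cfg$simulate$chr_length_cM)
    geno <- simulate_ril_genotypes(map, cfg$simulate$n_ril,
                                   cfg$simulate$n_generations,
                                   seed = sim_seed)
    truth_qtls <- if (isTRUE(cfg$simulate$use_default_qtls)) {
      default_qtls(geno)
    } else {
      list()
    }
    raw <- simulate_trajectories(geno, truth_qtls,
                                 weeks = cfg$weeks,
                                 n_replicates = cfg$simulate$n_replicates,
                                 seed = sim_seed + 1)
  }

  # ---- panels, mean curves, contrast summaries ----
  panels <- average_replicates(raw, weeks = cfg$weeks)
  dropped <- setdiff(unique(raw$ril_id), unique(panels$ril_id))
  for (r in dropped) note("average_replicates", "ril", r, "no_complete_panel")
  mean_curves <- fit_treatment_mean_curves(panels)
  contrast_tests <- test_contrasts(panels, intersect(
    cfg$contrasts, plasticity_contrasts()$contrast))

  # ---- per-contrast scan + clustering ----
  scan_seed <- stage_seed(cfg$seed, "scan")
  cluster_seed <- stage_seed(cfg$seed, "cluster")
  scans <- list()
  modules <- list()
  for (k in seq_along(cfg$contrasts)) {
    cn <- cfg$contrasts[k]
    trait <- compute_plasticity(panels, cn)
    sc <- cofunmap_scan(trait, geno,
                        n_perm = cfg$scan$n_perm, alpha = cfg$scan$alpha,
                        n_min = cfg$scan$n_min, seed = scan_seed + k)
    scans[[cn]] <- sc
    skipped <- dplyr::filter(as_tibble(sc), .data$skip_reason != "")
    for (i in seq_len(nrow(skipped))) {
      note("scan", "snp", paste0(cn, ":", skipped$marker[i]),
           skipped$skip_reason[i])
    }
    g <- gsd_curves(sc, significant_only = TRUE)
    n_sig <- length(unique(g$marker))
    if (n_sig >= cfg$cluster$min_snps) {
      modules[[cn]] <- select_modules(
        g, L_range = cfg$cluster$L_range, order = cfg$cluster$order,
        seed = cluster_seed + k, n_starts = cfg$cluster$n_starts)
    } else {
      note("cluster", "contrast", cn,
           sprintf("too_few_significant_snps:%d", n_sig))
    }
  }

  # ---- outputs ----
  paths <- list()
  wtsv <- function(d, name) {
    p <- file.path(cfg$out_dir, name)
    readr::write_tsv(d, p)
    paths[[name]] <<- p
  }
  wtsv(mean_curves, "mean_curves.tsv")
  wtsv(contrast_tests$contrasts, "contrast_tests.tsv")
  wtsv(contrast_tests$pairwise, "contrast_pairwise.tsv")
  for (cn in names(scans)) {
    wtsv(tidy(scans[[cn]]), paste0("scan_", cn, ".tsv"))
    wtsv(manhattan_export(scans[[cn]]), paste0("manhattan_", cn, ".tsv"))
  }
  for (cn in names(modules)) {
    wtsv(tidy(modules[[cn]]$best), paste0("modules_", cn, ".tsv"))
    wtsv(modules[[cn]]$table, paste0("bic_", cn, ".tsv"))
  }
  log_tbl <- if (length(log_rows)) dplyr::bind_rows(log_rows) else
    tibble(stage = character(), unit_type = character(),
           unit_id = character(), reason = character())
  wtsv(log_tbl, "exclusions.tsv")

  meta <- list(
    package = "plastmap",
    version = as.character(utils::packageVersion("plastmap")),
    seed = cfg$seed,
    weeks = cfg$weeks,
    contrasts = cfg$contrasts,
    scan = cfg$scan,
    cluster = cfg$cluster[c("L_range", "order", "n_starts", "min_snps")],
    thresholds = lapply(scans, function(s) attr(s, "threshold")),
    n_significant = lapply(scans, function(s)
      sum(s$significant, na.rm = TRUE)),
    best_L = lapply(modules, function(m) m$best_L),
    planted_qtls = vapply(truth_qtls, function(q) as.character(q$marker), "")
  )
  meta_path <- file.path(cfg$out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["run_metadata.json"]] <- meta_path

  invisible(list(genotypes = geno, panels = panels,
                 mean_curves = mean_curves,
                 contrast_tests = contrast_tests, scans = scans,
                 modules = modules, log = log_tbl, paths = paths,
                 config = cfg, truth_qtls = truth_qtls))
}
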