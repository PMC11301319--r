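# shared fixture builders (everything generated in code at test time)

# two-environment (H, L) simulated panel set with optional planted QTLs
sim_two_env <- function(n_ril, seed, qtls = list(), n_chr = 5,
                        n_markers = 40, n_replicates = 20,
                        treatments = c("H", "L")) {
  map <- genetic_map(n_chr, n_markers, 100)
  geno <- simulate_ril_genotypes(map, n_ril = n_ril, seed = seed)
  raw <- simulate_trajectories(geno, qtls, n_replicates = n_replicates,
                               seed = seed + 1, treatments = treatments)
  list(geno = geno, raw = raw, panels = average_replicates(raw))
}

# QTL shifting the asymptote by +/- gap/2 around the baseline of a treatment
plant_gap_qtl <- function(geno, marker_idx, gap, treatment = "L") {
  base <- default_baselines()
  b <- unlist(base[base$treatment == treatment, c("a", "b", "r")])
  eff <- list(list("0" = c(b[[1]] + gap / 2, b[[2]], b[[3]]),
                   "2" = c(b[[1]] - gap / 2, b[[2]], b[[3]])))
  names(eff) <- treatment
  qtl_spec(geno$map$id[marker_idx], eff)
}

# long phenotype table built from exact per-RIL trajectories (one replicate)
raw_from_curves <- function(curves, treatment, weeks = seq_len(ncol(curves))) {
  n <- nrow(curves)
  tibble::tibble(
    ril_id = rep(sprintf("RIL%03d", seq_len(n)), each = length(weeks)),
    treatment = treatment,
    replicate = 1L,
    week = rep(weeks, times = n),
    leaf_number = as.vector(t(curves))
  )
}

# noiseless six-treatment panels from per-RIL random offsets around the
# treatment baselines (offsets shared across treatments per RIL)
six_panels_exact <- function(n_ril = 12, weeks = 1:8, seed = 7) {
  base <- default_baselines()
  withr::with_seed(seed, {
    off <- stats::rnorm(n_ril, 0, 1.5)
    raws <- lapply(base$treatment, function(tr) {
      b <- base[base$treatment == tr, ]
      mu <- logistic_mean(weeks, b$a, b$b, b$r)
      curves <- outer(off, rep(1, length(weeks))) +
        matrix(mu, n_ril, length(weeks), byrow = TRUE)
      raw_from_curves(curves, tr, weeks)
    })
    average_replicates(dplyr::bind_rows(raws))
  })
}

# RIL x week leaf numbers of one treatment panel
panel_mat_of <- function(panels, treatment) {
  d <- panels[panels$treatment == treatment, ]
  w <- tidyr::pivot_wider(tibble::as_tibble(d), id_cols = "ril_id",
                          names_from = "week", values_from = "leaf_number")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$ril_id
  m
}

# RIL x week trait values as a named matrix
as_trait_matrix <- function(trait) {
  w <- tidyr::pivot_wider(tibble::as_tibble(trait), id_cols = "ril_id",
                          names_from = "week", values_from = "value")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$ril_id
  m
}

# multivariate normal log-likelihood oracle (independent of the C++ path)
mvn_loglik <- function(Z, mu, Sigma) {
  R <- chol(Sigma)
  E <- sweep(Z, 2, mu)
  v <- backsolve(R, t(E), transpose = TRUE)
  sum(-0.5 * (ncol(Z) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(v^2)))
}

# GSD curves drawn from L well-separated module mean curves + SAD(1) noise
sim_gsd_families <- function(S = 60, L = 3, weeks = 1:8, sep = 3,
                             phi = 0.4, nu2 = 0.09, seed = 1) {
  withr::with_seed(seed, {
    truth <- rep_len(seq_len(L), S)
    shapes <- vapply(seq_len(L), function(l) {
      sep * l + 0.5 * sin(weeks / 2 + l)
    }, numeric(length(weeks)))
    E <- matrix(stats::rnorm(S * length(weeks), sd = sqrt(nu2)), S)
    for (t in 2:length(weeks)) E[, t] <- phi * E[, t - 1] + E[, t]
    G <- t(shapes)[truth, ] + E
    rownames(G) <- sprintf("snp%02d", seq_len(S))
    colnames(G) <- weeks
    list(G = G, truth = truth)
  })
}
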