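test_that("SAD(1) closed-form inverse and determinant match generic numerics", {
  withr::with_seed(31, {
    for (i in 1:20) {
      phi <- runif(1, -0.95, 0.95)
      nu2 <- runif(1, 0.1, 5)
      T <- sample(2:10, 1)
      S <- sad1_covariance(phi, nu2, T)
      expect_lt(max(abs(sad1_inverse(phi, nu2, T) %*% S - diag(T))), 1e-8)
      expect_equal(det(S), sad1_determinant(phi, nu2, T),
                   tolerance = 1e-10)
      expect_identical(S, t(S))
      expect_silent(chol(S))  # SPD
    }
  })
  expect_equal(sad1_covariance(0, 2, 3), 2 * diag(3))
  expect_error(sad1_covariance(1, 1, 4), "phi")
  expect_error(sad1_covariance(0.5, -1, 4), "nu2")
})

test_that("composite covariance is the commuting sum of the two environments", {
  expect_equal(unclass(composite_covariance(c(0, 1.5), c(0, 2.5), 4)),
               4 * diag(4), ignore_attr = TRUE)
  A <- composite_covariance(c(0.6, 1), c(-0.3, 2), 6)
  B <- composite_covariance(c(-0.3, 2), c(0.6, 1), 6)
  expect_equal(unclass(A), unclass(B), ignore_attr = TRUE)
  # vanishing second summand recovers a single SAD(1) matrix
  C <- composite_covariance(c(0.5, 1.2), c(0.2, 1e-10), 5)
  expect_equal(unclass(C), sad1_covariance(0.5, 1.2, 5),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("lr_statistic follows its definition and clips optimizer noise", {
  expect_equal(lr_statistic(-10, -10), 0)
  expect_equal(lr_statistic(-10, -7), 6)
  expect_warning(out <- lr_statistic(-7, -7.1), "negative LR")
  expect_equal(out, 0)
})

test_that("null fit recovers a known generating difference curve", {
  # paired environment panels whose difference follows the likelihood model
  # exactly: component logistic means plus SAD(1) noise per environment
  n <- 80
  tt <- 1:8
  mu_x <- logistic_mean(tt, 30, 20, 0.6)
  mu_y <- logistic_mean(tt, 24, 18, 0.65)
  withr::with_seed(41, {
    Ex <- matrix(rnorm(n * 8), n) %*% chol(sad1_covariance(0.6, 0.15, 8))
    Ey <- matrix(rnorm(n * 8), n) %*% chol(sad1_covariance(0.5, 0.1, 8))
  })
  X <- matrix(mu_x, n, 8, byrow = TRUE) + Ex
  Y <- matrix(mu_y, n, 8, byrow = TRUE) + Ey
  raw <- dplyr::bind_rows(raw_from_curves(X, "L", tt),
                          raw_from_curves(Y, "H", tt))
  trait <- compute_plasticity(average_replicates(raw), "pWPP")
  f0 <- fit_null(trait)
  # fitted mean curve close to the generating difference curve
  mu <- mu_x - mu_y
  mu_hat <- fitted_mean_curves(f0)
  expect_lt(max(abs(mu_hat$mean_plasticity - mu)), 0.25)
  # fitted logL at least the truth-evaluated likelihood (optimality)
  Sig <- composite_covariance(c(0.6, 0.15), c(0.5, 0.1), 8)
  ll_truth <- mvn_loglik(X - Y, mu, unclass(Sig))
  expect_gte(f0$logL0, ll_truth - 1e-6)
  # the fit dominates arbitrary hand-supplied parameter points too
  ll_hand <- mvn_loglik(X - Y, mu * 0.9,
                        unclass(composite_covariance(c(0.5, 0.2),
                                                     c(0.4, 0.12), 8)))
  expect_gte(f0$logL0, ll_hand)
})

test_that("duplicating every RIL exactly doubles the null log-likelihood", {
  withr::with_seed(43, {
    Z <- matrix(rnorm(20 * 8, 5), 20)
  })
  mk <- function(M) {
    tr <- tibble::tibble(
      ril_id = rep(sprintf("R%03d", seq_len(nrow(M))), each = 8),
      week = rep(1:8, nrow(M)),
      value = as.vector(t(M))
    )
    attr(tr, "weeks") <- 1:8
    tr
  }
  f1 <- fit_null(mk(Z))
  f2 <- fit_null(mk(rbind(Z, Z)))
  expect_equal(f2$logL0, 2 * f1$logL0, tolerance = 1e-8)
})

test_that("alternative fit collapses to the null with one genotype class", {
  s <- sim_two_env(20, seed = 51, n_chr = 1, n_markers = 6, n_replicates = 3)
  tr <- compute_plasticity(s$panels, "pWPP")
  g <- stats::setNames(rep(0L, 20), rownames(as_trait_matrix(tr)))
  f <- fit_alternative(tr, g)
  expect_equal(f$logL1, f$logL0)
  expect_equal(lr_statistic(f$logL0, f$logL1), 0)
})

test_that("log-likelihood is invariant under joint RIL reordering", {
  s <- sim_two_env(24, seed = 53, n_chr = 1, n_markers = 6, n_replicates = 3)
  tr <- compute_plasticity(s$panels, "pWPP")
  Z <- as_trait_matrix(tr)
  g <- stats::setNames(s$geno$G[rownames(Z), 3], rownames(Z))
  f <- fit_alternative(tr, g)
  # reorder the trait rows; named genotypes realign automatically
  perm <- rev(seq_len(nrow(Z)))
  tr2 <- tibble::tibble(
    ril_id = rep(rownames(Z)[perm], each = ncol(Z)),
    week = rep(as.numeric(colnames(Z)), nrow(Z)),
    value = as.vector(t(Z[perm, ]))
  )
  attr(tr2, "weeks") <- as.numeric(colnames(Z))
  attr(tr2, "mean_x") <- attr(tr, "mean_x")
  attr(tr2, "mean_y") <- attr(tr, "mean_y")
  f2 <- fit_alternative(tr2, g)
  expect_equal(f2$logL1, f$logL1)
  expect_equal(f2$logL0, f$logL0)
})

test_that("small classes are dropped and empty groupings rejected", {
  s <- sim_two_env(20, seed = 55, n_chr = 1, n_markers = 6, n_replicates = 3)
  tr <- compute_plasticity(s$panels, "pWPP")
  rils <- rownames(as_trait_matrix(tr))
  g <- stats::setNames(c(rep(0L, 17), rep(2L, 3)), rils)
  f <- fit_alternative(tr, g, n_min = 5)   # class 2 dropped
  expect_equal(f$J, 1)
  expect_equal(f$n_used, 17)
  g_all_small <- stats::setNames(rep(c(0L, 1L, 2L), length.out = 20), rils)
  expect_warning(out <- fit_alternative(tr, g_all_small, n_min = 10),
                 "skipped")
  expect_null(out)
})

test_that("permutation settings are validated", {
  s <- sim_two_env(12, seed = 57, n_chr = 1, n_markers = 4, n_replicates = 2)
  tr <- compute_plasticity(s$panels, "pWPP")
  expect_error(permutation_threshold(tr, s$geno, n_perm = 10), "at least 20")
  expect_error(permutation_threshold(tr, s$geno, n_perm = 20, alpha = 0.01),
               "too small")
})

test_that("threshold quantiles are monotone in alpha", {
  withr::with_seed(61, maxima <- rexp(100, 0.2))
  thr05 <- unname(quantile(maxima, 0.95, type = 1))
  thr01 <- unname(quantile(maxima, 0.99, type = 1))
  expect_gte(thr01, thr05)
  # degenerate maxima: threshold equals the common value
  expect_equal(unname(quantile(rep(3.3, 50), 0.95, type = 1)), 3.3)
})

test_that("scan is deterministic, duplicates agree, and planted QTLs dominate", {
  map <- genetic_map(2, 15, 100)
  geno <- simulate_ril_genotypes(map, n_ril = 50, seed = 63)
  qtl <- plant_gap_qtl(geno, 8, gap = 8)
  raw <- simulate_trajectories(geno, list(qtl), n_replicates = 10, seed = 64,
                               treatments = c("H", "L"))
  tr <- compute_plasticity(average_replicates(raw), "pWPP")
  # duplicate the planted SNP as an extra marker
  geno2 <- geno
  geno2$G <- cbind(geno$G, dup = geno$G[, 8])
  geno2$map <- dplyr::bind_rows(
    geno$map, dplyr::mutate(geno$map[8, ], id = "dup"))
  colnames(geno2$G)[ncol(geno2$G)] <- "dup"
  sc1 <- cofunmap_scan(tr, geno2, n_perm = 20, alpha = 0.05, seed = 65)
  sc2 <- cofunmap_scan(tr, geno2, n_perm = 20, alpha = 0.05, seed = 65)
  expect_identical(tidy(sc1), tidy(sc2))             # determinism
  expect_equal(sc1$lr[sc1$marker == "dup"],
               sc1$lr[8])                            # duplicated column
  expect_equal(which.max(sc1$lr[1:30]), 8)           # planted SNP dominates
  # null-simulated SNPs sit stochastically below the planted QTL's LR
  expect_gt(sc1$lr[8], quantile(sc1$lr[-c(8, 31)], 0.95, na.rm = TRUE))
  # empirical P consistent with the threshold rule
  sig <- !is.na(sc1$lr) & sc1$lr >= attr(sc1, "threshold")
  expect_equal(sc1$significant, sig)
})

test_that("disjoint RIL sets are rejected", {
  s <- sim_two_env(12, seed = 67, n_chr = 1, n_markers = 4, n_replicates = 2)
  tr <- compute_plasticity(s$panels, "pWPP")
  geno_other <- s$geno
  geno_other$ril_ids <- paste0("X", geno_other$ril_ids)
  rownames(geno_other$G) <- geno_other$ril_ids
  expect_error(cofunmap_scan(tr, geno_other, n_perm = 0),
               "empty intersection")
})
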