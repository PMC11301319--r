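# bare genotype-model stub whose difference curves are (numerically) flat
flat_model <- function(levels, n_j) {
  th <- cbind(a_x = levels + 10, b_x = 1e-9, r_x = 1,
              a_y = 10, b_y = 1e-9, r_y = 1)
  list(theta = th, n_j = n_j)
}

test_that("GSD curves follow the weighted-variance formula", {
  # two balanced classes with flat means 4 and 2: g = |4 - 2| / 2 = 1
  g <- gsd_curve(flat_model(c(4, 2), c(10, 10)), weeks = 1:8)
  expect_equal(g$gsd, rep(1, 8), tolerance = 1e-6)
  # weights 3:1 with means 0 and 4: weighted variance 3, g = sqrt(3)
  g2 <- gsd_curve(flat_model(c(0, 4), c(3, 1)), weeks = 1:8)
  expect_equal(g2$gsd, rep(sqrt(3), 8), tolerance = 1e-6)
  # single class: identically zero with a warning
  expect_warning(g3 <- gsd_curve(flat_model(5, 20), weeks = 1:8), "zero")
  expect_equal(g3$gsd, rep(0, 8))
})

test_that("GSD is invariant to genotype class relabelling", {
  m <- flat_model(c(1, 5, 3), c(4, 7, 9))
  m_rev <- list(theta = m$theta[3:1, ], n_j = m$n_j[3:1])
  expect_equal(gsd_curve(m, weeks = 1:6)$gsd,
               gsd_curve(m_rev, weeks = 1:6)$gsd)
})

test_that("single-component fit degenerates to a pooled GLS curve", {
  fam <- sim_gsd_families(S = 20, L = 1, sep = 2, seed = 3)
  sol <- em_fit(fam$G, L = 1, order = 3, seed = 1)
  expect_true(all(sol$resp == 1))
  # oracle: GLS of the pooled mean onto the Legendre basis with fitted Sigma
  B <- plastmap:::legendre_basis(1:8, 3)
  Q <- sad1_inverse(sol$phi, sol$nu2, 8)
  beta <- solve(crossprod(B, Q %*% B), crossprod(B, Q %*% colMeans(fam$G)))
  expect_equal(unname(sol$coef[, 1]), unname(as.vector(beta)),
               tolerance = 1e-6)
})

test_that("EM log-likelihood is monotone and beats the truth evaluation", {
  fam <- sim_gsd_families(S = 45, L = 3, sep = 3, seed = 5)
  sol <- em_fit(fam$G, L = 3, seed = 2, n_starts = 4)
  expect_true(all(diff(sol$logl_trace) >= -1e-7))
  # mixture log-likelihood at the generating parameters
  Sig <- sad1_covariance(0.4, 0.09, 8)
  shapes <- vapply(1:3, function(l) 3 * l + 0.5 * sin((1:8) / 2 + l),
                   numeric(8))
  ll_truth <- sum(log(rowSums(vapply(1:3, function(l) {
    E <- sweep(fam$G, 2, shapes[, l])
    R <- chol(Sig)
    v <- backsolve(R, t(E), transpose = TRUE)
    exp(-0.5 * (8 * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(v^2))) / 3
  }, numeric(45)))))
  expect_gte(sol$logL, ll_truth - 1e-6)
})

test_that("well-separated curve families are recovered with high ARI", {
  skip_if_not_installed("mclust")
  fam <- sim_gsd_families(S = 60, L = 3, sep = 3, seed = 8)
  sol <- em_fit(fam$G, L = 3, seed = 4, n_starts = 5)
  ari <- mclust::adjustedRandIndex(sol$assignment, fam$truth)
  expect_gte(ari, 0.9)
  # responsibilities are a proper soft partition
  expect_equal(rowSums(sol$resp), rep(1, 60), tolerance = 1e-10)
  expect_equal(sum(sol$pi), 1, tolerance = 1e-10)
  # balanced design: mixing proportions near 1/3
  expect_true(all(abs(sort(sol$pi) - 1 / 3) < 0.12))
})

test_that("BIC selection finds planted structure and collapses no-structure", {
  fam <- sim_gsd_families(S = 36, L = 3, sep = 3, seed = 12)
  sel <- select_modules(fam$G, L_range = 1:5, seed = 3, n_starts = 4)
  expect_equal(sel$best_L, 3)
  expect_equal(nrow(sel$table), 5)

  flat <- matrix(rep(2 + sin(1:8 / 2), each = 12), 12, byrow = FALSE)
  rownames(flat) <- sprintf("s%02d", 1:12)
  colnames(flat) <- 1:8
  sel_flat <- select_modules(flat, L_range = 1:3, seed = 1, n_starts = 2)
  expect_equal(sel_flat$best_L, 1)
})

test_that("module summaries partition the SNP set", {
  fam <- sim_gsd_families(S = 24, L = 2, sep = 4, seed = 15)
  sol <- em_fit(fam$G, L = 2, seed = 1, n_starts = 3)
  sm <- module_effect_summary(sol)
  expect_setequal(sm$members$marker, rownames(fam$G))
  expect_equal(nrow(sm$members), 24)  # each SNP in exactly one module
  expect_equal(sort(unique(sm$curves$module)), 1:2)
  # single-module summary curve equals the L = 1 mean curve
  sol1 <- em_fit(fam$G, L = 1, seed = 1)
  sm1 <- module_effect_summary(sol1)
  expect_equal(sm1$curves$mean_effect, sol1$mean_curves[, 1])
})

test_that("degenerate inputs are rejected", {
  fam <- sim_gsd_families(S = 5, L = 1, seed = 2)
  expect_error(em_fit(fam$G, L = 9), "1 <= L")
  expect_error(em_fit(fam$G[0, , drop = FALSE], L = 1), "no GSD")
})
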