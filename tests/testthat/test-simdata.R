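test_that("repeated selfing drives heterozygosity to the analytic rate", {
  # after k selfing rounds from a fully heterozygous F1, per-locus
  # heterozygote frequency is (1/2)^k; F10 means k = 9
  map <- genetic_map(1, 4, 90)
  g <- simulate_ril_genotypes(map, n_ril = 3000, n_generations = 10, seed = 2)
  p_het <- mean(g$G == 1L)
  expected <- 0.5^9
  mc_sd <- sqrt(expected * (1 - expected) / length(g$G))
  expect_lt(abs(p_het - expected), 4 * mc_sd + 1e-4)
  # allele frequency stays 1/2 under selfing
  freq_B <- mean(g$G[g$G != -9L]) / 2
  expect_lt(abs(freq_B - 0.5), 4 * sqrt(0.25 / length(g$G)))
})

test_that("genotype correlation decays with map distance and vanishes unlinked", {
  map <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", id = c("a", "b", "c", "d"),
                   pos_cM = c(0, 5, 20, 60)),
    tibble::tibble(chrom = "chr2", id = "e", pos_cM = 0)
  )
  g <- simulate_ril_genotypes(map, n_ril = 1500, seed = 4)
  G <- g$G
  r_near <- cor(G[, "a"], G[, "b"])
  r_mid <- cor(G[, "a"], G[, "c"])
  r_far <- cor(G[, "a"], G[, "d"])
  r_unlinked <- cor(G[, "a"], G[, "e"])
  expect_true(r_near > r_mid && r_mid > r_far)
  expect_lt(abs(r_unlinked), 0.08)
  expect_gt(r_near, 0.8)
})

test_that("zero map distance yields identical marker columns in the limit", {
  map <- tibble::tibble(chrom = "chr1", id = c("a", "b"),
                        pos_cM = c(0, 1e-9))
  g <- simulate_ril_genotypes(map, n_ril = 500, n_generations = 30, seed = 6)
  expect_identical(unname(g$G[, "a"]), unname(g$G[, "b"]))
  expect_true(all(g$G %in% c(0L, 2L)))  # F30: fixation
})

test_that("map validation rejects malformed maps", {
  expect_error(simulate_ril_genotypes(genetic_map(1, 3)[0, ], 10), "empty")
  bad <- tibble::tibble(chrom = "chr1", id = c("a", "b"), pos_cM = c(5, 2))
  expect_error(simulate_ril_genotypes(bad, 10), "strictly increasing")
})

test_that("trajectories equal logistic means under zero noise", {
  map <- genetic_map(1, 10, 50)
  g <- simulate_ril_genotypes(map, n_ril = 5, seed = 1)
  noise0 <- default_noise() |> dplyr::mutate(nu2 = 0)
  raw <- simulate_trajectories(g, list(), noise = noise0, n_replicates = 1,
                               treatments = "H", seed = 1)
  b <- default_baselines() |> dplyr::filter(treatment == "H")
  mu <- logistic_mean(1:8, b$a, b$b, b$r)
  for (r in unique(raw$ril_id)) {
    expect_equal(raw$leaf_number[raw$ril_id == r], mu)
  }
})

test_that("same seed reproduces trajectories exactly", {
  map <- genetic_map(1, 8, 50)
  g <- simulate_ril_genotypes(map, n_ril = 6, seed = 9)
  r1 <- simulate_trajectories(g, list(), n_replicates = 2, seed = 33)
  r2 <- simulate_trajectories(g, list(), n_replicates = 2, seed = 33)
  expect_identical(r1, r2)
})

test_that("a planted QTL shifts group mean plasticity by the asymptote algebra", {
  # genotype-0 a = 30 vs genotype-2 a = 20 in L, a = 25 for both in H:
  # late-time group difference in pWPP approaches (30-25) - (20-25) = 10
  map <- genetic_map(1, 20, 80)
  g <- simulate_ril_genotypes(map, n_ril = 40, seed = 12)
  q <- qtl_spec(g$map$id[10], list(
    L = list("0" = c(30, 20, 0.6), "2" = c(20, 20, 0.6)),
    H = list("0" = c(25, 20, 0.6), "2" = c(25, 20, 0.6))
  ))
  noise0 <- default_noise() |> dplyr::mutate(nu2 = 0)
  raw <- simulate_trajectories(g, list(q), noise = noise0, weeks = 1:25,
                               n_replicates = 1, seed = 5)
  tr <- compute_plasticity(average_replicates(raw), "pWPP")
  Z <- as_trait_matrix(tr)
  gg <- g$G[rownames(Z), 10]
  d <- mean(Z[gg == 0L, 25]) - mean(Z[gg == 2L, 25])
  expect_equal(d, 10, tolerance = 0.01)
})

test_that("QTL marker indices out of range are rejected", {
  map <- genetic_map(1, 5, 50)
  g <- simulate_ril_genotypes(map, n_ril = 4, seed = 1)
  bad <- qtl_spec(99L, list(H = list("0" = c(20, 10, 0.5),
                                     "2" = c(22, 10, 0.5))))
  expect_error(simulate_trajectories(g, list(bad), n_replicates = 1),
               "out of range")
})

test_that("simulated residual covariance converges to the SAD(1) target", {
  map <- genetic_map(1, 3, 10)
  g <- simulate_ril_genotypes(map, n_ril = 2, seed = 3)
  noise <- tibble::tibble(treatment = "H", phi = 0.7, nu2 = 2)
  target <- sad1_covariance(0.7, 2, 8)
  frob <- vapply(c(50, 2000), function(nrep) {
    raw <- simulate_trajectories(g, list(), noise = noise,
                                 n_replicates = nrep, treatments = "H",
                                 seed = 77)
    b <- default_baselines() |> dplyr::filter(treatment == "H")
    mu <- logistic_mean(1:8, b$a, b$b, b$r)
    E <- matrix(raw$leaf_number, ncol = 8, byrow = TRUE) -
      matrix(mu, nrow = 2 * nrep, ncol = 8, byrow = TRUE)
    norm(cov(E) - target, "F")
  }, numeric(1))
  expect_lt(frob[2], frob[1])
  expect_lt(frob[2] / norm(target, "F"), 0.15)
})
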