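test_that("replicate averaging takes the mean over observed values", {
  raw <- tibble::tibble(
    ril_id = "RIL001", treatment = "H",
    replicate = rep(1:3, each = 2),
    week = rep(1:2, 3),
    leaf_number = c(4, 10, 6, 12, NA, 14)
  )
  p <- average_replicates(raw)
  expect_equal(p$leaf_number[p$week == 1], 5)   # mean(4, 6, NA)
  expect_equal(p$leaf_number[p$week == 2], 12)  # mean(10, 12, 14)

  same <- raw |> dplyr::mutate(leaf_number = 7)
  expect_true(all(average_replicates(same)$leaf_number == 7))

  expect_error(average_replicates(dplyr::mutate(raw, week = week + 0.5)),
               "integer")
})

test_that("RILs with an empty week are dropped from the panel", {
  raw <- tibble::tibble(
    ril_id = rep(c("RIL001", "RIL002"), each = 2),
    treatment = "H", replicate = 1L, week = rep(1:2, 2),
    leaf_number = c(3, NA, 4, 8)
  )
  p <- average_replicates(raw)
  expect_setequal(unique(p$ril_id), "RIL002")
})

test_that("plasticity is the elementwise treatment difference", {
  cx <- rbind(c(3, 5, 8), c(2, 4, 6))
  cy <- rbind(c(1, 2, 3), c(2, 4, 6))
  raw <- dplyr::bind_rows(raw_from_curves(cx, "L", 1:3),
                          raw_from_curves(cy, "H", 1:3))
  tr <- compute_plasticity(average_replicates(raw), "pWPP")  # L - H
  Z <- as_trait_matrix(tr)
  expect_equal(unname(Z["RIL001", ]), c(2, 3, 5))
  expect_equal(unname(Z["RIL002", ]), c(0, 0, 0))

  # swapping the treatment labels flips the sign
  raw_sw <- dplyr::bind_rows(raw_from_curves(cx, "H", 1:3),
                             raw_from_curves(cy, "L", 1:3))
  Z_sw <- as_trait_matrix(compute_plasticity(average_replicates(raw_sw), "pWPP"))
  expect_equal(Z_sw, -Z)
})

test_that("unknown contrasts and empty intersections are rejected", {
  panels <- six_panels_exact(n_ril = 4)
  expect_error(compute_plasticity(panels, "WPP_X"), "unknown contrast")
  raw <- dplyr::bind_rows(
    raw_from_curves(matrix(1:6, 2), "L", 1:3) |>
      dplyr::mutate(ril_id = paste0("A", ril_id)),
    raw_from_curves(matrix(1:6, 2), "H", 1:3)
  )
  expect_error(compute_plasticity(average_replicates(raw), "pWPP"),
               "fewer than two RILs")
})

test_that("contrast algebra identities hold exactly per RIL", {
  panels <- six_panels_exact(n_ril = 10, seed = 21)
  tr <- lapply(stats::setNames(nm = plasticity_contrasts()$contrast),
               function(cn) as_trait_matrix(compute_plasticity(panels, cn)))
  rils <- rownames(tr$pWPP)
  # TPP_L - TPP_H = MPP_L + oWPP_H - pWPP
  lhs <- tr$TPP_L[rils, ] - tr$TPP_H[rils, ]
  rhs <- tr$MPP_L[rils, ] + tr$oWPP_H[rils, ] - tr$pWPP[rils, ]
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # MPP_L + oWPP_H = LL - HH (telescoping)
  LL <- as_trait_matrix(compute_plasticity(panels, "TPP_L")) +
    as_trait_matrix(compute_plasticity(panels, "pWPP"))  # (LL-L)+(L-H) = LL-H
  direct <- tr$MPP_L[rils, ] + tr$oWPP_H[rils, ]
  hh_ll <- as_trait_matrix(compute_plasticity(panels, "TPP_H"))  # HH - H
  expect_equal(direct, LL[rils, ] - hh_ll[rils, ], tolerance = 1e-12)
})

test_that("asymptotic summaries report mean and SE of fitted asymptotes", {
  tt <- 1:8
  curves <- matrix(logistic_mean(tt, 14, 8, 0.7), 4, 8, byrow = TRUE)
  p <- average_replicates(raw_from_curves(curves, "H", tt))
  s <- asymptotic_summary(p)
  expect_equal(s$mean, 14, tolerance = 1e-4)
  expect_lt(s$se, 1e-4)

  c3 <- rbind(logistic_mean(tt, 10, 8, 0.9), logistic_mean(tt, 12, 8, 0.9),
              logistic_mean(tt, 14, 8, 0.9))
  s3 <- asymptotic_summary(average_replicates(raw_from_curves(c3, "L", tt)))
  expect_equal(s3$mean, 12, tolerance = 1e-3)
  expect_equal(s3$se, 2 / sqrt(3), tolerance = 1e-2)
})

test_that("contrasts with identical data give pairwise P = 1", {
  # construct panels where TPP_H and TPP_L per-RIL values coincide:
  # HH = H + d_i and LL = L + d_i with flat trajectories
  withr::with_seed(5, {
    n <- 8
    d <- stats::rnorm(n, 3, 1)
    H <- matrix(10, n, 8)
    L <- H  # identical parental panels, so TPP_H and TPP_L data coincide
    raw <- dplyr::bind_rows(
      raw_from_curves(H, "H"), raw_from_curves(L, "L"),
      raw_from_curves(H + d, "HH"), raw_from_curves(L + d, "LL"),
      raw_from_curves(L, "LH"), raw_from_curves(H, "HL")
    )
  })
  res <- test_contrasts(average_replicates(raw),
                        contrasts = c("TPP_H", "TPP_L"),
                        comparisons = list(c("TPP_H", "TPP_L")))
  expect_equal(res$pairwise$p, 1)
  lets <- res$contrasts$letter
  expect_equal(lets[1], lets[2])  # shared compact letter
})

test_that("planted contrast differences are detected by the Welch family", {
  # oWPP_L mean 4 vs oWPP_H mean 1 (sd 2): expect significance at n = 40
  withr::with_seed(9, {
    n <- 40
    HH <- matrix(10, n, 8)
    HL <- HH + stats::rnorm(n, 1, 2)
    LH <- matrix(11, n, 8)
    LL <- LH + stats::rnorm(n, 4, 2)
    raw <- dplyr::bind_rows(
      raw_from_curves(HH, "HH"), raw_from_curves(HL, "HL"),
      raw_from_curves(LH, "LH"), raw_from_curves(LL, "LL")
    )
  })
  res <- test_contrasts(average_replicates(raw),
                        contrasts = c("oWPP_H", "oWPP_L"),
                        comparisons = list(c("oWPP_L", "oWPP_H")))
  expect_lt(res$pairwise$p_adj, 0.05)
  lets <- res$contrasts$letter
  expect_false(lets[1] == lets[2])
})

test_that("one-sample contrast test keeps its nominal type-I rate", {
  # flat trajectories with zero-mean RIL effects: asymptotic plasticity has
  # true mean 0, so rejections should stay near the nominal 5% level
  rejections <- vapply(1:15, function(r) {
    withr::with_seed(100 + r, {
      n <- 15
      H <- matrix(10, n, 6) + stats::rnorm(n, 0, 1.5)
      L <- matrix(10, n, 6) + stats::rnorm(n, 0, 1.5)
    })
    raw <- dplyr::bind_rows(raw_from_curves(H, "H", 1:6),
                            raw_from_curves(L, "L", 1:6))
    res <- test_contrasts(average_replicates(raw), contrasts = "pWPP",
                          comparisons = list())
    res$contrasts$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.25)
})

test_that("degenerate zero-variance traits are handled explicitly", {
  n <- 6
  raw <- dplyr::bind_rows(
    raw_from_curves(matrix(10, n, 4), "H", 1:4),
    raw_from_curves(matrix(10, n, 4), "L", 1:4)
  )
  res <- test_contrasts(average_replicates(raw), contrasts = "pWPP",
                        comparisons = list())
  expect_equal(res$contrasts$p, 1)  # zero variance, zero mean
})
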