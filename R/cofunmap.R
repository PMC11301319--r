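#' SAD(1) covariance matrix
#'
#' First-order structured antedependence covariance over `T` equally spaced
#' time points: `Sigma(t1, t2) = nu2 * phi^(t2 - t1) * (1 - phi^(2 t1)) /
#' (1 - phi^2)` for `t1 <= t2`. Variances and covariances vary over time with
#' only two parameters, and the determinant and inverse have closed forms.
#'
#' @param phi Antedependence coefficient, `|phi| < 1`.
#' @param nu2 Innovation variance, `> 0`.
#' @param T Number of time points.
#' @return A `T x T` symmetric positive-definite matrix.
#' @seealso [sad1_inverse()], [sad1_determinant()], [composite_covariance()]
#' @export
#' @examples
#' sad1_covariance(0, 2, 3)  # 2 * diag(3)
sad1_covariance <- function(phi, nu2, T) {
  stopifnot(is.finite(phi), is.finite(nu2), T >= 1)
  if (abs(phi) >= 1) rlang::abort("SAD(1) requires |phi| < 1.")
  if (nu2 <= 0) rlang::abort("SAD(1) requires nu2 > 0.")
  t <- seq_len(T)
  outer(t, t, function(i, j) {
    nu2 * phi^abs(i - j) * (1 - phi^(2 * pmin(i, j))) / (1 - phi^2)
  })
}

#' Closed-form inverse of a SAD(1) covariance matrix
#'
#' The inverse is tridiagonal: `(1 + phi^2) / nu2` on the diagonal (except
#' `1 / nu2` in the last cell) and `-phi / nu2` on the off-diagonals.
#'
#' @inheritParams sad1_covariance
#' @return A `T x T` tridiagonal matrix equal to `solve(sad1_covariance(...))`.
#' @export
sad1_inverse <- function(phi, nu2, T) {
  stopifnot(abs(phi) < 1, nu2 > 0, T >= 1)
  Q <- diag(c(rep(1 + phi^2, T - 1), 1) / nu2, nrow = T)
  if (T > 1) {
    idx <- cbind(seq_len(T - 1), seq_len(T - 1) + 1)
    Q[idx] <- Q[idx[, 2:1, drop = FALSE]] <- -phi / nu2
  }
  Q
}

#' Closed-form determinant of a SAD(1) covariance matrix
#'
#' @inheritParams sad1_covariance
#' @return `nu2^T`.
#' @export
sad1_determinant <- function(phi, nu2, T) {
  stopifnot(abs(phi) < 1, nu2 > 0, T >= 1)
  nu2^T
}

#' Composite residual covariance of a plasticity trait
#'
#' Under independence of the two environments, the covariance of the
#' difference trait is the elementwise sum of the two environment-specific
#' SAD(1) matrices. No closed-form inverse is assumed for the sum; generic
#' Cholesky factorisation is used downstream.
#'
#' @param px,py Length-2 numeric vectors `c(phi, nu2)` for the two
#'   environments.
#' @param T Number of time points.
#' @return A `T x T` matrix with attribute `params`.
#' @export
composite_covariance <- function(px, py, T) {
  M <- sad1_covariance(px[[1]], px[[2]], T) +
    sad1_covariance(py[[1]], py[[2]], T)
  attr(M, "params") <- c(phi_x = px[[1]], nu2_x = px[[2]],
                         phi_y = py[[1]], nu2_y = py[[2]])
  M
}

#' Likelihood-ratio statistic
#'
#' `LR = 2 (logL1 - logL0)`, clipped at zero. A negative value beyond `tol`
#' indicates optimizer failure (the null is nested in the alternative) and
#' triggers a warning.
#'
#' @param logL0,logL1 Maximised log-likelihoods under the no-QTL and QTL
#'   models.
#' @param tol Negative-LR tolerance.
#' @return The LR statistic (non-negative).
#' @export
lr_statistic <- function(logL0, logL1, tol = 1e-6) {
  stopifnot(is.finite(logL0), is.finite(logL1))
  lr <- 2 * (logL1 - logL0)
  if (lr < -tol) {
    rlang::warn(sprintf("negative LR (%.3g) clipped to 0; optimizer noise.", lr))
  }
  pmax(lr, 0)
}

# Optimiser budgets. Single-SNP fits (user-facing) run the block-coordinate
# scheme to convergence; genome-wide scans use one warm-started round per SNP
# (means under the null covariance, then one covariance update), which the
# permutation calibration sees identically on observed and reshuffled data.
default_scan_control <- function(control = list()) {
  utils::modifyList(
    list(evalA = 300L, evalB = 120L, rounds = 6L, starts0 = 3L, tol = 1e-7),
    control
  )
}

fast_scan_control <- function(control = list()) {
  utils::modifyList(
    list(evalA = 70L, evalB = 40L, rounds = 1L, starts0 = 3L, tol = 1e-6),
    control
  )
}

# Unweighted least-squares fit of a difference-of-logistics curve to a mean
# trajectory, over the six log-parameters; used to initialise the likelihood
# fits, whose per-class curves then start from this solution.
fit_difference_curve <- function(zbar, tt, starts) {
  obj <- function(p) {
    p <- pmin(pmax(p, -12), 12)
    mu <- exp(p[1]) / (1 + exp(p[2]) * exp(-exp(p[3]) * tt)) -
      exp(p[4]) / (1 + exp(p[5]) * exp(-exp(p[6]) * tt))
    sum((zbar - mu)^2)
  }
  best <- NULL
  for (p0 in starts) {
    o <- tryCatch(
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 1200, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    o2 <- tryCatch(
      stats::optim(o$par, obj, method = "BFGS",
                   control = list(maxit = 200, reltol = 1e-13)),
      error = function(e) o
    )
    if (o2$value > o$value) o2 <- o
    if (is.null(best) || o2$value < best$value) best <- o2
  }
  pmin(pmax(best$par, -12), 12)
}

# Starting log-parameters for the two component logistic curves: component
# fits to the grand mean trajectories of the two source panels when the
# trait carries them, plus shifted reconstructions of the difference curve,
# each refined by a direct least-squares fit of the difference curve itself.
cofunmap_init <- function(trait, Z, tt) {
  zbar <- colMeans(Z)
  comp_start <- function(mx, my) {
    fx <- fit_logistic(as.numeric(mx), tt)
    fy <- fit_logistic(as.numeric(my), tt)
    log(pmax(c(fx$a, fx$b, fx$r, fy$a, fy$b, fy$r), 1e-6))
  }
  starts <- list()
  mx <- attr(trait, "mean_x")
  my <- attr(trait, "mean_y")
  if (!is.null(mx) && !is.null(my)) {
    starts[[length(starts) + 1]] <- comp_start(mx, my)
  }
  for (off in c(5, 15, 40) * max(1, max(abs(zbar)) / 5)) {
    mx2 <- pmax(zbar, 0) + off
    starts[[length(starts) + 1]] <- comp_start(mx2, mx2 - zbar)
  }
  fit_difference_curve(zbar, tt, starts)
}

trait_weeks <- function(trait, Z) {
  w <- attr(trait, "weeks")
  if (is.null(w)) w <- as.numeric(colnames(Z))
  if (any(is.na(w))) rlang::abort("trait carries no usable time grid.")
  w
}

new_cofunmap_fit <- function(res, weeks, null = FALSE) {
  th <- res$theta1
  colnames(th) <- c("a_x", "b_x", "r_x", "a_y", "b_y", "r_y")
  th0 <- res$theta0
  colnames(th0) <- colnames(th)
  structure(
    list(logL0 = res$logL0, logL1 = res$logL1, J = res$J,
         n_used = res$n_used, n_j = res$n_j,
         theta = th, cov = res$cov1, theta_null = th0, cov_null = res$cov0,
         weeks = weeks, is_null = null),
    class = "cofunmap_fit"
  )
}

#' @export
print.cofunmap_fit <- function(x, ...) {
  cat(sprintf("<cofunmap_fit> J = %d classes, n = %d, logL0 = %.3f, logL1 = %.3f, LR = %.3f\n",
              x$J, x$n_used, x$logL0, x$logL1,
              lr_statistic(x$logL0, x$logL1)))
  invisible(x)
}

#' @export
tidy.cofunmap_fit <- function(x, ...) {
  th <- x$theta
  tibble(
    class = seq_len(nrow(th)),
    n = x$n_j,
    a_x = th[, "a_x"], b_x = th[, "b_x"], r_x = th[, "r_x"],
    a_y = th[, "a_y"], b_y = th[, "b_y"], r_y = th[, "r_y"],
    asymptote_diff = th[, "a_x"] - th[, "a_y"]
  )
}

#' @export
glance.cofunmap_fit <- function(x, ...) {
  tibble(logL0 = x$logL0, logL1 = x$logL1,
         lr = lr_statistic(x$logL0, x$logL1),
         J = x$J, n = x$n_used)
}

#' Fitted genotype mean plasticity curves
#'
#' Evaluates the fitted difference-of-logistics mean curve of each genotype
#' class on the measurement grid.
#'
#' @param fit A `cofunmap_fit`.
#' @return Tibble `class`, `week`, `mean_plasticity`.
#' @export
fitted_mean_curves <- function(fit) {
  stopifnot(inherits(fit, "cofunmap_fit"))
  th <- fit$theta
  purrr::map_dfr(seq_len(nrow(th)), function(j) {
    mu <- logistic_mean(fit$weeks, th[j, "a_x"], th[j, "b_x"], th[j, "r_x"]) -
      logistic_mean(fit$weeks, th[j, "a_y"], th[j, "b_y"], th[j, "r_y"])
    tibble(class = j, week = fit$weeks, mean_plasticity = mu)
  })
}

#' Fit the no-QTL model to a plasticity trait
#'
#' Maximises the composite functional-mapping likelihood with a single mean
#' curve (difference of two logistic curves, 6 parameters) and a composite
#' SAD(1) covariance (4 parameters), by alternating generalised least-squares
#' mean-curve fits with covariance shape optimisation (overall scale profiled
#' in closed form).
#'
#' @param trait A `plasticity_trait` from [compute_plasticity()].
#' @param control Optimiser settings (advanced): `evalA`, `evalB`, `rounds`,
#'   `starts0`, `tol`.
#' @return A `cofunmap_fit` with `logL0 == logL1` (no genotype split).
#' @export
fit_null <- function(trait, control = list()) {
  Z <- trait_matrix(trait)
  if (nrow(Z) < 2) rlang::abort("need at least two RILs.")
  tt <- trait_weeks(trait, Z)
  init <- cofunmap_init(trait, Z, tt)
  res <- cpp_fit_single(Z, rep(0L, nrow(Z)), tt, init,
                        default_scan_control(control))
  new_cofunmap_fit(res, tt, null = TRUE)
}

#' Fit the QTL model at one SNP
#'
#' Splits RILs by genotype code at the SNP; classes with fewer than `n_min`
#' lines are dropped and their RILs excluded, missing genotypes excluded.
#' Each retained class gets its own difference-of-logistics mean curve; the
#' composite SAD(1) covariance is shared across classes and re-estimated.
#' Genotype curves are initialised from the null solution, so the likelihood
#' ratio is non-negative by construction.
#'
#' @param trait A `plasticity_trait`.
#' @param genotype Integer genotype codes (0/1/2, -9 missing), either named
#'   by RIL id or aligned with the trait's RIL order.
#' @param n_min Minimum class size (default 5).
#' @inheritParams fit_null
#' @return A `cofunmap_fit`; `NULL` (with a warning) if no class survives
#'   filtering.
#' @export
fit_alternative <- function(trait, genotype, n_min = 5, control = list()) {
  Z <- trait_matrix(trait)
  tt <- trait_weeks(trait, Z)
  if (!is.null(names(genotype))) {
    genotype <- genotype[rownames(Z)]
  }
  if (length(genotype) != nrow(Z)) {
    rlang::abort("genotype vector must align with the trait's RILs.")
  }
  g <- as.integer(genotype)
  g[is.na(g)] <- -9L
  codes <- sort(intersect(unique(g), 0:2))
  keep <- codes[vapply(codes, function(cc) sum(g == cc) >= n_min, TRUE)]
  if (length(keep) == 0) {
    rlang::warn("no genotype class reaches n_min; SNP skipped.")
    return(NULL)
  }
  grp <- rep(-1L, length(g))
  for (j in seq_along(keep)) grp[g == keep[j]] <- j - 1L
  init <- cofunmap_init(trait, Z, tt)
  res <- cpp_fit_single(Z, grp, tt, init, default_scan_control(control))
  out <- new_cofunmap_fit(res, tt)
  out$codes <- keep
  out
}

align_trait_genotypes <- function(trait, genotypes) {
  Z <- trait_matrix(trait)
  shared <- intersect(rownames(Z), genotypes$ril_ids)
  if (length(shared) == 0) {
    rlang::abort("empty intersection of RIL ids between trait and genotypes.")
  }
  list(Z = Z[shared, , drop = FALSE],
       G = genotypes$G[shared, , drop = FALSE],
       ril_ids = shared)
}

scan_perm_matrix <- function(n, n_perm, seed) {
  withr::with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_perm), function(i) sample.int(n))),
           nrow = n, ncol = n_perm)
  })
}

#' Genome-wide QTL scan of a plasticity trait
#'
#' Computes the composite functional-mapping likelihood-ratio statistic at
#' every SNP, and calibrates the genome-wide 5% threshold as the
#' `1 - alpha` quantile of the maximum LR over `n_perm` permutations in which
#' whole RIL phenotype vectors are reshuffled against the genotype rows
#' (breaking all SNP-trait association while preserving the temporal
#' covariance of the trait). The empirical P value of a SNP is the fraction
#' of permutation maxima at or above its LR.
#'
#' @param trait A `plasticity_trait`.
#' @param genotypes A `ril_genotypes` object; RILs are aligned with the trait
#'   by id intersection.
#' @param n_perm Number of permutations (>= 20; 0 skips calibration).
#' @param alpha Genome-wide significance level.
#' @param n_min Minimum genotype class size per SNP.
#' @param seed Integer seed for the permutations.
#' @inheritParams fit_null
#' @return A `cofunmap_scan` tibble with one row per SNP (`marker`, `chrom`,
#'   `pos_bp`, `pos_cM`, `J`, `n_used`, `lr`, `p_emp`, `significant`,
#'   `skip_reason`, list-column `model`) and attributes `threshold`,
#'   `perm_max`, `alpha`, `n_perm`, `seed`, `null_fit`, `contrast`, `weeks`.
#' @export
cofunmap_scan <- function(trait, genotypes, n_perm = 100, alpha = 0.05,
                          n_min = 5, seed = 1, control = list()) {
  stopifnot(inherits(genotypes, "ril_genotypes"))
  if (n_perm > 0) check_perm_settings(n_perm, alpha)
  al <- align_trait_genotypes(trait, genotypes)
  if (ncol(al$G) == 0) rlang::abort("no SNPs to scan.")
  tt <- trait_weeks(trait, al$Z)
  init <- cofunmap_init(trait, al$Z, tt)
  perms <- if (n_perm > 0) {
    scan_perm_matrix(nrow(al$Z), n_perm, seed)
  } else {
    matrix(integer(0), nrow = nrow(al$Z), ncol = 0)
  }
  res <- cpp_scan(al$Z, al$G, tt, init, as.integer(n_min), perms,
                  fast_scan_control(control), keep_models = TRUE)

  lr <- res$lr
  if (n_perm > 0) {
    maxima <- res$perm_max
    threshold <- unname(stats::quantile(maxima, 1 - alpha, type = 1))
    p_emp <- vapply(lr, function(x) {
      if (is.na(x)) NA_real_ else mean(maxima >= x)
    }, numeric(1))
    signif <- !is.na(lr) & lr >= threshold
  } else {
    maxima <- numeric(0)
    threshold <- NA_real_
    p_emp <- rep(NA_real_, length(lr))
    signif <- rep(NA, length(lr))
  }

  map <- genotypes$map
  out <- tibble(
    marker = map$id, chrom = map$chrom,
    pos_bp = map$pos_bp, pos_cM = map$pos_cM,
    J = res$J, n_used = res$n_used,
    lr = lr, logL0 = res$logL0, logL1 = res$logL1,
    p_emp = p_emp, significant = signif,
    skip_reason = as.character(res$skip_reason),
    model = lapply(seq_along(lr), function(s) {
      m <- res$models[[s]]
      if (is.null(m)) return(NULL)
      colnames(m$theta) <- c("a_x", "b_x", "r_x", "a_y", "b_y", "r_y")
      m$cov <- res$cov[s, ]
      m
    })
  )
  structure(out, class = c("cofunmap_scan", class(out)),
            threshold = threshold, perm_max = maxima, alpha = alpha,
            n_perm = n_perm, seed = seed, weeks = tt,
            null_fit = list(theta = res$null_theta, cov = res$null_cov,
                            logL = res$null_logL),
            contrast = attr(trait, "contrast"))
}

check_perm_settings <- function(n_perm, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  if (n_perm < 20) rlang::abort("n_perm must be at least 20.")
  if (floor(alpha * n_perm) < 1) {
    rlang::abort(sprintf(
      "n_perm = %d is too small to estimate the %.3g quantile; increase n_perm.",
      n_perm, 1 - alpha))
  }
  invisible(TRUE)
}

#' Permutation-calibrated genome-wide LR threshold
#'
#' Reshuffles RIL phenotype vectors against genotype rows `n_perm` times,
#' reruns the full scan each time, and returns the empirical `1 - alpha`
#' quantile of the genome-wide maximum LR.
#'
#' @inheritParams cofunmap_scan
#' @return List with `threshold`, `maxima`, `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(trait, genotypes, n_perm = 100,
                                  alpha = 0.05, n_min = 5, seed = 1,
                                  control = list()) {
  check_perm_settings(n_perm, alpha)
  al <- align_trait_genotypes(trait, genotypes)
  tt <- trait_weeks(trait, al$Z)
  init <- cofunmap_init(trait, al$Z, tt)
  perms <- scan_perm_matrix(nrow(al$Z), n_perm, seed)
  res <- cpp_scan(al$Z, al$G, tt, init, as.integer(n_min), perms,
                  fast_scan_control(control), keep_models = FALSE)
  maxima <- res$perm_max
  list(threshold = unname(stats::quantile(maxima, 1 - alpha, type = 1)),
       maxima = maxima, alpha = alpha, n_perm = n_perm, seed = seed)
}

#' @export
tidy.cofunmap_scan <- function(x, ...) {
  dplyr::select(as_tibble(x), -"model")
}

#' @export
glance.cofunmap_scan <- function(x, ...) {
  tibble(
    n_snp = nrow(x),
    n_tested = sum(!is.na(x$lr)),
    n_significant = sum(x$significant, na.rm = TRUE),
    threshold = attr(x, "threshold"),
    alpha = attr(x, "alpha"),
    n_perm = attr(x, "n_perm"),
    max_lr = max(x$lr, na.rm = TRUE)
  )
}

#' Manhattan-ready export of a scan
#'
#' Empirical P values of zero (LR above every permutation maximum) are
#' floored at `1 / (2 * n_perm)` for plotting on the -log10 scale.
#'
#' @param scan A `cofunmap_scan`.
#' @return Tibble `chrom`, `pos`, `neg_log10_p`, `significant`.
#' @export
manhattan_export <- function(scan) {
  stopifnot(inherits(scan, "cofunmap_scan"))
  n_perm <- attr(scan, "n_perm")
  floor_p <- if (isTRUE(n_perm > 0)) 1 / (2 * n_perm) else NA_real_
  scan |>
    as_tibble() |>
    dplyr::filter(!is.na(.data$lr)) |>
    dplyr::mutate(neg_log10_p = -log10(pmax(.data$p_emp, floor_p))) |>
    dplyr::select(chrom = "chrom", pos = "pos_bp", "neg_log10_p",
                  "significant")
}

#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' @export
autoplot.cofunmap_scan <- function(object, ...) {
  d <- manhattan_export(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$neg_log10_p,
                                  colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "alpha")), linetype = 2) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](P)),
                  title = paste0("Plasticity QTL scan",
                                 if (!is.null(attr(object, "contrast")))
                                   paste0(": ", attr(object, "contrast"))
                                 else "")) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}
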