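#' Genetic standard deviation (GSD) curve of a fitted QTL
#'
#' The time-varying genetic effect of a SNP is summarised as the weighted
#' population standard deviation of its genotype mean plasticity curves:
#' `g(t) = sqrt( (1/n) sum_j n_j mu_j(t)^2 - ((1/n) sum_j n_j mu_j(t))^2 )`,
#' with weights given by the genotype class sizes. A single-class SNP has a
#' zero curve.
#'
#' @param fit A `cofunmap_fit` (or a scan `model` list with `theta`, `n_j`).
#' @param weeks Time grid (defaults to the fit's grid).
#' @return Tibble `week`, `gsd`.
#' @export
gsd_curve <- function(fit, weeks = NULL) {
  if (inherits(fit, "cofunmap_fit")) {
    th <- fit$theta; nj <- fit$n_j
    weeks <- weeks %||% fit$weeks
  } else {
    th <- fit$theta; nj <- fit$n_j
    if (is.null(weeks)) rlang::abort("weeks needed for a bare model list.")
  }
  if (nrow(th) == 1) {
    rlang::warn("single genotype class: GSD curve is identically zero.")
    return(tibble(week = weeks, gsd = rep(0, length(weeks))))
  }
  mus <- vapply(seq_len(nrow(th)), function(j) {
    logistic_mean(weeks, th[j, "a_x"], th[j, "b_x"], th[j, "r_x"]) -
      logistic_mean(weeks, th[j, "a_y"], th[j, "b_y"], th[j, "r_y"])
  }, numeric(length(weeks)))
  w <- nj / sum(nj)
  m1 <- as.numeric(mus %*% w)
  m2 <- as.numeric(mus^2 %*% w)
  tibble(week = weeks, gsd = sqrt(pmax(m2 - m1^2, 0)))
}

#' GSD curves for the SNPs of a scan
#'
#' @param scan A `cofunmap_scan`.
#' @param significant_only Keep only genome-wide significant SNPs.
#' @return Tibble `marker`, `week`, `gsd`.
#' @export
gsd_curves <- function(scan, significant_only = TRUE) {
  stopifnot(inherits(scan, "cofunmap_scan"))
  weeks <- attr(scan, "weeks")
  d <- as_tibble(scan) |> dplyr::filter(!is.na(.data$lr), .data$J > 1)
  if (significant_only) d <- dplyr::filter(d, .data$significant)
  if (nrow(d) == 0) return(tibble(marker = character(), week = numeric(),
                                  gsd = numeric()))
  purrr::map_dfr(seq_len(nrow(d)), function(i) {
    g <- gsd_curve(d$model[[i]], weeks = weeks)
    g$marker <- d$marker[i]
    g[, c("marker", "week", "gsd")]
  })
}

# curves tibble (marker, week, value-col) -> S x T matrix
gsd_matrix <- function(gsd, value = "gsd") {
  if (is.matrix(gsd)) return(gsd)
  wide <- tidyr::pivot_wider(gsd, id_cols = "marker", names_from = "week",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$marker
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# Legendre polynomial basis (degrees 0..order) on time rescaled to [-1, 1]
legendre_basis <- function(tt, order) {
  x <- if (length(tt) > 1) 2 * (tt - min(tt)) / (max(tt) - min(tt)) - 1 else 0
  B <- matrix(0, length(tt), order + 1)
  B[, 1] <- 1
  if (order >= 1) B[, 2] <- x
  if (order >= 2) {
    for (k in 2:order) {
      B[, k + 1] <- ((2 * k - 1) * x * B[, k] - (k - 1) * B[, k - 1]) / k
    }
  }
  B
}

logdmvnorm_chol <- function(E, cholL) {
  # E: residual matrix S x T; returns per-row log density
  T <- ncol(E)
  v <- backsolve(cholL, t(E), upper.tri = TRUE, transpose = TRUE)
  -0.5 * (T * log(2 * pi) + 2 * sum(log(diag(cholL))) + colSums(v^2))
}

# Covariance update of the M-step: Sigma = nu2 * R(phi) with det R = 1, so
# the Q-function part is S T log(nu2) + tr(Sigma^{-1} W); nu2 is profiled in
# closed form and phi found by a 1-D search. The old parameters are kept if
# (numerically) better, preserving EM monotonicity.
em_mstep_cov <- function(W, S_tot, T, phi_old, nu2_old, min_nu2) {
  obj_full <- function(phi, nu2) {
    S_tot * T * log(nu2) + sum(sad1_inverse(phi, nu2, T) * W)
  }
  prof_nu2 <- function(phi) {
    max(sum(sad1_inverse(phi, 1, T) * W) / (S_tot * T), min_nu2)
  }
  opt <- stats::optimize(function(p) obj_full(p, prof_nu2(p)),
                         interval = c(-0.985, 0.985))
  phi_new <- opt$minimum
  nu2_new <- prof_nu2(phi_new)
  if (obj_full(phi_new, nu2_new) <= obj_full(phi_old, nu2_old)) {
    c(phi = phi_new, nu2 = nu2_new)
  } else {
    c(phi = phi_old, nu2 = nu2_old)
  }
}

#' Fit a Gaussian mixture of GSD curves (one module count)
#'
#' EM for a mixture of `L` T-variate normals whose module mean curves are
#' Legendre polynomials of the given order and whose covariance is a single
#' SAD(1) matrix shared by all modules. The M-step solves the module curves
#' by generalised least squares in closed form and updates the covariance by
#' profiling the innovation variance over a 1-D search in `phi`; the
#' observed-data log-likelihood is non-decreasing across iterations.
#'
#' @param gsd GSD curves: tibble `marker`, `week`, `gsd` (from
#'   [gsd_curves()]) or a numeric matrix S x T with named rows.
#' @param L Number of modules (1 <= L <= S).
#' @param order Legendre polynomial order of the module mean curves
#'   (default 4).
#' @param seed Integer seed for the k-means initialisations.
#' @param n_starts Number of EM starts (best log-likelihood kept).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change below
#'   `tol` or `max_iter` iterations.
#' @param weeks Time grid (defaults to the matrix column names).
#' @return A `module_solution`: mixing proportions `pi`, coefficient matrix
#'   `coef`, module `mean_curves`, SAD(1) `phi`/`nu2`, responsibility matrix
#'   `resp`, hard `assignment`, `logL`, `bic`, free-parameter count `d`, and
#'   the per-iteration `logl_trace` of the best start.
#' @export
em_fit <- function(gsd, L, order = 4, seed = 1, n_starts = 10,
                   max_iter = 500, tol = 1e-8, weeks = NULL) {
  Gm <- gsd_matrix(gsd)
  S <- nrow(Gm); T <- ncol(Gm)
  if (S == 0) rlang::abort("no GSD curves supplied.")
  if (L < 1 || L > S) rlang::abort("need 1 <= L <= number of curves.")
  weeks <- weeks %||% as.numeric(colnames(Gm))
  if (any(is.na(weeks))) weeks <- seq_len(T)
  B <- legendre_basis(weeks, order)
  min_nu2 <- 1e-8

  run_one <- function(assign0) {
    resp <- matrix(0, S, L)
    resp[cbind(seq_len(S), assign0)] <- 1
    phi <- 0.3
    nu2 <- max(mean(apply(Gm, 2, stats::var)), min_nu2)
    if (!is.finite(nu2)) nu2 <- 1
    pi_l <- rep(1 / L, L)
    coef <- matrix(0, order + 1, L)
    logl_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      # M-step (for it == 1 this initialises parameters from assign0)
      wsum <- pmax(colSums(resp), 1e-12)
      pi_l <- wsum / sum(wsum)
      Q <- sad1_inverse(phi, nu2, T)
      BtQB <- crossprod(B, Q %*% B)
      for (l in seq_len(L)) {
        gbar <- colSums(resp[, l] * Gm) / wsum[l]
        coef[, l] <- solve(BtQB, crossprod(B, Q %*% gbar))
      }
      M <- B %*% coef   # T x L module mean curves
      W <- matrix(0, T, T)
      for (l in seq_len(L)) {
        E <- sweep(Gm, 2, M[, l])
        W <- W + crossprod(sqrt(resp[, l]) * E)
      }
      cv <- em_mstep_cov(W, S, T, phi, nu2, min_nu2)
      phi <- unname(cv["phi"]); nu2 <- unname(cv["nu2"])
      # E-step + observed-data log-likelihood
      Sig <- sad1_covariance(phi, nu2, T)
      cholL <- chol(Sig)
      logd <- vapply(seq_len(L), function(l) {
        logdmvnorm_chol(sweep(Gm, 2, M[, l]), cholL)
      }, numeric(S))
      logd <- matrix(logd, S, L) + matrix(log(pi_l), S, L, byrow = TRUE)
      mmax <- apply(logd, 1, max)
      lse <- mmax + log(rowSums(exp(logd - mmax)))
      ll <- sum(lse)
      resp <- exp(logd - lse)
      logl_trace <- c(logl_trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) <= tol * (1 + abs(ll))) break
      ll_prev <- ll
    }
    list(pi = pi_l, coef = coef, mean_curves = M, phi = phi, nu2 = nu2,
         resp = resp, logL = ll, logl_trace = logl_trace)
  }

  best <- NULL
  for (st in seq_len(n_starts)) {
    assign0 <- withr::with_seed(seed + st - 1, {
      if (L == 1) {
        rep(1L, S)
      } else {
        km <- tryCatch(
          stats::kmeans(Gm, centers = L, nstart = 3)$cluster,
          error = function(e) sample(rep_len(seq_len(L), S))
        )
        km
      }
    })
    fit <- run_one(assign0)
    if (is.null(best) || fit$logL > best$logL) best <- fit
    if (L == 1) break  # single-component fit is deterministic
  }

  d <- L * (order + 1) + 2 + (L - 1)
  structure(
    c(best,
      list(L = L, order = order, d = d,
           bic = -2 * best$logL + d * log(S),
           assignment = max.col(best$resp, ties.method = "first"),
           weeks = weeks, snp_ids = rownames(Gm))),
    class = "module_solution"
  )
}

#' @export
print.module_solution <- function(x, ...) {
  cat(sprintf("<module_solution> L = %d modules, S = %d curves, logL = %.3f, BIC = %.3f\n",
              x$L, nrow(x$resp), x$logL, x$bic))
  invisible(x)
}

#' @export
tidy.module_solution <- function(x, ...) {
  tibble(marker = x$snp_ids %||% as.character(seq_len(nrow(x$resp))),
         module = x$assignment,
         max_responsibility = apply(x$resp, 1, max))
}

#' @export
glance.module_solution <- function(x, ...) {
  tibble(L = x$L, logL = x$logL, bic = x$bic, d = x$d,
         phi = x$phi, nu2 = x$nu2)
}

#' Select the number of QTL modules by BIC
#'
#' Fits the mixture for every candidate module count and picks the BIC
#' minimiser (`BIC = -2 logL + d log S`, `d = L (order + 1) + 2 + (L - 1)`),
#' breaking ties toward the smaller count.
#'
#' @inheritParams em_fit
#' @param L_range Candidate module counts (values above S are dropped).
#' @return List with `best_L`, `best` (its `module_solution`), `table`
#'   (tibble `L`, `logL`, `bic`, `d`) and `solutions`.
#' @export
select_modules <- function(gsd, L_range = 1:6, order = 4, seed = 1,
                           n_starts = 10, max_iter = 500, tol = 1e-8,
                           weeks = NULL) {
  Gm <- gsd_matrix(gsd)
  L_range <- sort(unique(as.integer(L_range)))
  L_range <- L_range[L_range >= 1 & L_range <= nrow(Gm)]
  if (length(L_range) == 0) rlang::abort("empty L_range after bounding by S.")
  sols <- lapply(L_range, function(L) {
    em_fit(Gm, L, order = order, seed = seed, n_starts = n_starts,
           max_iter = max_iter, tol = tol, weeks = weeks)
  })
  tab <- purrr::map_dfr(sols, function(s) {
    tibble(L = s$L, logL = s$logL, bic = s$bic, d = s$d)
  })
  best_i <- which.min(tab$bic)   # first minimum = smallest L on ties
  list(best_L = tab$L[best_i], best = sols[[best_i]], table = tab,
       solutions = sols)
}

#' Per-module mean effect curves and memberships
#'
#' @param solution A `module_solution`.
#' @return List with `curves` (tibble `module`, `week`, `mean_effect`, `pi`,
#'   `n_members`) and `members` (tibble `module`, `marker`).
#' @export
module_effect_summary <- function(solution) {
  stopifnot(inherits(solution, "module_solution"))
  ids <- solution$snp_ids %||% as.character(seq_len(nrow(solution$resp)))
  members <- tibble(module = solution$assignment, marker = ids) |>
    dplyr::arrange(.data$module, .data$marker)
  counts <- tabulate(solution$assignment, nbins = solution$L)
  curves <- purrr::map_dfr(seq_len(solution$L), function(l) {
    tibble(module = l, week = solution$weeks,
           mean_effect = solution$mean_curves[, l],
           pi = solution$pi[l], n_members = counts[l])
  })
  list(curves = curves, members = members)
}

#' @export
autoplot.module_solution <- function(object, ...) {
  sm <- module_effect_summary(object)
  ggplot2::ggplot(sm$curves,
                  ggplot2::aes(x = .data$week, y = .data$mean_effect,
                               colour = factor(.data$module))) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "week", y = "mean genetic effect (GSD, leaves)",
                  colour = "module",
                  title = sprintf("%d QTL modules", object$L)) +
    ggplot2::theme_bw()
}

#' BIC profile plot for module selection
#'
#' @param selection Result of [select_modules()].
#' @return A ggplot.
#' @export
plot_bic <- function(selection) {
  ggplot2::ggplot(selection$table, ggplot2::aes(x = .data$L, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = selection$table[which.min(selection$table$bic), ],
                        colour = "red", size = 3) +
    ggplot2::labs(x = "number of modules L", y = "BIC") +
    ggplot2::theme_bw()
}

#' Export member SNPs of each module as BED
#'
#' Coordinates are 0-based, half-open; the score column carries the module
#' index.
#'
#' @param solution A `module_solution` fitted on curves from `scan`.
#' @param scan The `cofunmap_scan` providing SNP coordinates.
#' @param path Output BED path.
#' @return Invisibly, the exported tibble.
#' @export
write_module_bed <- function(solution, scan, path) {
  sm <- module_effect_summary(solution)
  d <- sm$members |>
    dplyr::inner_join(as_tibble(scan)[, c("marker", "chrom", "pos_bp")],
                      by = "marker") |>
    dplyr::mutate(start = .data$pos_bp - 1L, end = .data$pos_bp) |>
    dplyr::select("chrom", "start", "end", name = "marker",
                  score = "module")
  readr::write_tsv(d, path, col_names = FALSE)
  invisible(d)
}
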