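#' Logistic growth curve
#'
#' Evaluates the S-shaped leaf-number growth law `a / (1 + b * exp(-r * t))`,
#' where `a` is the asymptotic leaf number, `b` shapes the initial growth and
#' `r` is the specific growth rate per week.
#'
#' @param t Numeric vector of times (weeks).
#' @param a,b,r Positive logistic parameters.
#' @return Numeric vector of expected leaf numbers, same length as `t`.
#' @export
#' @examples
#' logistic_mean(0, 10, 9, 1)          # a / (1 + b) = 1
#' logistic_mean(log(9), 10, 9, 1)     # inflection: a / 2
logistic_mean <- function(t, a, b, r) {
  stopifnot(is.numeric(t), a > 0, b > 0, r > 0)
  a / (1 + b * exp(-r * t))
}

# Starting values for a logistic fit: asymptote from the series maximum,
# (b, r) from the log-linearised regression log(a0/y - 1) ~ t.
logistic_starts <- function(y, tt) {
  ymax <- max(y)
  a_grid <- ymax * c(1.02, 1.2, 1.6)
  starts <- list()
  for (a0 in a_grid) {
    frac <- pmin(pmax(y / a0, 1e-6), 1 - 1e-6)
    w <- log(1 / frac - 1)
    fit <- stats::lm(w ~ tt)
    b0 <- exp(coef(fit)[[1]])
    r0 <- -coef(fit)[[2]]
    if (!is.finite(b0) || b0 <= 0) b0 <- 1
    if (!is.finite(r0) || r0 <= 0) r0 <- 0.5
    starts[[length(starts) + 1]] <- c(a0, b0, r0)
  }
  starts[[length(starts) + 1]] <- c(ymax * 1.1, 1, 0.2)
  starts[[length(starts) + 1]] <- c(ymax * 1.1, 20, 1)
  starts
}

#' Fit a logistic growth curve by nonlinear least squares
#'
#' Minimises the residual sum of squares of [logistic_mean()] over the
#' trajectory. Positivity of `(a, b, r)` is enforced by optimising on the log
#' scale; several data-driven starting points guard against the multi-modal
#' objective of short series, and ties in RSS are broken toward the smallest
#' asymptote.
#'
#' @param y Numeric trajectory (one value per time point, `NA` allowed if at
#'   least three values remain).
#' @param tt Measurement times, strictly increasing, same length as `y`.
#' @return An object of class `logistic_fit`: list with `a`, `b`, `r`, `rss`,
#'   `fitted`, `converged`.
#' @export
#' @examples
#' tt <- 1:8
#' y <- logistic_mean(tt, 12, 5, 0.8)
#' fit_logistic(y, tt)$a
fit_logistic <- function(y, tt = seq_along(y)) {
  stopifnot(length(y) == length(tt), all(diff(tt) > 0))
  keep <- is.finite(y)
  if (sum(keep) < 3) {
    rlang::abort("fit_logistic() needs at least three observed values.")
  }
  yk <- y[keep]
  tk <- tt[keep]
  if (any(yk < 0)) rlang::abort("leaf numbers must be non-negative.")

  # log-parameterised RSS; lower clamp on log(b) keeps the flat-curve limit
  # (constant data) finite while effectively reaching b -> 0.
  obj <- function(p) {
    p <- pmin(pmax(p, -12), 12)
    mu <- exp(p[1]) / (1 + exp(p[2]) * exp(-exp(p[3]) * tk))
    sum((yk - mu)^2)
  }
  best <- NULL
  for (s in logistic_starts(yk, tk)) {
    p0 <- log(pmax(s, 1e-5))
    o <- tryCatch(
      stats::optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 600, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(o)) next
    o2 <- tryCatch(
      stats::optim(o$par, obj, method = "BFGS",
                   control = list(maxit = 300, reltol = 1e-14)),
      error = function(e) o
    )
    cand <- if (o2$value <= o$value) o2 else o
    if (is.null(best) ||
        cand$value < best$value - 1e-12 ||
        (abs(cand$value - best$value) <= 1e-12 && cand$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(
      list(a = NA_real_, b = NA_real_, r = NA_real_, rss = NA_real_,
           fitted = rep(NA_real_, length(tt)), converged = FALSE),
      class = "logistic_fit"
    ))
  }
  p <- pmin(pmax(best$par, -12), 12)
  a <- exp(p[1]); b <- exp(p[2]); r <- exp(p[3])
  structure(
    list(a = a, b = b, r = r, rss = best$value,
         fitted = logistic_mean(tt, a, b, r), converged = TRUE),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> a = %.4g, b = %.4g, r = %.4g (RSS %.3g)\n",
              x$a, x$b, x$r, x$rss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.logistic_fit <- function(x, ...) {
  tibble(term = c("a", "b", "r"), estimate = c(x$a, x$b, x$r))
}

#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged)
}

#' Fit the treatment-level mean growth curves
#'
#' Averages trajectories across RILs within each treatment panel and fits one
#' logistic curve per treatment, as done for the mean trajectories of the six
#' light treatments.
#'
#' @param panels Replicate-averaged panels in long form, as returned by
#'   [average_replicates()] (columns `treatment`, `ril_id`, `week`,
#'   `leaf_number`).
#' @return A tibble with one row per treatment: `treatment`, `a`, `b`, `r`,
#'   `rss`, `n_ril`.
#' @export
fit_treatment_mean_curves <- function(panels) {
  stopifnot(is.data.frame(panels))
  if (nrow(panels) == 0) rlang::abort("empty panel table.")
  panels |>
    dplyr::group_by(.data$treatment, .data$week) |>
    dplyr::summarise(leaf_number = mean(.data$leaf_number),
                     n_ril = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$treatment) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$week)
      f <- fit_logistic(d$leaf_number, d$week)
      tibble(a = f$a, b = f$b, r = f$r, rss = f$rss, n_ril = max(d$n_ril))
    }) |>
    dplyr::ungroup()
}
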