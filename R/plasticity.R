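#' Average replicates into per-RIL trajectory panels
#'
#' Computes the arithmetic mean leaf number over replicates for every
#' (RIL, treatment, week) cell, ignoring missing replicate values; the mean
#' across replicates is the trait value of the line in that treatment. A RIL
#' is dropped from a treatment panel if any week has no observed replicate.
#'
#' @param raw Long tibble with columns `ril_id`, `treatment`, `replicate`,
#'   `week`, `leaf_number`.
#' @param weeks Expected measurement weeks; defaults to the sorted unique
#'   weeks present.
#' @return A `trajectory_panels` tibble: `treatment`, `ril_id`, `week`,
#'   `leaf_number` (one row per RIL x week per treatment).
#' @export
average_replicates <- function(raw, weeks = NULL) {
  req <- c("ril_id", "treatment", "replicate", "week", "leaf_number")
  if (!all(req %in% names(raw))) {
    rlang::abort(paste("phenotype table must have columns:",
                       paste(req, collapse = ", ")))
  }
  if (!is.numeric(raw$week) || any(!is.finite(raw$week)) ||
      any(raw$week %% 1 != 0) || any(raw$week < 1)) {
    rlang::abort("week must be a positive integer index.")
  }
  weeks <- weeks %||% sort(unique(raw$week))
  if (!all(raw$week %in% weeks)) {
    rlang::abort("phenotype table contains weeks outside the configured grid.")
  }
  panels <- raw |>
    dplyr::group_by(.data$treatment, .data$ril_id, .data$week) |>
    dplyr::summarise(
      leaf_number = mean(.data$leaf_number, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(leaf_number = ifelse(is.nan(.data$leaf_number), NA_real_,
                                       .data$leaf_number))
  # drop RILs with an empty week anywhere in a panel
  complete <- panels |>
    dplyr::group_by(.data$treatment, .data$ril_id) |>
    dplyr::summarise(
      ok = sum(is.finite(.data$leaf_number)) == length(weeks),
      .groups = "drop"
    )
  out <- panels |>
    dplyr::inner_join(dplyr::filter(complete, .data$ok),
                      by = c("treatment", "ril_id")) |>
    dplyr::select(-"ok") |>
    dplyr::arrange(.data$treatment, .data$ril_id, .data$week)
  structure(out, class = c("trajectory_panels", class(out)),
            weeks = weeks)
}

# RIL x week matrix of one treatment panel (rows named by RIL id).
panel_matrix <- function(panels, treatment) {
  d <- panels[panels$treatment == treatment, , drop = FALSE]
  if (nrow(d) == 0) {
    rlang::abort(sprintf("treatment '%s' absent from panels.", treatment))
  }
  wide <- tidyr::pivot_wider(d, id_cols = "ril_id", names_from = "week",
                             values_from = "leaf_number")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$ril_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

#' Compute a time-course plasticity trait
#'
#' The plasticity of RIL i is the elementwise difference of its
#' replicate-averaged trajectories in two treatments,
#' `z_i = (x_i(t_1) - y_i(t_1), ..., x_i(t_T) - y_i(t_T))`, for the minuend
#' and subtrahend fixed by the named contrast (see
#' [plasticity_contrasts()]). Only RILs present in both panels are kept.
#'
#' @param panels A `trajectory_panels` tibble from [average_replicates()].
#' @param contrast One of `pWPP`, `oWPP_H`, `oWPP_L`, `TPP_H`, `TPP_L`,
#'   `MPP_H`, `MPP_L`.
#' @return A `plasticity_trait` tibble `ril_id`, `week`, `value`, with
#'   attributes `contrast`, `minuend`, `subtrahend`, `weeks`, and the grand
#'   mean trajectories `mean_x`, `mean_y` of the two source panels (used to
#'   initialise the likelihood fits).
#' @export
compute_plasticity <- function(panels, contrast) {
  tab <- plasticity_contrasts()
  row <- tab[tab$contrast == contrast, ]
  if (nrow(row) != 1) {
    rlang::abort(sprintf(
      "unknown contrast '%s'; expected one of %s.",
      contrast, paste(tab$contrast, collapse = ", ")))
  }
  X <- panel_matrix(panels, row$minuend)
  Y <- panel_matrix(panels, row$subtrahend)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 2) {
    rlang::abort("fewer than two RILs shared by the two treatment panels.")
  }
  Z <- X[shared, , drop = FALSE] - Y[shared, , drop = FALSE]
  weeks <- as.numeric(colnames(Z))
  out <- tibble(
    ril_id = rep(shared, each = length(weeks)),
    week = rep(weeks, times = length(shared)),
    value = as.vector(t(Z))
  )
  structure(out, class = c("plasticity_trait", class(out)),
            contrast = contrast, minuend = row$minuend,
            subtrahend = row$subtrahend, weeks = weeks,
            mean_x = colMeans(X[shared, , drop = FALSE]),
            mean_y = colMeans(Y[shared, , drop = FALSE]))
}

# RIL x week matrix of a plasticity trait.
trait_matrix <- function(trait) {
  wide <- tidyr::pivot_wider(as_tibble(trait), id_cols = "ril_id",
                             names_from = "week", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$ril_id
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

# Per-RIL asymptotic leaf number for one panel matrix: the fitted logistic
# asymptote, falling back to the final-week value when the fit fails.
ril_asymptotes <- function(M) {
  weeks <- as.numeric(colnames(M))
  vapply(seq_len(nrow(M)), function(i) {
    f <- tryCatch(fit_logistic(M[i, ], weeks), error = function(e) NULL)
    if (is.null(f) || !isTRUE(f$converged) || !is.finite(f$a)) {
      M[i, ncol(M)]
    } else {
      f$a
    }
  }, numeric(1))
}

#' Asymptotic leaf number per treatment (mean and SE across RILs)
#'
#' The asymptote of each RIL is the fitted logistic `a` (final-week value
#' when the fit fails); the standard error describes leaf-number variation
#' across RILs.
#'
#' @param panels A `trajectory_panels` tibble.
#' @return Tibble `treatment`, `mean`, `se`, `n_ril`, `n_fallback`.
#' @export
asymptotic_summary <- function(panels) {
  trs <- unique(panels$treatment)
  purrr::map_dfr(trs, function(tr) {
    M <- panel_matrix(panels, tr)
    weeks <- as.numeric(colnames(M))
    a <- numeric(nrow(M)); fb <- 0L
    for (i in seq_len(nrow(M))) {
      f <- tryCatch(fit_logistic(M[i, ], weeks), error = function(e) NULL)
      if (is.null(f) || !isTRUE(f$converged) || !is.finite(f$a)) {
        a[i] <- M[i, ncol(M)]; fb <- fb + 1L
      } else {
        a[i] <- f$a
      }
    }
    tibble(treatment = tr, mean = mean(a),
           se = stats::sd(a) / sqrt(length(a)),
           n_ril = length(a), n_fallback = fb)
  })
}

#' Test plasticity contrasts for significance
#'
#' For each contrast, the per-RIL asymptotic plasticity (difference of fitted
#' asymptotes between the two treatments, final-week difference as fallback)
#' is tested against zero with a two-sided one-sample t test; the requested
#' pairwise comparisons between contrasts use Welch two-sample t tests.
#' P values are Benjamini-Hochberg adjusted across the whole family, and
#' compact letters are derived from the adjusted pairwise matrix (contrasts
#' sharing a letter are not significantly different).
#'
#' @param panels A `trajectory_panels` tibble with the needed treatments.
#' @param contrasts Contrast names to summarise (default: all seven present).
#' @param comparisons List of length-2 character vectors of contrast names to
#'   compare pairwise; defaults to `oWPP_L` vs `oWPP_H`, `TPP_H` vs `TPP_L`,
#'   `MPP_H` vs `MPP_L` plus `pWPP` vs each offspring WPP when available.
#' @param alpha Significance level for the letter display.
#' @return List with `contrasts` (tibble: contrast, mean, se, n, p, p_adj,
#'   letter) and `pairwise` (tibble: contrast1, contrast2, p, p_adj),
#'   plus attribute `method`.
#' @export
test_contrasts <- function(panels, contrasts = NULL, comparisons = NULL,
                           alpha = 0.05) {
  tab <- plasticity_contrasts()
  have <- unique(panels$treatment)
  avail <- tab$contrast[tab$minuend %in% have & tab$subtrahend %in% have]
  contrasts <- contrasts %||% avail
  bad <- setdiff(contrasts, tab$contrast)
  if (length(bad)) rlang::abort(paste("unknown contrast:", bad[1]))

  vals <- lapply(contrasts, function(cn) {
    row <- tab[tab$contrast == cn, ]
    X <- panel_matrix(panels, row$minuend)
    Y <- panel_matrix(panels, row$subtrahend)
    shared <- intersect(rownames(X), rownames(Y))
    if (length(shared) < 2) rlang::abort("need >= 2 RILs per trait.")
    ril_asymptotes(X[shared, , drop = FALSE]) -
      ril_asymptotes(Y[shared, , drop = FALSE])
  })
  names(vals) <- contrasts

  one <- purrr::map_dfr(contrasts, function(cn) {
    v <- vals[[cn]]
    if (stats::sd(v) == 0) {
      p <- if (mean(v) == 0) 1 else 0
    } else {
      p <- stats::t.test(v)$p.value
    }
    tibble(contrast = cn, mean = mean(v),
           se = stats::sd(v) / sqrt(length(v)), n = length(v), p = p)
  })

  if (is.null(comparisons)) {
    cand <- list(c("oWPP_L", "oWPP_H"), c("TPP_H", "TPP_L"),
                 c("MPP_H", "MPP_L"), c("pWPP", "oWPP_H"),
                 c("pWPP", "oWPP_L"))
    comparisons <- Filter(function(p) all(p %in% contrasts), cand)
  }
  empty_pair <- tibble(contrast1 = character(), contrast2 = character(),
                       p = numeric(), p_adj = numeric())
  pair <- purrr::map_dfr(comparisons, function(cp) {
    v1 <- vals[[cp[1]]]; v2 <- vals[[cp[2]]]
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      p <- if (isTRUE(all.equal(mean(v1), mean(v2)))) 1 else 0
      if (p == 0) rlang::warn("zero-variance contrasts with unequal means.")
    } else if (length(v1) == length(v2) && isTRUE(all.equal(v1, v2))) {
      p <- 1
    } else {
      p <- stats::t.test(v1, v2, var.equal = FALSE)$p.value
    }
    tibble(contrast1 = cp[1], contrast2 = cp[2], p = p)
  })

  if (nrow(pair) == 0) pair <- empty_pair
  adj <- stats::p.adjust(c(one$p, pair$p), method = "BH")
  one$p_adj <- adj[seq_len(nrow(one))]
  if (nrow(pair)) pair$p_adj <- adj[-seq_len(nrow(one))]

  one$letter <- compact_letters(one$contrast, one$mean, pair, alpha)
  structure(list(contrasts = one, pairwise = pair),
            method = "one-sample and Welch two-sample t tests, BH-adjusted")
}

#' @export
autoplot.trajectory_panels <- function(object, ...) {
  means <- object |>
    dplyr::group_by(.data$treatment, .data$week) |>
    dplyr::summarise(leaf_number = mean(.data$leaf_number), .groups = "drop")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$week, y = .data$leaf_number,
                                       group = .data$ril_id)) +
    ggplot2::geom_line(alpha = 0.15, colour = "grey50") +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = NULL, colour = .data$treatment),
                       linewidth = 1.2) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "week", y = "leaf number") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.plasticity_trait <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$week, y = .data$value,
                                       group = .data$ril_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                          geom = "line", colour = "red", linewidth = 1.2) +
    ggplot2::labs(x = "week", y = "plasticity (leaves)",
                  title = attr(object, "contrast")) +
    ggplot2::theme_bw()
}

# Compact letter display by insert-and-absorb over a pairwise adjusted-P
# table; pairs never tested are treated as not significantly different.
compact_letters <- function(items, means, pairwise, alpha = 0.05) {
  k <- length(items)
  ord <- order(-means)
  sig <- matrix(FALSE, k, k, dimnames = list(items, items))
  if (nrow(pairwise)) {
    padj <- if ("p_adj" %in% names(pairwise)) pairwise$p_adj else pairwise$p
    for (i in seq_len(nrow(pairwise))) {
      a <- pairwise$contrast1[i]; b <- pairwise$contrast2[i]
      sig[a, b] <- sig[b, a] <- padj[i] < alpha
    }
  }
  groups <- list()  # each group: indices (in ord space) sharing a letter
  for (pos in seq_len(k)) {
    it <- ord[pos]
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (!any(sig[it, groups[[gi]]])) {
        groups[[gi]] <- c(groups[[gi]], it)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- it
  }
  # absorb redundant groups
  keep <- rep(TRUE, length(groups))
  for (gi in seq_along(groups)) {
    for (gj in seq_along(groups)) {
      if (gi != gj && keep[gj] && keep[gi] &&
          all(groups[[gi]] %in% groups[[gj]])) {
        keep[gi] <- FALSE
        break
      }
    }
  }
  groups <- groups[keep]
  letts <- rep("", k)
  for (gi in seq_along(groups)) {
    for (it in groups[[gi]]) {
      letts[it] <- paste0(letts[it], letters[gi])
    }
  }
  letts
}
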