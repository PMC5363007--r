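# ggplot2 views of fitted objects.

#' Mean-variance overview of a variability test
#'
#' Plots each family's mean log-RPKG against its residual variance, colored
#' by the call at a chosen FDR level; the expected null variance is drawn
#' as a reference band implied by the bootstrap ensemble.
#'
#' @param object a `ccoda_test`.
#' @param fdr which calibrated level's calls to color by (default 0.05).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ccoda_test <- function(object, fdr = 0.05, ...) {
  col <- sprintf("call_fdr%02d", round(fdr * 100))
  r <- object$results
  if (!col %in% names(r)) {
    abort(sprintf("no calls at FDR %g in this fit", fdr))
  }
  d <- tibble(
    mu = unname(object$fit$mu),
    V_eps = r$V_eps,
    null_mean = r$null_mean,
    call = factor(r[[col]], c("invariable", "non-significant", "variable"))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mu, y = .data$V_eps)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call),
                        size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_mean),
                       colour = "grey30", linewidth = 0.4,
                       stat = "smooth", method = "loess",
                       formula = y ~ x, se = FALSE) +
    ggplot2::scale_colour_manual(values = c(
      invariable = "#2166ac", `non-significant` = "grey60",
      variable = "#b2182b"
    ), drop = FALSE) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "mean log-RPKG", y = "residual variance",
                  colour = sprintf("call (FDR %g%%)", 100 * fdr)) +
    ggplot2::theme_minimal()
}

#' Null-ensemble diagnostic for selected families
#'
#' Histograms of the bootstrap null residual variances with the observed
#' statistic marked, for up to `n_max` families.
#'
#' @param object a `ccoda_test`.
#' @param families family IDs to show (default: first 6).
#' @param n_max cap on the number of panels.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_null_ensemble <- function(object, families = NULL, n_max = 6L, ...) {
  stopifnot(inherits(object, "ccoda_test"))
  ids <- families %||% utils::head(object$null$family_id, n_max)
  ids <- utils::head(intersect(ids, object$null$family_id), n_max)
  if (!length(ids)) abort("no matching families")
  idx <- match(ids, object$null$family_id)
  d <- purrr::map_dfr(seq_along(ids), function(i) {
    tibble(family_id = ids[[i]],
           V0 = object$null$stats[idx[[i]], ])
  })
  obs <- tibble(family_id = ids,
                V_eps = object$results$V_eps[match(ids, object$results$family_id)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$V0)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$V_eps),
                        colour = "#b2182b") +
    ggplot2::facet_wrap(~family_id, scales = "free") +
    ggplot2::labs(x = "null residual variance", y = "replicates") +
    ggplot2::theme_minimal()
}

#' Calibration-curve view of empirical-FDR cutoffs
#'
#' Shows the per-replicate calibrated cutoffs behind a
#' [calibrate_empirical_fdr()] table, split by direction and FDR level.
#'
#' @param cutoffs result of [calibrate_empirical_fdr()] (must carry its
#'   `"replicates"` attribute).
#' @return a ggplot.
#' @export
plot_calibration <- function(cutoffs) {
  reps <- attr(cutoffs, "replicates", exact = TRUE)
  if (is.null(reps)) abort("`cutoffs` lacks the per-replicate attribute")
  ggplot2::ggplot(reps, ggplot2::aes(x = factor(.data$ratio),
                                     y = .data$cutoff,
                                     colour = .data$direction)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(data = cutoffs,
                        ggplot2::aes(yintercept = .data$cutoff,
                                     colour = .data$direction),
                        linetype = 2) +
    ggplot2::facet_wrap(~fdr, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "variable : invariable ratio", y = "q-value cutoff") +
    ggplot2::theme_minimal()
}
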