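# Study-effect linear model on log-RPKG.
#
# For gene family g and sample s in study y:
#   D[g, s] = mu_g + beta[g, y] + eps[g, s]
# with mu_g the grand mean of the family across all samples and beta[g, y]
# the study-y mean minus mu_g, so residuals are obtained by subtracting
# per-study means. The test statistic is the residual variance V_eps of
# eps[g, ] pooled over all samples (denominator m - 1).

#' Fit the study-effect model to a log-RPKG table
#'
#' @param abund wide log-RPKG tibble or families x samples matrix.
#' @param design data frame with `sample_id`, `study_id` covering exactly the
#'   abundance samples; every study needs >= 2 samples.
#' @return an object of class `ccoda_fit` with elements `mu` (per-family
#'   grand mean), `beta` (families x studies offsets), `residuals`
#'   (families x samples), `V_eps` (per-family residual variance),
#'   `r_squared` (share of total variance removed by the gene and study
#'   means; a diagnostic), `design` and `study`.
#' @examples
#' m <- matrix(c(1, 3, 4, 6), 1, dimnames = list("g1", paste0("s", 1:4)))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 study_id = c("A", "A", "B", "B"))
#' fit <- fit_study_model(m, d)
#' fit$mu        # 3.5
#' fit$beta      # -1.5, 1.5
#' fit$residuals # -1, 1, -1, 1
#' @export
fit_study_model <- function(abund, design) {
  m <- abund_matrix(abund)
  if (ncol(m) < 2L) abort("need at least two samples")
  design <- check_design(design, colnames(m))
  study <- factor(design$study_id, levels = unique(design$study_id))
  mu <- rowMeans(m)
  eps <- m
  beta <- matrix(0, nrow(m), nlevels(study),
                 dimnames = list(rownames(m), levels(study)))
  for (y in levels(study)) {
    idx <- which(study == y)
    study_mean <- rowMeans(m[, idx, drop = FALSE])
    beta[, y] <- study_mean - mu
    eps[, idx] <- m[, idx, drop = FALSE] - study_mean
  }
  grand <- mean(m)
  ss_tot <- sum((m - grand)^2)
  ss_res <- sum(eps^2)
  structure(
    list(
      mu = mu,
      beta = beta,
      residuals = eps,
      V_eps = row_vars(eps),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
      design = design,
      study = study
    ),
    class = "ccoda_fit"
  )
}

#' @export
print.ccoda_fit <- function(x, ...) {
  cat(sprintf(
    "<ccoda_fit> %d families, %d samples, %d stud%s (R^2 = %.3f)\n",
    nrow(x$residuals), ncol(x$residuals), nlevels(x$study),
    if (nlevels(x$study) > 1L) "ies" else "y", x$r_squared
  ))
  invisible(x)
}

#' Residual variance per gene family
#'
#' Unbiased sample variance (denominator m - 1) of the fitted residuals of
#' each family, pooled across all samples. This is the variability statistic
#' compared against the parametric-bootstrap null.
#'
#' @param fit a `ccoda_fit` from [fit_study_model()].
#' @return named numeric vector of residual variances.
#' @export
residual_variance <- function(fit) {
  stopifnot(inherits(fit, "ccoda_fit"))
  if (ncol(fit$residuals) < 2L) abort("variance needs at least two samples")
  fit$V_eps
}

#' Scale residuals by their expected null standard deviation
#'
#' For visualization: divides each family's residuals by its mean root null
#' variance, `mean(sqrt(V0[g, b]))` over bootstrap replicates b, so that a
#' family behaving exactly as the negative-binomial null predicts has
#' scaled-residual variance near 1 regardless of its mean abundance.
#'
#' @param fit a `ccoda_fit`.
#' @param null a `ccoda_null` ensemble (see [null_statistics()]) computed
#'   for the same families.
#' @return wide tibble of scaled residuals (`value_kind = "residual"`);
#'   families whose expected null sd is zero are set to `NA` and reported in
#'   the `flagged` attribute.
#' @export
scale_residuals <- function(fit, null) {
  stopifnot(inherits(fit, "ccoda_fit"), inherits(null, "ccoda_null"))
  ids <- rownames(fit$residuals)
  if (!identical(ids, null$family_id)) {
    abort("null ensemble was computed for different families")
  }
  expected_sd <- null$mean_root
  flagged <- ids[expected_sd <= 0 | !is.finite(expected_sd)]
  scl <- fit$residuals / expected_sd
  scl[expected_sd <= 0 | !is.finite(expected_sd), ] <- NA_real_
  out <- abund_tbl(scl, kind = "residual")
  attr(out, "flagged") <- flagged
  out
}
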