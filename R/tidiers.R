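# broom-style accessors for fitted objects.

#' Tidy the per-family results of a variability test
#'
#' @param x a `ccoda_test`.
#' @param ... unused.
#' @return tibble with one row per family: `family_id`, `V_eps`,
#'   `null_mean`, `p`, `q`, `direction`, `call_fdr*` columns and `flag`.
#' @export
tidy.ccoda_test <- function(x, ...) {
  x$results
}

#' One-row summary of a variability test
#'
#' @param x a `ccoda_test`.
#' @param ... unused.
#' @return tibble: problem size, model R^2, pi0, per-study k_y range, and
#'   call counts at the 5% FDR level.
#' @export
glance.ccoda_test <- function(x, ...) {
  r <- x$results
  call05 <- r[["call_fdr05"]]
  tibble(
    n_families = nrow(r),
    n_samples = ncol(x$fit$residuals),
    n_studies = nlevels(x$fit$study),
    B = x$null$B,
    r_squared = x$fit$r_squared,
    pi0 = x$pi0,
    k_y_min = min(x$dispersion$k_y),
    k_y_max = max(x$dispersion$k_y),
    n_variable = if (is.null(call05)) NA_integer_ else sum(call05 == "variable"),
    n_invariable = if (is.null(call05)) NA_integer_ else sum(call05 == "invariable"),
    n_non_significant = if (is.null(call05)) NA_integer_ else sum(call05 == "non-significant")
  )
}

#' Tidy a study-effect model fit
#'
#' @param x a `ccoda_fit`.
#' @param ... unused.
#' @return tibble per family: grand mean `mu`, one `beta_*` column per
#'   study, and the residual variance `V_eps`.
#' @export
tidy.ccoda_fit <- function(x, ...) {
  beta <- tibble::as_tibble(as.data.frame(x$beta, check.names = FALSE))
  names(beta) <- paste0("beta_", names(beta))
  dplyr::bind_cols(
    tibble(family_id = rownames(x$residuals), mu = unname(x$mu)),
    beta,
    tibble(V_eps = unname(x$V_eps))
  )
}

#' @export
glance.ccoda_fit <- function(x, ...) {
  tibble(
    n_families = nrow(x$residuals),
    n_samples = ncol(x$residuals),
    n_studies = nlevels(x$study),
    r_squared = x$r_squared
  )
}

#' Tidy a dispersion model
#'
#' @param x a `ccoda_dispersion`.
#' @param ... unused.
#' @return long tibble per (family, study): count mean `mu`, per-gene
#'   method-of-moments `k_hat` (NA where undefined) and the study
#'   consensus `k_y` (NA until estimated).
#' @export
tidy.ccoda_dispersion <- function(x, ...) {
  ys <- colnames(x$mu_gy)
  purrr::map_dfr(ys, function(y) {
    tibble(
      family_id = rownames(x$mu_gy),
      study_id = y,
      mu = unname(x$mu_gy[, y]),
      k_hat = unname(x$k_gy[, y]),
      k_y = unname(x$k_y[[y]])
    )
  })
}
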