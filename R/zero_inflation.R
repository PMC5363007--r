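# Zero-inflation screening: are there more zero counts than a negative
# binomial predicts?

#' Zero-inflation test for one count vector
#'
#' Fits an intercept-only zero-inflated negative binomial and an ordinary
#' negative binomial to the counts and compares them with a likelihood-
#' ratio test on the inflation term (1 df; conservative because the null
#' puts the mixing weight on its boundary). Counts without any zeros get
#' p = 1 outright — there is nothing to inflate.
#'
#' @param counts non-negative integer vector (one family in one study).
#' @return one-row tibble: `n`, `n_zero`, `pi_hat` (estimated structural-
#'   zero fraction), `p`, `flag` (`"nonconvergence"` with `p = NA` when the
#'   fit fails).
#' @export
zero_inflation_test <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers")
  }
  n <- length(counts)
  nz <- sum(counts == 0)
  if (nz == 0L) {
    return(tibble(n = n, n_zero = 0L, pi_hat = 0, p = 1,
                  flag = NA_character_))
  }
  d <- data.frame(yy = counts)
  fits <- tryCatch({
    m1 <- suppressWarnings(glmmTMB::glmmTMB(
      yy ~ 1, ziformula = ~1, family = glmmTMB::nbinom2, data = d
    ))
    m0 <- suppressWarnings(glmmTMB::glmmTMB(
      yy ~ 1, family = glmmTMB::nbinom2, data = d
    ))
    list(m1 = m1, m0 = m0)
  }, error = function(e) NULL)
  if (is.null(fits)) {
    return(tibble(n = n, n_zero = nz, pi_hat = NA_real_, p = NA_real_,
                  flag = "nonconvergence"))
  }
  ll1 <- as.numeric(stats::logLik(fits$m1))
  ll0 <- as.numeric(stats::logLik(fits$m0))
  if (!is.finite(ll1) || !is.finite(ll0)) {
    return(tibble(n = n, n_zero = nz, pi_hat = NA_real_, p = NA_real_,
                  flag = "nonconvergence"))
  }
  lrt <- max(0, 2 * (ll1 - ll0))
  pi_hat <- stats::plogis(glmmTMB::fixef(fits$m1)$zi[[1L]])
  tibble(n = n, n_zero = nz, pi_hat = pi_hat,
         p = pchisq(lrt, df = 1L, lower.tail = FALSE),
         flag = NA_character_)
}

#' Zero-inflation screen over families and studies
#'
#' Runs [zero_inflation_test()] per family within each study and corrects
#' p-values per study with [storey_qvalues()] (families with failed fits
#' are excluded from the correction and keep `q = NA`).
#'
#' @param counts wide counts tibble or matrix.
#' @param design data frame with `sample_id`, `study_id`.
#' @param q_threshold threshold for the `inflated` flag (default 0.05).
#' @return tibble per (family, study): `n_zero`, `pi_hat`, `p`, `q`,
#'   `inflated`, `flag`.
#' @export
ccoda_zero_inflation <- function(counts, design, q_threshold = 0.05) {
  m <- abund_matrix(counts)
  design <- check_design(design, colnames(m))
  study <- factor(design$study_id, levels = unique(design$study_id))
  out <- purrr::map_dfr(levels(study), function(y) {
    idx <- which(study == y)
    rows <- purrr::map_dfr(seq_len(nrow(m)), function(g) {
      zero_inflation_test(m[g, idx])
    })
    rows <- tibble::add_column(rows, family_id = rownames(m), study_id = y,
                               .before = 1L)
    ok <- !is.na(rows$p)
    rows$q <- NA_real_
    if (any(ok)) rows$q[ok] <- as.numeric(storey_qvalues(rows$p[ok]))
    rows
  })
  out$inflated <- !is.na(out$q) & out$q <= q_threshold
  out
}
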