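# Negative-binomial dispersion estimation.
#
# The NB size parameter k is defined through var = mu + mu^2/k, i.e.
# k = mu^2 / (var - mu): small k means strong overdispersion, k -> Inf
# approaches Poisson. Each study is summarized by a single consensus size
# k_y, taken as the mode of the per-gene method-of-moments estimates — the
# mode is robust to the minority of genuinely (in)variable families that
# contaminate the per-gene estimates.

#' Per-gene, per-study method-of-moments dispersion estimates
#'
#' For each family x study cell with sample variance greater than the sample
#' mean, computes `k_hat = mean^2 / (var - mean)`; cells that are not
#' overdispersed (variance <= mean) are left `NA` — the estimator is
#' undefined there, not an error.
#'
#' @param counts wide counts tibble or matrix.
#' @param design data frame with `sample_id`, `study_id`.
#' @return an object of class `ccoda_dispersion`: list with `mu_gy` and
#'   `k_gy` (families x studies matrices), `design`, and (initially empty)
#'   `k_y`.
#' @export
estimate_gene_k <- function(counts, design) {
  m <- abund_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  design <- check_design(design, colnames(m))
  study <- factor(design$study_id, levels = unique(design$study_id))
  ys <- levels(study)
  mu_gy <- k_gy <- matrix(NA_real_, nrow(m), length(ys),
                          dimnames = list(rownames(m), ys))
  for (y in ys) {
    idx <- which(study == y)
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    v <- row_vars(sub)
    mu_gy[, y] <- mu
    over <- v > mu & mu > 0
    k_gy[over, y] <- mu[over]^2 / (v[over] - mu[over])
  }
  structure(
    list(mu_gy = mu_gy, k_gy = k_gy,
         k_y = setNames(rep(NA_real_, length(ys)), ys),
         design = design),
    class = "ccoda_dispersion"
  )
}

#' @export
print.ccoda_dispersion <- function(x, ...) {
  cat(sprintf("<ccoda_dispersion> %d families x %d studies\n",
              nrow(x$mu_gy), ncol(x$mu_gy)))
  if (any(is.finite(x$k_y))) {
    cat("  k_y:", paste(sprintf("%s = %.3g", names(x$k_y), x$k_y),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Consensus study-level dispersion
#'
#' Summarizes the defined per-gene estimates of one study into a single
#' size parameter. The default takes the mode of a Gaussian kernel density
#' estimate fitted to `log(k_hat)` (normal-reference bandwidth, 512 grid
#' points spanning the observed range padded by three bandwidths) and
#' exponentiates the arg-max. `"median"` and `"harmonic"` (harmonic mean)
#' are available for comparison; the mode is more robust when a sizeable
#' minority of families are truly more or less dispersed than the bulk.
#'
#' @param model a `ccoda_dispersion` from [estimate_gene_k()].
#' @param study study ID (default: all studies in the model).
#' @param estimator `"mode"`, `"median"` or `"harmonic"`.
#' @param min_genes minimum number of defined per-gene estimates required
#'   (default 30); below this the estimate is refused and the user should
#'   supply `k_y` directly.
#' @return named numeric vector of per-study consensus sizes `k_y`.
#' @export
estimate_study_k <- function(model, study = NULL,
                             estimator = c("mode", "median", "harmonic"),
                             min_genes = 30L) {
  stopifnot(inherits(model, "ccoda_dispersion"))
  estimator <- match.arg(estimator)
  ys <- study %||% colnames(model$k_gy)
  out <- setNames(numeric(length(ys)), ys)
  for (y in ys) {
    if (!y %in% colnames(model$k_gy)) abort(sprintf("unknown study '%s'", y))
    k <- model$k_gy[, y]
    k <- k[is.finite(k) & k > 0]
    if (length(k) < min_genes) {
      abort(sprintf(
        "study '%s' has only %d defined k estimates (< %d); supply k_y directly",
        y, length(k), min_genes
      ))
    }
    out[[y]] <- switch(estimator,
      mode = kde_mode(log(k)),
      median = median(k),
      harmonic = 1 / mean(1 / k)
    )
  }
  if (identical(estimator, "mode")) out <- exp(out)
  out
}

# Mode of a Gaussian KDE on the given values (log scale in our use).
# Degenerate all-equal input short-circuits to that value.
kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[[1L]])
  d <- density(x, bw = "nrd0", n = 512L, cut = 3)
  d$x[which.max(d$y)]
}
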