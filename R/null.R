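# Parametric-bootstrap null for the residual-variance statistic.
#
# Under the null every family in a study shares one NB size k_y; counts are
# drawn NB(mu_gy, k_y) with the observed per-study count means, then pushed
# through the identical normalization + study-model pipeline to give null
# residual variances V0[g, b] for b = 1..B.

#' Draw replicate count matrices under the negative-binomial null
#'
#' @param model a `ccoda_dispersion` whose `k_y` has been filled (via
#'   [estimate_study_k()] or supplied directly).
#' @param design data frame with `sample_id`, `study_id`; defines which k_y
#'   and mu_gy each sample uses.
#' @param B number of replicates.
#' @param seed optional integer seed.
#' @return list of `B` count matrices (families x samples).
#' @export
simulate_null_counts <- function(model, design, B, seed = NULL) {
  stopifnot(inherits(model, "ccoda_dispersion"))
  design <- check_design(design)
  study <- as.character(design$study_id)
  if (!all(study %in% colnames(model$mu_gy))) {
    abort("design contains studies absent from the dispersion model")
  }
  k_y <- model$k_y[unique(study)]
  if (any(!is.finite(k_y)) || any(k_y <= 0)) {
    abort("k_y must be positive and finite for every study (estimate or supply it)")
  }
  mu_mat <- model$mu_gy[, study, drop = FALSE]
  colnames(mu_mat) <- design$sample_id
  size_mat <- matrix(rep(model$k_y[study], each = nrow(mu_mat)),
                     nrow(mu_mat), length(study))
  with_seed(seed, {
    lapply(seq_len(B), function(b) {
      matrix(rnbinom(length(mu_mat), size = size_mat, mu = mu_mat),
             nrow(mu_mat), ncol(mu_mat), dimnames = dimnames(mu_mat))
    })
  })
}

#' Null ensemble of residual variances
#'
#' Pushes null count matrices through [counts_to_log_rpkg()],
#' [fit_study_model()] and [residual_variance()] — exactly the treatment of
#' the real data — and collects the per-family null statistics.
#'
#' @param null_counts list of count matrices from [simulate_null_counts()].
#' @param design study design data frame.
#' @param afl complete AFL table or single bp value (default 1000).
#' @param ge genome equivalents (named by sample) or single value.
#' @param pseudocount pseudocount used for the real data.
#' @return object of class `ccoda_null`: `family_id`, `stats` (families x B
#'   matrix of V0), `mean`, `sd`, `mean_root` (mean of sqrt(V0), the
#'   expected null sd used for residual scaling), `B`.
#' @export
null_statistics <- function(null_counts, design, afl = 1000, ge = 1,
                            pseudocount = 1) {
  if (!length(null_counts)) abort("need at least one null replicate")
  g <- nrow(null_counts[[1L]])
  stats <- matrix(NA_real_, g, length(null_counts),
                  dimnames = list(rownames(null_counts[[1L]]), NULL))
  for (b in seq_along(null_counts)) {
    d <- counts_to_log_rpkg(null_counts[[b]], afl = afl, ge = ge,
                            pseudocount = pseudocount)
    fit <- fit_study_model(d, design)
    stats[, b] <- fit$V_eps
  }
  new_ccoda_null(stats)
}

new_ccoda_null <- function(stats, adjusted = FALSE,
                           fallback = character(0)) {
  sqrt_mean <- rowMeans(sqrt(pmax(stats, 0)))
  structure(
    list(
      family_id = rownames(stats),
      stats = stats,
      mean = rowMeans(stats),
      sd = apply(stats, 1L, sd),
      mean_root = sqrt_mean,
      B = ncol(stats),
      adjusted = adjusted,
      fallback = fallback
    ),
    class = "ccoda_null"
  )
}

#' @export
print.ccoda_null <- function(x, ...) {
  cat(sprintf("<ccoda_null> %d families x B = %d replicates%s\n",
              length(x$family_id), x$B,
              if (isTRUE(x$adjusted)) " (cluster-bootstrap adjusted)" else ""))
  invisible(x)
}

# Fused generation + statistics path used by ccoda_test(): avoids holding
# B count matrices in memory at realistic problem sizes.
null_ensemble_fused <- function(model, design, B, afl, ge, pseudocount,
                                seed = NULL) {
  design <- check_design(design)
  study <- as.character(design$study_id)
  mu_mat <- model$mu_gy[, study, drop = FALSE]
  k_y <- model$k_y[unique(study)]
  if (any(!is.finite(k_y)) || any(k_y <= 0)) {
    abort("k_y must be positive and finite for every study")
  }
  g <- nrow(mu_mat)
  s <- ncol(mu_mat)
  size_vec <- rep(model$k_y[study], each = g)
  mu_vec <- as.vector(mu_mat)
  # per-cell normalization offset: log(AFL/1000) + log(GE)
  if (length(afl) == 1L && is.numeric(afl)) {
    afl_mat <- matrix(afl, g, s)
  } else {
    afl_mat <- abund_matrix(afl)[rownames(mu_mat), design$sample_id, drop = FALSE]
  }
  if (length(ge) == 1L && is.null(names(ge))) {
    ge_vec <- rep(ge, s)
  } else {
    ge_vec <- unname(ge[design$sample_id])
  }
  offset <- log(afl_mat / 1000) + rep(log(ge_vec), each = g)
  idx_by_study <- split(seq_len(s), factor(study, levels = unique(study)))
  stats <- matrix(NA_real_, g, B, dimnames = list(rownames(mu_mat), NULL))
  with_seed(seed, {
    for (b in seq_len(B)) {
      cnt <- rnbinom(g * s, size = size_vec, mu = mu_vec)
      d <- matrix(log(cnt + pseudocount), g, s) - offset
      for (idx in idx_by_study) {
        d[, idx] <- d[, idx, drop = FALSE] -
          rowMeans(d[, idx, drop = FALSE])
      }
      stats[, b] <- rowSums(d * d) / (s - 1L)
    }
  })
  new_ccoda_null(stats)
}

#' Cluster-bootstrap adjustment of the null ensemble
#'
#' The parametric null draws every family independently and so discards the
#' covariance between families (operons, genomes). This optional adjustment
#' resamples whole samples with replacement within each study (a cluster
#' bootstrap, preserving between-family covariance), recomputes the
#' residual-variance statistic on each resample, and centers/scales those
#' non-parametric statistics to the parametric null's per-family mean and
#' sd:
#' `V0' = (V' - mean(V')) / sd(V') * sd(V0) + mean(V0)`.
#'
#' @param null parametric `ccoda_null` ensemble.
#' @param abund the real log-RPKG table (wide tibble or matrix) the
#'   ensemble was built for.
#' @param design study design data frame.
#' @param B number of bootstrap resamples (default: same as the ensemble).
#' @param seed optional integer seed.
#' @return a `ccoda_null` whose `stats` are the adjusted statistics;
#'   families with degenerate bootstrap sd fall back to their parametric
#'   rows and are listed in `$fallback`.
#' @export
cluster_bootstrap_adjust <- function(null, abund, design, B = null$B,
                                     seed = NULL) {
  stopifnot(inherits(null, "ccoda_null"))
  m <- abund_matrix(abund)
  if (!identical(rownames(m), null$family_id)) {
    abort("abundance families do not match the null ensemble")
  }
  design <- check_design(design, colnames(m))
  study <- factor(design$study_id, levels = unique(design$study_id))
  idx_by_study <- split(seq_len(ncol(m)), study)
  boot <- matrix(NA_real_, nrow(m), B, dimnames = list(rownames(m), NULL))
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- unlist(lapply(idx_by_study, function(ix) {
        sample(ix, length(ix), replace = TRUE)
      }), use.names = FALSE)
      d <- m[, cols, drop = FALSE]
      pos <- 0L
      for (ix in idx_by_study) {
        sel <- pos + seq_along(ix)
        d[, sel] <- d[, sel, drop = FALSE] - rowMeans(d[, sel, drop = FALSE])
        pos <- pos + length(ix)
      }
      boot[, b] <- rowSums(d * d) / (ncol(m) - 1L)
    }
  })
  bmean <- rowMeans(boot)
  bsd <- apply(boot, 1L, sd)
  degenerate <- bsd <= 0 | !is.finite(bsd)
  adj <- (boot - bmean) / bsd * null$sd + null$mean
  if (any(degenerate)) {
    keep <- null$stats[degenerate, , drop = FALSE]
    if (ncol(keep) != B) {
      keep <- keep[, rep_len(seq_len(ncol(keep)), B), drop = FALSE]
    }
    adj[degenerate, ] <- keep
  }
  out <- new_ccoda_null(adj, adjusted = TRUE,
                        fallback = null$family_id[degenerate])
  out$mean_root <- null$mean_root  # residual scaling stays parametric
  out
}
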