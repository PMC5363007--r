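# The variability test proper: two-tailed bootstrap p-values, Storey
# q-values, and classification at empirically calibrated FDR cutoffs.

#' Two-tailed parametric-bootstrap p-values
#'
#' For each family g with observed residual variance V and null replicates
#' V0[b], the p-value counts null squared relative deviations from the null
#' mean at least as large as the observed one:
#' `p = ( #\{b : ((V0_b - m0)/m0)^2 >= ((V - m0)/m0)^2\} + 1 ) / (B + 1)`
#' with `m0 = mean(V0)`. Ties count as exceedances; the smallest attainable
#' p is `1/(B+1)`. Families whose null mean is zero have no usable null
#' scale: their p is set to 1 and they are flagged.
#'
#' @param V named numeric vector of observed residual variances (order must
#'   match the ensemble's families).
#' @param null a `ccoda_null` ensemble.
#' @return tibble with `family_id`, `V_eps`, `null_mean`, `p`, `flag`.
#' @export
pvalue_two_tailed <- function(V, null) {
  stopifnot(inherits(null, "ccoda_null"))
  if (length(V) != length(null$family_id)) {
    abort("V and null ensemble cover different numbers of families")
  }
  if (!is.null(names(V)) && !identical(names(V), null$family_id)) {
    abort("V names do not match the null ensemble families")
  }
  m0 <- unname(null$mean)
  bad <- m0 <= 0 | !is.finite(m0)
  obs_dev <- ((V - m0) / m0)^2
  null_dev <- ((null$stats - m0) / m0)^2
  exceed <- rowSums(null_dev >= obs_dev)
  p <- (exceed + 1) / (null$B + 1)
  p[bad] <- 1
  tibble(
    family_id = null$family_id,
    V_eps = unname(V),
    null_mean = m0,
    p = unname(p),
    flag = ifelse(unname(bad), "degenerate_null", NA_character_)
  )
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution and
#' converts p-values to q-values. The default `"smoother"` method computes
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over
#' `lambda = 0.05, 0.10, ..., 0.95`, fits a cubic smoothing spline (df = 3)
#' and takes its value at the largest lambda, clamped to (0, 1]. The
#' `"bootstrap"` method instead picks the lambda minimizing the bootstrap
#' mean squared error of pi0(lambda). Then
#' `q_i = pi0 * min_{j : p_j >= p_i} (m * p_j / rank_j)`, which is monotone
#' non-decreasing in p and never exceeds 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pi0_method `"smoother"` (default) or `"bootstrap"`.
#' @param lambda grid of candidate lambdas.
#' @return numeric vector of q-values, same length/order as `p`; the
#'   estimated pi0 is attached as attribute `"pi0"`.
#' @export
storey_qvalues <- function(p, pi0_method = c("smoother", "bootstrap"),
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_method <- match.arg(pi0_method)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  m <- length(p)
  pi0_hat <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  if (length(unique(p)) == 1L || m < 2L) {
    pi0 <- min(max(pi0_hat), 1)
  } else if (pi0_method == "smoother") {
    pi0 <- tryCatch({
      fit <- suppressWarnings(smooth.spline(lambda, pi0_hat, df = 3))
      predict(fit, x = max(lambda))$y
    }, error = function(e) min(pi0_hat))
    pi0 <- min(max(pi0, 0), 1)
  } else {
    min_pi0 <- quantile(pi0_hat, 0.1, names = FALSE)
    mse <- vapply(seq_along(lambda), function(i) {
      w <- sum(p > lambda[i])
      # binomial plug-in MSE of pi0(lambda) about the low quantile
      (w / (m^2 * (1 - lambda[i])^2)) * (1 - w / m) +
        (pi0_hat[i] - min_pi0)^2
    }, numeric(1))
    pi0 <- min(max(pi0_hat[which.min(mse)], 0), 1)
  }
  if (pi0 <= 0) pi0 <- 1 / m  # all p tiny: keep q positive and ordered
  o <- order(p, decreasing = TRUE)
  r <- rank(p, ties.method = "max")
  q <- pi0 * m * p / r
  q[o] <- cummin(q[o])
  q <- pmin(q, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Default empirical-FDR q-value cutoffs
#'
#' The direction-specific q-value cutoffs calibrated by labeled simulation
#' (see [calibrate_empirical_fdr()]): the test's realized false discovery
#' rate differs between the variable and invariable directions, so each
#' direction gets its own cutoff per nominal FDR level.
#'
#' @return tibble with columns `fdr`, `direction`, `cutoff`.
#' @export
ccoda_cutoffs <- function() {
  tibble(
    fdr = rep(c(0.05, 0.10, 0.25), each = 2L),
    direction = rep(c("variable", "invariable"), times = 3L),
    cutoff = c(0.0238, 0.108, 0.0669, 0.180, 0.181, 0.294)
  )
}

#' Classify families at calibrated FDR levels
#'
#' Direction is `"variable"` when the observed residual variance exceeds the
#' family's null mean and `"invariable"` otherwise. At each FDR level a
#' family is called in its direction iff its q-value is at or below that
#' direction's cutoff; otherwise it is `"non-significant"`.
#'
#' @param results tibble with `family_id`, `V_eps`, `null_mean`, `p`, `q`
#'   (e.g. [pvalue_two_tailed()] output plus a `q` column).
#' @param cutoffs cutoff table as from [ccoda_cutoffs()] or
#'   [calibrate_empirical_fdr()].
#' @return `results` with `direction` and one `call_fdr<level>` column per
#'   FDR level (values `"variable"`, `"invariable"` or `"non-significant"`).
#' @export
classify_families <- function(results, cutoffs = ccoda_cutoffs()) {
  need <- c("family_id", "V_eps", "null_mean", "q")
  miss <- setdiff(need, names(results))
  if (length(miss) > 0L) {
    abort(sprintf("`results` is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!all(c("fdr", "direction", "cutoff") %in% names(cutoffs))) {
    abort("`cutoffs` must have columns fdr, direction, cutoff")
  }
  out <- tibble::as_tibble(results)
  out$direction <- ifelse(out$V_eps > out$null_mean, "variable", "invariable")
  for (lev in sort(unique(cutoffs$fdr))) {
    sub <- cutoffs[cutoffs$fdr == lev, ]
    cut_for <- setNames(sub$cutoff, sub$direction)
    if (!all(c("variable", "invariable") %in% names(cut_for))) {
      abort(sprintf("cutoff table lacks both directions at FDR %g", lev))
    }
    called <- out$q <= unname(cut_for[out$direction])
    col <- sprintf("call_fdr%02d", round(lev * 100))
    out[[col]] <- ifelse(called, out$direction, "non-significant")
  }
  out
}

#' Covariate-corrected dispersion analysis of a count table
#'
#' The full test: normalizes counts to log-RPKG, removes per-study means
#' with the study-effect model, measures each family's residual variance,
#' builds a negative-binomial parametric-bootstrap null with per-study
#' dispersion (mode of per-gene method-of-moments estimates, unless `k` is
#' supplied), and reports two-tailed bootstrap p-values, Storey q-values
#' and direction-specific calls at calibrated FDR levels.
#'
#' @param counts wide counts tibble (`family_id` + one column per sample)
#'   or matrix.
#' @param design data frame with `sample_id`, `study_id`; if `total_reads`,
#'   `read_length` and `ags` columns are present, genome equivalents are
#'   computed from them, otherwise a `ge` column or 1 is used.
#' @param afl complete AFL table (bp) or single value; default 1000 treats
#'   every family as 1 kb.
#' @param pseudocount pseudocount added before normalization (default 1).
#' @param B number of parametric-bootstrap replicates (default 750).
#' @param k optional named vector of per-study NB sizes; when supplied the
#'   per-study estimation step is skipped (e.g. in simulations with known
#'   dispersion, or phylum-restricted tests reusing full-data estimates).
#' @param mu optional per-family count means for the null generator: a
#'   families x studies matrix, or a vector (one mean per family) recycled
#'   across studies. Default: per-study means of the observed raw counts.
#'   Supplying the generating means (together with `k`) gives the oracle
#'   null used when evaluating the test on simulated data with known
#'   parameters; conditioning on data-estimated means is slightly
#'   conservative for low-abundance families.
#' @param k_estimator consensus estimator for k_y: `"mode"` (default),
#'   `"median"` or `"harmonic"`.
#' @param cluster_bootstrap if `TRUE`, adjust the null with the
#'   within-study cluster bootstrap (see [cluster_bootstrap_adjust()]).
#' @param cutoffs FDR cutoff table (default [ccoda_cutoffs()]).
#' @param pi0_method pi0 estimator for [storey_qvalues()].
#' @param min_k_genes floor on defined per-gene k estimates per study.
#' @param seed optional integer seed making the whole run reproducible.
#' @return object of class `ccoda_test`; use [tidy()] for the per-family
#'   result table, [glance()] for a one-row summary, and [autoplot()] for a
#'   mean-variance overview.
#' @examples
#' sim <- simulate_dataset(ccoda_sim_config(
#'   genes = 60, n_total = 30, prop_true_pos = 0.2, seed = 1
#' ))
#' res <- ccoda_test(sim$counts, sim$design, B = 50, seed = 2)
#' tidy(res)
#' glance(res)
#' @export
ccoda_test <- function(counts, design, afl = 1000, pseudocount = 1,
                       B = 750, k = NULL, mu = NULL,
                       k_estimator = c("mode", "median", "harmonic"),
                       cluster_bootstrap = FALSE,
                       cutoffs = ccoda_cutoffs(),
                       pi0_method = c("smoother", "bootstrap"),
                       min_k_genes = 30L, seed = NULL) {
  k_estimator <- match.arg(k_estimator)
  pi0_method <- match.arg(pi0_method)
  m <- abund_matrix(counts)
  design <- check_design(design, colnames(m))
  ge <- if (all(c("total_reads", "read_length", "ags") %in% names(design))) {
    genome_equivalents(design)
  } else if ("ge" %in% names(design)) {
    setNames(design$ge, design$sample_id)
  } else {
    setNames(rep(1, nrow(design)), design$sample_id)
  }
  if (!identical(afl, 1000) && is.data.frame(afl)) afl <- impute_afl(afl)

  logr <- counts_to_log_rpkg(m, afl = afl, ge = ge, pseudocount = pseudocount)
  fit <- fit_study_model(logr, design)
  V <- residual_variance(fit)

  disp <- estimate_gene_k(m, design)
  if (is.null(k)) {
    disp$k_y <- estimate_study_k(disp, estimator = k_estimator,
                                 min_genes = min_k_genes)
  } else {
    ys <- colnames(disp$mu_gy)
    if (is.null(names(k))) {
      if (length(k) != length(ys)) {
        abort("unnamed `k` must have one value per study")
      }
      names(k) <- ys
    }
    miss <- setdiff(ys, names(k))
    if (length(miss) > 0L) {
      abort(sprintf("`k` missing stud%s: %s",
                    if (length(miss) > 1L) "ies" else "y",
                    paste(miss, collapse = ", ")))
    }
    disp$k_y <- k[ys]
  }
  if (!is.null(mu)) {
    if (is.matrix(mu)) {
      if (!identical(dim(mu), dim(disp$mu_gy))) {
        abort("`mu` matrix must be families x studies")
      }
      disp$mu_gy[] <- mu
    } else {
      if (length(mu) != nrow(disp$mu_gy)) {
        abort("`mu` vector must have one mean per family")
      }
      disp$mu_gy[] <- mu
    }
  }

  null <- null_ensemble_fused(disp, design, B = B, afl = afl, ge = ge,
                              pseudocount = pseudocount,
                              seed = if (is.null(seed)) NULL else seed)
  null_param <- null
  if (isTRUE(cluster_bootstrap)) {
    null <- cluster_bootstrap_adjust(
      null, logr, design, B = B,
      seed = if (is.null(seed)) NULL else seed + 1L
    )
  }

  res <- pvalue_two_tailed(V, null)
  q <- storey_qvalues(res$p, pi0_method = pi0_method)
  res$q <- as.numeric(q)
  res <- classify_families(res, cutoffs = cutoffs)

  structure(
    list(
      results = res,
      fit = fit,
      dispersion = disp,
      null = null,
      null_parametric = null_param,
      pi0 = attr(q, "pi0"),
      params = list(pseudocount = pseudocount, B = B,
                    k_estimator = if (is.null(k)) k_estimator else "supplied",
                    cluster_bootstrap = cluster_bootstrap, seed = seed),
      cutoffs = cutoffs
    ),
    class = "ccoda_test"
  )
}

#' @export
print.ccoda_test <- function(x, ...) {
  r <- x$results
  call05 <- grep("^call_fdr05$", names(r), value = TRUE)
  cat(sprintf(
    "<ccoda_test> %d families, %d samples, %d stud%s, B = %d\n",
    nrow(r), ncol(x$fit$residuals), nlevels(x$fit$study),
    if (nlevels(x$fit$study) > 1L) "ies" else "y", x$null$B
  ))
  cat(sprintf("  k_y (%s): %s\n", x$params$k_estimator,
              paste(sprintf("%s = %.3g", names(x$dispersion$k_y),
                            x$dispersion$k_y), collapse = ", ")))
  cat(sprintf("  pi0 = %.3f\n", x$pi0))
  if (length(call05) == 1L) {
    tab <- table(factor(r[[call05]],
                        c("invariable", "non-significant", "variable")))
    cat(sprintf("  calls at 5%% FDR: %d invariable / %d non-significant / %d variable\n",
                tab[[1L]], tab[[2L]], tab[[3L]]))
  }
  invisible(x)
}
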