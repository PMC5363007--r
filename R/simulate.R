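# Simulation framework: multi-study negative-binomial datasets with known
# (in)variable families, power / type-I-error evaluation, and empirical FDR
# calibration of q-value cutoffs.
#
# Study conditions: three studies; per-study size k_y ~ lognormal(meanlog
# -0.65, sdlog 0.57); per-family means ~ lognormal(meanlog 2.94, sdlog
# 2.23); a "variable" true positive divides k_y by the effect size z (more
# overdispersed), an "invariable" one multiplies it by z.

#' Simulation configuration
#'
#' @param n_studies number of studies (default 3).
#' @param genes number of gene families shared across studies (default
#'   1000).
#' @param n_total total samples, split equally across studies (default
#'   120).
#' @param k_logmean,k_logsd lognormal parameters of the per-study size k_y
#'   (defaults -0.65, 0.57).
#' @param mean_logmean,mean_logsd lognormal parameters of per-family count
#'   means (defaults 2.94, 2.23).
#' @param effect_size multiplier z > 1 applied to k for true positives
#'   (default 4).
#' @param prop_true_pos fraction of families that are true positives
#'   (default 0).
#' @param var_invar_ratio ratio of variable to invariable true positives
#'   (default 1).
#' @param seed optional integer seed.
#' @return a `ccoda_sim_config` list.
#' @export
ccoda_sim_config <- function(n_studies = 3L, genes = 1000L, n_total = 120L,
                             k_logmean = -0.65, k_logsd = 0.57,
                             mean_logmean = 2.94, mean_logsd = 2.23,
                             effect_size = 4, prop_true_pos = 0,
                             var_invar_ratio = 1, seed = NULL) {
  if (effect_size <= 1) abort("`effect_size` z must be > 1")
  if (prop_true_pos < 0 || prop_true_pos >= 1) {
    abort("`prop_true_pos` must be in [0, 1)")
  }
  if (var_invar_ratio <= 0) abort("`var_invar_ratio` must be > 0")
  if (n_total < 2L * n_studies) abort("need >= 2 samples per study")
  structure(
    list(n_studies = as.integer(n_studies), genes = as.integer(genes),
         n_total = as.integer(n_total), k_logmean = k_logmean,
         k_logsd = k_logsd, mean_logmean = mean_logmean,
         mean_logsd = mean_logsd, effect_size = effect_size,
         prop_true_pos = prop_true_pos, var_invar_ratio = var_invar_ratio,
         seed = seed),
    class = "ccoda_sim_config"
  )
}

#' Simulate a labeled multi-study count dataset
#'
#' Null families draw counts NB(mean_g, k_y); variable true positives use
#' size k_y / z (larger variance given the mean) and invariable ones
#' k_y * z. Family means are shared across studies; each study has its own
#' k_y.
#'
#' @param cfg a [ccoda_sim_config()].
#' @return list of class `ccoda_sim`: `counts` (wide tibble), `design`
#'   (tibble `sample_id`, `study_id`), `labels` (tibble `family_id`,
#'   `label` in null/variable/invariable), `k_y` (true per-study sizes),
#'   `means` (true per-family means), `config`.
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "ccoda_sim_config"))
  with_seed(cfg$seed, {
    per_study <- rep(cfg$n_total %/% cfg$n_studies, cfg$n_studies)
    extra <- cfg$n_total - sum(per_study)
    if (extra > 0L) per_study[seq_len(extra)] <- per_study[seq_len(extra)] + 1L
    studies <- sprintf("study%d", seq_len(cfg$n_studies))
    design <- tibble(
      sample_id = sprintf("s%03d", seq_len(cfg$n_total)),
      study_id = rep(studies, times = per_study)
    )
    k_y <- setNames(rlnorm(cfg$n_studies, cfg$k_logmean, cfg$k_logsd),
                    studies)
    means <- setNames(rlnorm(cfg$genes, cfg$mean_logmean, cfg$mean_logsd),
                      sprintf("g%04d", seq_len(cfg$genes)))

    n_tp <- round(cfg$genes * cfg$prop_true_pos)
    n_var <- round(n_tp * cfg$var_invar_ratio / (1 + cfg$var_invar_ratio))
    n_invar <- n_tp - n_var
    label <- rep("null", cfg$genes)
    if (n_tp > 0L) {
      tp_idx <- sample.int(cfg$genes, n_tp)
      label[tp_idx[seq_len(n_var)]] <- "variable"
      if (n_invar > 0L) {
        label[tp_idx[n_var + seq_len(n_invar)]] <- "invariable"
      }
    }
    size_mult <- c(null = 1, variable = 1 / cfg$effect_size,
                   invariable = cfg$effect_size)[label]

    counts <- matrix(0L, cfg$genes, cfg$n_total,
                     dimnames = list(names(means), design$sample_id))
    for (y in seq_len(cfg$n_studies)) {
      idx <- which(design$study_id == studies[y])
      size_g <- k_y[[y]] * size_mult
      counts[, idx] <- rnbinom(
        cfg$genes * length(idx),
        size = rep(size_g, times = length(idx)),
        mu = rep(means, times = length(idx))
      )
    }
    structure(
      list(
        counts = abund_tbl(counts, kind = "counts"),
        design = design,
        labels = tibble(family_id = names(means), label = label),
        k_y = k_y,
        means = means,
        config = cfg
      ),
      class = "ccoda_sim"
    )
  })
}

#' @export
print.ccoda_sim <- function(x, ...) {
  cat(sprintf(
    "<ccoda_sim> %d families x %d samples in %d studies (%d variable, %d invariable true positives)\n",
    nrow(x$labels), nrow(x$design), length(x$k_y),
    sum(x$labels$label == "variable"), sum(x$labels$label == "invariable")
  ))
  invisible(x)
}

#' Type-I error and power against known simulation labels
#'
#' @param sim a `ccoda_sim` (for its labels) or a labels tibble with
#'   `family_id`, `label`.
#' @param results per-family result tibble with `family_id`, `p` (e.g.
#'   `tidy()` of a [ccoda_test()]).
#' @param p_cut p-value threshold (default 0.05).
#' @return tibble with rows overall/variable/invariable: `alpha` (fraction
#'   of true-null families with p <= p_cut), `power` (fraction of that
#'   class of true positives with p <= p_cut), and the counts involved.
#'   `alpha` is only defined on the overall row; with no null families it
#'   is `NA`.
#' @export
evaluate_error_rates <- function(sim, results, p_cut = 0.05) {
  labels <- if (inherits(sim, "ccoda_sim")) sim$labels else tibble::as_tibble(sim)
  stopifnot(all(c("family_id", "label") %in% names(labels)),
            all(c("family_id", "p") %in% names(results)))
  d <- dplyr::inner_join(labels, results[, c("family_id", "p")],
                         by = "family_id")
  if (nrow(d) != nrow(labels)) {
    abort("results do not cover all labeled families")
  }
  sig <- d$p <= p_cut
  null_idx <- d$label == "null"
  rate <- function(idx) if (any(idx)) mean(sig[idx]) else NA_real_
  tibble(
    class = c("overall", "variable", "invariable"),
    alpha = c(rate(null_idx), NA_real_, NA_real_),
    power = c(rate(!null_idx), rate(d$label == "variable"),
              rate(d$label == "invariable")),
    n_null = c(sum(null_idx), NA_integer_, NA_integer_),
    n_true_pos = c(sum(!null_idx), sum(d$label == "variable"),
                   sum(d$label == "invariable"))
  )
}

#' Calibrate empirical-FDR q-value cutoffs by labeled simulation
#'
#' Simulates datasets with a fixed fraction of true positives over a grid
#' of variable:invariable ratios, runs the full test on each, and — per
#' direction and per target FDR level — finds the largest q-value cutoff
#' whose realized false discovery rate among same-direction calls stays at
#' or below the target (step search over the observed q-values, no
#' interpolation). The reported cutoff is the median over the ratio grid
#' (replicates pooled); replicates where no cutoff attains the target are
#' dropped from the median with a warning.
#'
#' @param fdr_levels target FDR levels (default 0.05, 0.10, 0.25).
#' @param ratios grid of variable:invariable true-positive ratios.
#' @param reps replicate simulations per ratio (default 1).
#' @param n_total,genes,prop_true_pos,effect_size simulation conditions
#'   passed to [ccoda_sim_config()] (defaults: 120 samples, 1000 families,
#'   43% true positives, z = 4).
#' @param B parametric-bootstrap replicates per test run.
#' @param k_estimator consensus dispersion estimator (default `"mode"`).
#' @param seed integer seed; each simulated dataset and test gets a
#'   deterministic sub-seed.
#' @return cutoff tibble (`fdr`, `direction`, `cutoff`) usable in
#'   [ccoda_test()]/[classify_families()]; the per-replicate cutoffs are
#'   attached as attribute `"replicates"` and the effect size as `"z"`.
#' @export
calibrate_empirical_fdr <- function(fdr_levels = c(0.05, 0.10, 0.25),
                                    ratios = c(0.1, 0.2, 0.5, 1, 2, 5, 10),
                                    reps = 1L, n_total = 120L, genes = 1000L,
                                    prop_true_pos = 0.43, effect_size = 4,
                                    B = 200L,
                                    k_estimator = c("mode", "median",
                                                    "harmonic"),
                                    seed = NULL) {
  k_estimator <- match.arg(k_estimator)
  grid <- expand.grid(ratio = ratios, rep = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE)
  per_rep <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sub_seed <- if (is.null(seed)) NULL else (seed + 101L * i) %% .Machine$integer.max
    cfg <- ccoda_sim_config(
      genes = genes, n_total = n_total, prop_true_pos = prop_true_pos,
      effect_size = effect_size, var_invar_ratio = grid$ratio[[i]],
      seed = sub_seed
    )
    sim <- simulate_dataset(cfg)
    res <- ccoda_test(sim$counts, sim$design, B = B,
                      k_estimator = k_estimator,
                      seed = if (is.null(sub_seed)) NULL else sub_seed + 1L)
    d <- dplyr::inner_join(res$results[, c("family_id", "q", "direction")],
                           sim$labels, by = "family_id")
    per_rep[[i]] <- purrr::map_dfr(fdr_levels, function(lev) {
      purrr::map_dfr(c("variable", "invariable"), function(dir) {
        tibble(ratio = grid$ratio[[i]], rep = grid$rep[[i]], fdr = lev,
               direction = dir,
               cutoff = largest_q_cutoff(d$q[d$direction == dir],
                                         d$label[d$direction == dir] == dir,
                                         lev))
      })
    })
  }
  all_reps <- dplyr::bind_rows(per_rep)
  if (anyNA(all_reps$cutoff)) {
    warn(sprintf(
      "%d replicate/level combinations had no cutoff attaining the target FDR; dropped from the median",
      sum(is.na(all_reps$cutoff))
    ))
  }
  out <- all_reps |>
    dplyr::group_by(.data$fdr, .data$direction) |>
    dplyr::summarise(cutoff = median(.data$cutoff, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(.data$fdr, dplyr::desc(.data$direction))
  attr(out, "replicates") <- all_reps
  attr(out, "z") <- effect_size
  out
}

# Largest q with realized FDR <= target, stepping over observed q values of
# the families called in one direction. `true_pos` flags which of those
# families genuinely belong to the direction.
largest_q_cutoff <- function(q, true_pos, target) {
  if (length(q) == 0L) return(NA_real_)
  o <- order(q)
  q <- q[o]
  fp <- cumsum(!true_pos[o])
  fdr <- fp / seq_along(q)
  # realized FDR at cutoff q[i] must use all calls with q <= q[i]: for tied
  # q values only the last position counts
  last_of_tie <- c(q[-1L] != q[-length(q)], TRUE)
  ok <- fdr <= target & last_of_tie
  if (!any(ok)) return(NA_real_)
  max(q[ok])
}
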