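# Normalization of raw gene-family counts to log-RPKG:
# reads per kilobase of genome equivalents, on the natural-log scale after a
# pseudocount. Corrects for two confounders: average family length (AFL, bp)
# and sequencing effort in genome units (genome equivalents, derived from
# total reads, read length and average genome size).

#' Impute missing average family lengths
#'
#' When a family has no mapped reads in a sample there is no AFL for that
#' cell; missing entries are filled with the arithmetic mean of the family's
#' observed AFL values across samples. Observed entries are never altered.
#'
#' @param afl wide AFL tibble (`family_id` + one bp column per sample) or a
#'   families x samples matrix; `NA` marks missing.
#' @param default optional global fallback (bp) for families with no observed
#'   AFL in any sample; without it such families are an error.
#' @return a complete AFL table in the same wide-tibble form.
#' @export
impute_afl <- function(afl, default = NULL) {
  m <- abund_matrix(afl)
  if (any(m[!is.na(m)] <= 0)) abort("observed AFL entries must be positive")
  means <- rowMeans(m, na.rm = TRUE)
  none <- !is.finite(means)
  if (any(none)) {
    if (is.null(default)) {
      abort(sprintf(
        "famil%s with no observed AFL in any sample (supply `default`): %s",
        if (sum(none) > 1L) "ies" else "y",
        paste(utils::head(rownames(m)[none], 5L), collapse = ", ")
      ))
    }
    if (default <= 0) abort("`default` AFL must be positive")
    means[none] <- default
  }
  idx <- which(is.na(m))
  m[idx] <- means[row(m)[idx]]
  abund_tbl(m, kind = "afl")
}

#' Genome equivalents per sample
#'
#' The sequencing effort of a sample expressed in genomes:
#' `GE = total_reads * read_length / ags`, where `ags` is the average genome
#' size (bp) of the community. Dividing counts by GE gives abundances per
#' genome rather than per read.
#'
#' @param info data frame with columns `sample_id`, `total_reads`,
#'   `read_length`, `ags` (all strictly positive).
#' @return a named numeric vector of genome equivalents, one per sample.
#' @examples
#' genome_equivalents(data.frame(
#'   sample_id = "s1", total_reads = 1.5e7, read_length = 90, ags = 4.5e6
#' )) # 300 genome equivalents
#' @export
genome_equivalents <- function(info) {
  need <- c("sample_id", "total_reads", "read_length", "ags")
  miss <- setdiff(need, names(info))
  if (length(miss) > 0L) {
    abort(sprintf("`info` is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  for (col in need[-1L]) {
    v <- info[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("`%s` must be strictly positive and finite", col))
    }
  }
  setNames(info$total_reads * info$read_length / info$ags,
           as.character(info$sample_id))
}

#' Normalize counts to log-RPKG
#'
#' Adds a pseudocount to the raw counts, divides by family length in kb and
#' by the sample's genome equivalents, and takes the natural log:
#' `log_rpkg = ln( ((count + pseudocount) / (AFL/1000)) / GE )`.
#'
#' @param counts wide counts tibble or matrix (families x samples).
#' @param afl complete AFL table (same families and samples as `counts`);
#'   see [impute_afl()]. A single number is recycled to all cells.
#' @param ge genome equivalents: named vector (by sample) or single number.
#' @param pseudocount count added to every cell before normalization
#'   (default 1); must be > 0 so zeros stay finite after the log.
#' @return wide tibble of log-RPKG values (`value_kind = "log_rpkg"`).
#' @export
counts_to_log_rpkg <- function(counts, afl = 1000, ge = 1, pseudocount = 1) {
  m <- abund_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  if (length(afl) == 1L && is.numeric(afl)) {
    aflm <- matrix(afl, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    aflm <- abund_matrix(afl)
    aflm <- aflm[rownames(m), colnames(m), drop = FALSE]
  }
  if (anyNA(aflm)) abort("AFL table has missing entries; run impute_afl() first")
  if (any(aflm <= 0)) abort("AFL entries must be strictly positive")
  if (length(ge) == 1L && is.null(names(ge))) {
    gev <- rep(ge, ncol(m))
  } else {
    if (is.null(names(ge)) || !all(colnames(m) %in% names(ge))) {
      abort("`ge` must be named by sample and cover every sample")
    }
    gev <- unname(ge[colnames(m)])
  }
  if (any(gev <= 0)) abort("genome equivalents must be positive")
  out <- log(((m + pseudocount) / (aflm / 1000)) / rep(gev, each = nrow(m)))
  res <- abund_tbl(out, kind = "log_rpkg")
  attr(res, "pseudocount") <- pseudocount
  attr(res, "genome_equivalents") <- setNames(gev, colnames(m))
  res
}

#' Normalize by the median abundance of single-copy marker families
#'
#' Used by phylum-restricted tests, where a whole-metagenome average genome
#' size is not meaningful: each sample's column is divided by that sample's
#' median abundance over a set of universal single-copy marker gene
#' families. Input should already be AFL-corrected.
#'
#' @param counts wide abundance tibble or matrix (AFL-corrected counts).
#' @param marker_ids character vector of marker family IDs (must be rows of
#'   `counts`).
#' @return wide tibble of marker-normalized abundances (`value_kind =
#'   "rpkg"`).
#' @export
marker_normalize <- function(counts, marker_ids) {
  m <- abund_matrix(counts)
  marker_ids <- as.character(marker_ids)
  miss <- setdiff(marker_ids, rownames(m))
  if (length(miss) > 0L) {
    abort(sprintf("marker famil%s not in table: %s",
                  if (length(miss) > 1L) "ies" else "y",
                  paste(utils::head(miss, 5L), collapse = ", ")))
  }
  med <- apply(m[marker_ids, , drop = FALSE], 2L, median)
  zero <- med <= 0
  if (any(zero)) {
    abort(sprintf("sample(s) with zero median marker abundance: %s",
                  paste(colnames(m)[zero], collapse = ", ")))
  }
  abund_tbl(sweep(m, 2L, med, "/"), kind = "rpkg")
}

#' Rarefy count columns to a common depth
#'
#' Subsamples each sample's counts without replacement (multivariate
#' hypergeometric) so that every column sums exactly to `depth`, equalizing
#' sequencing effort across samples.
#'
#' @param counts wide counts tibble or matrix.
#' @param depth target column total; every sample must have at least this
#'   many reads.
#' @param seed optional integer seed for reproducibility.
#' @return wide counts tibble with all column sums equal to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL) {
  m <- abund_matrix(counts)
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  tot <- colSums(m)
  if (any(tot < depth)) {
    abort(sprintf("sample(s) shallower than depth %g: %s", depth,
                  paste(colnames(m)[tot < depth], collapse = ", ")))
  }
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      if (tot[j] == depth) next
      m[, j] <- rmvhyper(m[, j], depth)
    }
  })
  abund_tbl(m, kind = "counts")
}

# One multivariate-hypergeometric draw: sequential conditional rhyper.
rmvhyper <- function(x, k) {
  out <- numeric(length(x))
  remaining <- sum(x)
  for (i in seq_along(x)) {
    if (k <= 0) break
    if (remaining == x[i]) { out[i] <- k; k <- 0; break }
    d <- rhyper(1L, x[i], remaining - x[i], k)
    out[i] <- d
    k <- k - d
    remaining <- remaining - x[i]
  }
  out
}
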