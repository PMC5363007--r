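# Readers and writers for the tab-separated inputs and outputs.
#
# All tables are TSV, UTF-8, header required, "NA" for missing values.
# Row and column order is always taken from the file, never sorted: the
# bootstrap is seeded per position, so reordering would silently change
# downstream replicate streams.

#' Read a gene-family by sample abundance table
#'
#' Reads a TSV whose header row holds sample IDs and whose first column holds
#' gene-family IDs (e.g. KEGG Orthology accessions). The result is a wide
#' tibble with a `family_id` column followed by one numeric column per
#' sample, carrying a `value_kind` attribute.
#'
#' @param path path to a TSV file.
#' @param kind what the values are: `"counts"` (non-negative integers),
#'   `"rpkg"`, `"log_rpkg"` or `"residual"`.
#' @return a wide abundance tibble; row/column order preserved from the file.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("family_id\ts1\ts2", "K00001\t3\t0", "K00002\t1\t9"), tf)
#' read_abundance_table(tf, kind = "counts")
#' @export
read_abundance_table <- function(path,
                                 kind = c("counts", "rpkg", "log_rpkg",
                                          "residual")) {
  kind <- match.arg(kind)
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, na = "NA"))
  if (ncol(x) < 2L) abort(sprintf("'%s': expected family IDs plus samples", path))
  names(x)[1L] <- "family_id"
  x$family_id <- as.character(x$family_id)
  check_no_duplicates(x$family_id, "family")
  check_no_duplicates(names(x)[-1L], "sample")
  m <- as.matrix(x[, -1L, drop = FALSE])
  bad <- which(is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "'%s': non-numeric or missing cell at family '%s', sample '%s'",
      path, x$family_id[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]
    ))
  }
  if (kind == "counts") {
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L) {
      abort(sprintf(
        "'%s': negative count at family '%s', sample '%s'",
        path, x$family_id[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]
      ))
    }
    if (any(m != round(m))) {
      abort(sprintf("'%s': counts mode requires integer values", path))
    }
  }
  attr(x, "value_kind") <- kind
  x
}

#' Read per-sample study design and sequencing metadata
#'
#' Expects a TSV with columns `sample_id`, `study_id`, `total_reads`,
#' `read_length` and `ags` (average genome size in bp, e.g. from
#' MicrobeCensus).
#'
#' @param path path to a TSV file.
#' @return a tibble with one row per sample. Errors if any sample appears
#'   twice, any study has a single sample, or a required column is absent.
#' @export
read_study_design <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                       na = "NA")
  need <- c("sample_id", "study_id", "total_reads", "read_length", "ags")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    abort(sprintf("'%s': missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  x <- check_design(x)
  for (col in c("total_reads", "read_length", "ags")) {
    v <- x[[col]]
    if (any(!is.finite(v)) || any(v <= 0)) {
      abort(sprintf("'%s': column %s must be strictly positive", path, col))
    }
  }
  x
}

#' Read an average-family-length (AFL) table
#'
#' Same layout as [read_abundance_table()] but entries may be missing
#' (`NA`), e.g. when a family received no reads in a sample. Present entries
#' must be strictly positive (bp).
#'
#' @param path path to a TSV file.
#' @return a wide tibble (`family_id` + one column per sample) with possible
#'   `NA` entries.
#' @export
read_afl_table <- function(path) {
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, na = "NA"))
  names(x)[1L] <- "family_id"
  x$family_id <- as.character(x$family_id)
  check_no_duplicates(x$family_id, "family")
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (any(m[!is.na(m)] <= 0)) {
    abort(sprintf("'%s': present AFL entries must be strictly positive", path))
  }
  attr(x, "value_kind") <- "afl"
  x
}

#' Read a forest of gene-family trees from a tagged newick file
#'
#' Each line holds a gene-family ID, a tab, and one newick string. Branch
#' lengths are required on every edge; trees without them are rejected.
#'
#' @param path path to the tagged newick file.
#' @return a named list of `phylo` objects (names are family IDs).
#' @export
read_newick_forest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) {
      abort(sprintf("%s line %d: expected '<family_id>\\t<newick>'", path, i))
    }
    tr <- tryCatch(ape::read.tree(text = parts[[2L]]),
                   error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo")) {
      abort(sprintf("%s line %d: malformed newick", path, i))
    }
    if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
        anyNA(tr$edge.length)) {
      abort(sprintf("%s line %d: newick is missing branch lengths", path, i))
    }
    ids[[i]] <- parts[[1L]]
    out[[i]] <- tr
  }
  check_no_duplicates(ids, "family")
  names(out) <- ids
  out
}

#' Write the per-family variability test results to TSV
#'
#' Columns: `family_id`, `V_eps`, `p`, `q`, `direction`, then one
#' `call_fdr*` column per calibrated FDR level. Row order follows the input
#' family order.
#'
#' @param results a result tibble, e.g. `tidy()` of a [ccoda_test()] fit.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  keep <- c("family_id", "V_eps", "p", "q", "direction",
            grep("^call_fdr", names(results), value = TRUE))
  keep <- intersect(keep, names(results))
  readr::write_tsv(results[, keep, drop = FALSE], path, na = "NA")
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#' @param path path to the results TSV.
#' @return a tibble.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    family_id = readr::col_character(),
    direction = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE, na = "NA")
}
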