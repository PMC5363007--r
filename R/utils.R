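# Internal representation helpers.
#
# User-facing abundance tables are wide tibbles: first column `family_id`,
# remaining columns one per sample, with a "value_kind" attribute in
# {"counts", "rpkg", "log_rpkg", "residual"}. Numerical internals work on
# plain matrices (families x samples) with dimnames.

#' Convert a wide abundance tibble (or matrix) to a families x samples matrix
#'
#' @param x wide tibble with a `family_id` first column, or a numeric matrix
#'   with rownames (family IDs) and colnames (sample IDs).
#' @return numeric matrix with family IDs as rownames and sample IDs as
#'   colnames.
#' @keywords internal
#' @noRd
abund_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("abundance matrix must have family rownames and sample colnames")
    }
    storage.mode(x) <- "double"
    return(x)
  }
  if (!is.data.frame(x)) {
    abort("abundance table must be a data frame or a matrix")
  }
  if (ncol(x) < 2L) {
    abort("abundance table needs a family_id column plus at least one sample")
  }
  ids <- as.character(x[[1L]])
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("abundance values must be numeric")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Wrap a matrix back into the wide-tibble abundance representation
#' @keywords internal
#' @noRd
abund_tbl <- function(m, kind = NULL) {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble::add_column(out, family_id = rownames(m), .before = 1L)
  if (!is.null(kind)) attr(out, "value_kind") <- kind
  out
}

#' @keywords internal
#' @noRd
value_kind <- function(x, default = NULL) {
  attr(x, "value_kind", exact = TRUE) %||% default
}

check_no_duplicates <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    abort(sprintf(
      "duplicate %s ID(s): %s", what,
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Validate a study design tibble against a set of sample IDs
#'
#' @return the design, with `study_id` as character, rows ordered to match
#'   `sample_ids` when given.
#' @keywords internal
#' @noRd
check_design <- function(design, sample_ids = NULL, min_per_study = 2L) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "study_id") %in% names(design))) {
    abort("design must be a data frame with columns sample_id and study_id")
  }
  design <- tibble::as_tibble(design)
  design$sample_id <- as.character(design$sample_id)
  design$study_id <- as.character(design$study_id)
  check_no_duplicates(design$sample_id, "sample")
  tab <- table(design$study_id)
  if (length(tab) < 1L) abort("design must contain at least one study")
  small <- names(tab)[tab < min_per_study]
  if (length(small) > 0L) {
    abort(sprintf(
      "stud%s with fewer than %d samples (variance is undefined): %s",
      if (length(small) > 1L) "ies" else "y", min_per_study,
      paste(small, collapse = ", ")
    ))
  }
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, design$sample_id)
    extra <- setdiff(design$sample_id, sample_ids)
    if (length(missing) > 0L || length(extra) > 0L) {
      abort(sprintf(
        "design and abundance samples disagree (%d missing from design, %d extra)",
        length(missing), length(extra)
      ))
    }
    design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  }
  design
}

#' Per-sample study factor, in abundance column order
#' @keywords internal
#' @noRd
study_factor <- function(design, sample_ids) {
  design <- check_design(design, sample_ids)
  factor(design$study_id, levels = unique(design$study_id))
}

#' Deterministic per-call RNG scope
#'
#' Seeds the session RNG when `seed` is non-NULL and restores the previous
#' RNG state on exit, so seeded calls do not perturb the caller's stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Row variances with denominator m - 1
#' @keywords internal
#' @noRd
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}
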