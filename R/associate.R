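# Downstream association statistics: compositional clr transform, partial
# Kendall's tau with study nuisance terms, within-study permutation tests,
# and Fisher-exact gene-set enrichment.

#' Centered log-ratio transform of a composition table
#'
#' Each sample (row) is mapped to `ln((x + pseudo) / g(x + pseudo))` where
#' `g` is the row's geometric mean, so each transformed row sums to zero.
#' Removes the unit-sum constraint that induces spurious correlations among
#' relative abundances.
#'
#' @param taxa samples x taxa data frame (first column may be a sample ID)
#'   or numeric matrix of non-negative relative abundances.
#' @param pseudo offset preventing log of zero (default 1e-6).
#' @return tibble of the same shape with clr-transformed values.
#' @export
clr_transform <- function(taxa, pseudo = 1e-6) {
  id <- NULL
  if (is.data.frame(taxa) && !is.numeric(taxa[[1L]])) {
    id <- taxa[[1L]]
    taxa <- taxa[, -1L, drop = FALSE]
  }
  m <- as.matrix(taxa)
  if (!is.numeric(m)) abort("abundances must be numeric")
  if (any(m < 0)) abort("abundances must be non-negative")
  if (pseudo < 0) abort("`pseudo` must be >= 0")
  lx <- log(m + pseudo)
  out <- lx - rowMeans(lx)
  out <- tibble::as_tibble(as.data.frame(out, check.names = FALSE))
  if (!is.null(id)) out <- tibble::add_column(out, sample_id = id, .before = 1L)
  out
}

#' Partial Kendall's tau given study nuisance indicators
#'
#' Tie-corrected (tau-b) Kendall correlation between `x` and `y`, partialing
#' out the study structure: the pairwise tau-b matrix of `(x, y, nuisance
#' columns)` is inverted and the partial correlation read off as
#' `-R^{-1}[1,2] / sqrt(R^{-1}[1,1] * R^{-1}[2,2])`. Studies are coded as
#' binary indicator columns (one study dropped as reference). With a single
#' study this reduces to plain Kendall's tau-b.
#'
#' @param x,y numeric vectors, one value per sample.
#' @param design optional data frame with `sample_id`, `study_id` (rows in
#'   the order of `x`), or a factor/character vector of study labels;
#'   `NULL` means no nuisance terms.
#' @return the partial tau (scalar in `[-1, 1]`).
#' @export
partial_kendall_tau <- function(x, y, design = NULL) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 samples")
  nuis <- nuisance_matrix(design, length(x))
  if (is.null(nuis) || ncol(nuis) == 0L) {
    return(cor(x, y, method = "kendall"))
  }
  dat <- cbind(x = x, y = y, nuis)
  r <- suppressWarnings(cor(dat, method = "kendall"))
  if (anyNA(r)) {
    # a constant column (e.g. constant covariate) has no defined tau
    return(NA_real_)
  }
  inv <- tryCatch(solve(r), error = function(e) {
    abort("singular Kendall correlation matrix; drop collinear nuisance columns")
  })
  pt <- -inv[1L, 2L] / sqrt(inv[1L, 1L] * inv[2L, 2L])
  max(-1, min(1, pt))
}

# Study labels -> indicator matrix with the first study as reference.
nuisance_matrix <- function(design, n) {
  if (is.null(design)) return(NULL)
  s <- if (is.data.frame(design)) design$study_id else design
  if (length(s) != n) abort("design rows must match the number of samples")
  f <- factor(s, levels = unique(as.character(s)))
  if (nlevels(f) < 2L) return(NULL)
  stats::model.matrix(~ f)[, -1L, drop = FALSE]
}

#' Within-study permutation test of a partial-tau association
#'
#' Tests association between per-sample values `x` (e.g. one family's
#' residual log-RPKG) and a covariate `y`, controlling study structure both
#' in the statistic (nuisance indicators in the partial tau) and in the
#' null (the covariate is permuted only within studies). The p-value is
#' `(#\{|tau'| >= |tau|\} + 1) / (P + 1)`.
#'
#' @param x,y numeric vectors, one value per sample.
#' @param design data frame with `sample_id`, `study_id` in sample order
#'   (or a study label vector).
#' @param P number of permutations (default 250).
#' @param seed optional integer seed.
#' @return one-row tibble: `partial_tau`, `P`, `p`, `flag` (set when the
#'   covariate is constant within every study, where tau is undefined and p
#'   is 1).
#' @export
permutation_association_test <- function(x, y, design, P = 250L,
                                         seed = NULL) {
  if (P < 1L) abort("`P` must be >= 1")
  s <- if (is.data.frame(design)) design$study_id else design
  f <- factor(s, levels = unique(as.character(s)))
  idx_by_study <- split(seq_along(x), f)
  constant <- all(vapply(idx_by_study,
                         function(ix) length(unique(y[ix])) == 1L,
                         logical(1)))
  if (constant) {
    return(tibble(partial_tau = NA_real_, P = as.integer(P), p = 1,
                  flag = "constant_covariate"))
  }
  tau <- partial_kendall_tau(x, y, design)
  if (is.na(tau)) {
    return(tibble(partial_tau = NA_real_, P = as.integer(P), p = 1,
                  flag = "undefined_tau"))
  }
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(P)) {
      yp <- y
      for (ix in idx_by_study) yp[ix] <- y[ix][sample.int(length(ix))]
      tp <- partial_kendall_tau(x, yp, design)
      if (!is.na(tp) && abs(tp) >= abs(tau)) cnt <- cnt + 1L
    }
    cnt
  })
  tibble(partial_tau = tau, P = as.integer(P),
         p = (exceed + 1) / (P + 1), flag = NA_character_)
}

#' Association screen of many families against covariates
#'
#' Runs [permutation_association_test()] for every (family, covariate)
#' pair and corrects p-values per covariate with [storey_qvalues()].
#'
#' @param abund wide tibble or matrix of per-family per-sample values
#'   (typically residual log-RPKG).
#' @param covariates data frame: `sample_id` plus one numeric column per
#'   covariate, rows covering the abundance samples.
#' @param design data frame with `sample_id`, `study_id`.
#' @param P permutations per test (default 250).
#' @param q_threshold significance threshold on q (default 0.05).
#' @param seed optional integer seed.
#' @return tibble with one row per (family, covariate): `partial_tau`,
#'   `p`, `q`, `significant`, `flag`.
#' @export
ccoda_associate <- function(abund, covariates, design, P = 250L,
                            q_threshold = 0.05, seed = NULL) {
  m <- abund_matrix(abund)
  if (!"sample_id" %in% names(covariates)) {
    abort("`covariates` needs a sample_id column")
  }
  design <- check_design(design, colnames(m))
  cov <- covariates[match(colnames(m), covariates$sample_id), , drop = FALSE]
  if (anyNA(cov$sample_id)) abort("covariates must cover every sample")
  cov_names <- setdiff(names(cov), "sample_id")
  out <- vector("list", length(cov_names))
  for (j in seq_along(cov_names)) {
    yv <- cov[[cov_names[[j]]]]
    rows <- purrr::map_dfr(seq_len(nrow(m)), function(g) {
      permutation_association_test(
        m[g, ], yv, design, P = P,
        seed = if (is.null(seed)) NULL else seed + 7919L * j + g
      )
    })
    rows <- tibble::add_column(rows, family_id = rownames(m),
                               covariate = cov_names[[j]], .before = 1L)
    rows$q <- as.numeric(storey_qvalues(rows$p))
    out[[j]] <- rows
  }
  res <- dplyr::bind_rows(out)
  res$significant <- res$q <= q_threshold & is.na(res$flag)
  res
}

#' Fisher-exact enrichment of a gene set in annotation categories
#'
#' For each pathway/module, a two-tailed Fisher exact test on the 2x2 table
#' of membership in the gene set versus membership in the pathway, over the
#' background universe intersected with annotated families. Pathways with
#' no overlap with the universe are excluded. Enrichments are summarized at
#' `q <= q_threshold` with odds ratio > 1.
#'
#' @param gene_set character vector of family IDs (subset of `universe`).
#' @param annotation named list: pathway/module ID -> character vector of
#'   member family IDs.
#' @param universe character vector of background family IDs (e.g. all
#'   families observed in the data); it is intersected with the union of
#'   annotated families to form the effective background.
#' @param q_threshold threshold used for the `enriched` flag (default
#'   0.25).
#' @return tibble per pathway: 2x2 counts, `odds_ratio`, `p`, `q`,
#'   `enriched`.
#' @export
fisher_enrichment <- function(gene_set, annotation, universe,
                              q_threshold = 0.25) {
  if (length(universe) == 0L) abort("`universe` must be non-empty")
  if (!all(gene_set %in% universe)) {
    abort("`gene_set` must be a subset of `universe`")
  }
  background <- intersect(universe, unique(unlist(annotation)))
  if (length(background) == 0L) {
    abort("no annotated families intersect the universe")
  }
  gs <- intersect(gene_set, background)
  rows <- purrr::imap_dfr(annotation, function(members, pw) {
    pw_in <- intersect(members, background)
    if (length(pw_in) == 0L) return(NULL)
    a <- length(intersect(gs, pw_in))
    b <- length(gs) - a
    cc <- length(pw_in) - a
    d <- length(background) - a - b - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), 2L), alternative = "two.sided")
    tibble(pathway = pw, in_set_in_pathway = a, in_set_out = b,
           out_set_in_pathway = cc, out_set_out = d,
           odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  if (nrow(rows) == 0L) abort("no pathway overlaps the background universe")
  rows$q <- as.numeric(storey_qvalues(rows$p))
  rows$enriched <- rows$q <= q_threshold & rows$odds_ratio > 1
  rows
}

#' Seeded subsampling of family IDs for annotation-bias checks
#'
#' Draws equal-sized subsamples from several family-ID pools (e.g.
#' phylum-private families of each phylum plus families shared by all), so
#' enrichment comparisons are not confounded by pool size.
#'
#' @param pools named list of character vectors of family IDs.
#' @param size number drawn from each pool (default: size of the smallest
#'   pool).
#' @param seed optional integer seed.
#' @return named list of subsampled ID vectors.
#' @export
subsample_family_sets <- function(pools, size = NULL, seed = NULL) {
  if (!length(pools)) abort("`pools` must be non-empty")
  size <- size %||% min(lengths(pools))
  if (any(lengths(pools) < size)) {
    abort("every pool must have at least `size` families")
  }
  with_seed(seed, lapply(pools, function(ids) sample(ids, size)))
}
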