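# Phylogenetic-distribution (PD) scoring of gene-family trees.
#
# Tree density = sum of all edge lengths / mean root-to-tip height. Unlike
# raw tree height or leaf counts, density corrects for the rate of
# evolution: a slow-evolving but broadly distributed family still scores
# high, while rampant within-species duplication does not inflate it.

#' Tree density of one gene-family tree
#'
#' Unrooted inputs are midpoint-rooted first (tip height needs a root).
#' Requires at least `min_leaves` leaves (by default 5 representatives, the
#' floor below which a computed PD is considered unreliable) and a positive
#' mean tip height.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param min_leaves minimum number of leaves (default 5; use 2 for the
#'   bare geometric minimum).
#' @return one-row tibble: `n_leaves`, `sum_branch_lengths`,
#'   `mean_tip_height`, `tree_density`, `predicted = FALSE`.
#' @examples
#' star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
#' tree_density(star)$tree_density # 5: one effective lineage per leaf
#' @export
tree_density <- function(tree, min_leaves = 5L) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree must have branch lengths on every edge")
  }
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  n_leaves <- length(tree$tip.label)
  if (n_leaves < max(2L, min_leaves)) {
    abort(sprintf("tree has %d leaves; need at least %d", n_leaves,
                  max(2L, min_leaves)))
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  heights <- ape::node.depth.edgelength(tree)[seq_len(n_leaves)]
  mth <- mean(heights)
  if (mth <= 0) abort("degenerate tree: mean tip height is zero")
  tibble(
    n_leaves = n_leaves,
    sum_branch_lengths = sum(tree$edge.length),
    mean_tip_height = mth,
    tree_density = sum(tree$edge.length) / mth,
    predicted = FALSE
  )
}

#' Tree densities for a forest
#'
#' @param forest named list of `phylo` objects, e.g. from
#'   [read_newick_forest()].
#' @param min_leaves minimum leaves per computed density (default 5);
#'   smaller trees are skipped with `NA` density.
#' @return tibble with one row per family.
#' @export
forest_density <- function(forest, min_leaves = 5L) {
  purrr::imap_dfr(forest, function(tr, id) {
    row <- tryCatch(tree_density(tr, min_leaves = min_leaves),
                    error = function(e) {
                      tibble(n_leaves = length(tr$tip.label),
                             sum_branch_lengths = NA_real_,
                             mean_tip_height = NA_real_,
                             tree_density = NA_real_,
                             predicted = FALSE)
                    })
    tibble::add_column(row, family_id = id, .before = 1L)
  })
}

#' Extrapolate tree density from annotation counts
#'
#' For families with too few sequenced representatives to compute a tree
#' density, predicts it from the total number of annotations via a
#' least-squares fit of `log(density)` on `log(annotations)` (both span
#' orders of magnitude). Reports 5-fold cross-validated mean absolute
#' percentage error (MAPE) of the training fit.
#'
#' @param train data frame with columns `n_annotations` and `tree_density`
#'   (computed densities; >= 10 rows required).
#' @param query numeric vector of annotation counts to predict for (> 0).
#' @param folds cross-validation folds for the MAPE estimate (default 5).
#' @param seed optional seed for the fold assignment.
#' @return tibble: `n_annotations`, `tree_density` (predicted),
#'   `predicted = TRUE`; the CV MAPE (percent) is attached as attribute
#'   `"mape"` and the fitted model as `"model"`.
#' @export
predict_pd <- function(train, query, folds = 5L, seed = NULL) {
  stopifnot(all(c("n_annotations", "tree_density") %in% names(train)))
  train <- train[is.finite(train$tree_density) & train$tree_density > 0 &
                   train$n_annotations > 0, , drop = FALSE]
  if (nrow(train) < 10L) {
    abort("need at least 10 training families with computed densities")
  }
  if (any(query <= 0)) abort("query annotation counts must be > 0")
  fit <- lm(log(tree_density) ~ log(n_annotations), data = train)
  pred <- exp(predict(fit, newdata = data.frame(n_annotations = query)))
  folds <- min(folds, nrow(train))
  fold_id <- with_seed(seed,
    sample(rep_len(seq_len(folds), nrow(train))))
  ape_err <- numeric(0)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    if (all(hold) || !any(hold)) next
    cvfit <- lm(log(tree_density) ~ log(n_annotations),
                data = train[!hold, , drop = FALSE])
    hat <- exp(predict(cvfit, newdata = train[hold, , drop = FALSE]))
    ape_err <- c(ape_err, abs(hat - train$tree_density[hold]) /
                   train$tree_density[hold])
  }
  out <- tibble(n_annotations = query, tree_density = as.numeric(pred),
                predicted = TRUE)
  attr(out, "mape") <- 100 * mean(ape_err)
  attr(out, "model") <- fit
  out
}
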