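test_that("clr transform matches hand arithmetic and its identities", {
  x <- matrix(c(0.5, 0.25, 0.25), 1)
  out <- as.matrix(clr_transform(x, pseudo = 0))
  expect_equal(unname(out[1, ]), c(0.462, -0.231, -0.231), tolerance = 5e-4)
  expect_equal(unname(as.matrix(clr_transform(matrix(1 / 3, 1, 3), pseudo = 0))),
               matrix(0, 1, 3), tolerance = 1e-12)

  set.seed(71)
  comp <- matrix(runif(60), 10, 6)
  comp <- comp / rowSums(comp)
  res <- as.matrix(clr_transform(comp))
  expect_true(all(abs(rowSums(res)) < 1e-10))
  # invariant to a positive rescaling before closure
  res2 <- as.matrix(clr_transform(comp * 1000, pseudo = 0))
  res1 <- as.matrix(clr_transform(comp, pseudo = 0))
  expect_equal(res2, res1, tolerance = 1e-10)
  expect_error(clr_transform(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("partial Kendall tau: perfect concordance, reversal, invariance", {
  x <- c(1, 2, 3); y10 <- c(10, 20, 30)
  expect_equal(partial_kendall_tau(x, y10), 1)
  expect_equal(partial_kendall_tau(x, rev(y10)), -1)
  # invariant under strictly monotone transforms
  set.seed(72)
  xx <- rnorm(30); yy <- 0.5 * xx + rnorm(30)
  st <- rep(c("A", "B", "C"), each = 10)
  t0 <- partial_kendall_tau(xx, yy, st)
  expect_equal(partial_kendall_tau(exp(xx), yy^3 + yy * 2, st), t0,
               tolerance = 1e-12)
  expect_true(abs(t0) <= 1)
})

test_that("matrix-inversion partial tau tracks the residual-rank oracle", {
  set.seed(73)
  diffs <- replicate(20, {
    n <- 60
    st <- rep(c("A", "B", "C"), each = 20)
    shift <- c(A = 0, B = 0.5, C = -0.5)[st]
    x <- rnorm(n) + shift
    y <- 0.4 * x + rnorm(n) + 0.25 * shift
    partial_kendall_tau(x, y, st) - partial_tau_oracle(x, y, st)
  })
  expect_true(all(abs(diffs) < 0.05))
})

test_that("permutation test keeps study structure and has the p floor", {
  set.seed(74)
  n <- 24
  st <- rep(c("A", "B"), each = 12)
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.05)  # overwhelming association
  out <- permutation_association_test(x, y, st, P = 250, seed = 75)
  expect_equal(out$p, 1 / 251)
  expect_gt(out$partial_tau, 0.8)

  # a covariate constant within every study is undefined and flagged
  out2 <- permutation_association_test(x, c(A = 1, B = 2)[st], st,
                                       P = 50, seed = 76)
  expect_equal(out2$p, 1)
  expect_identical(out2$flag, "constant_covariate")
})

test_that("within-study permutations never mix covariate values across studies", {
  # covariate values are disjoint between studies; under within-study
  # shuffling each study keeps exactly its own multiset of values, so the
  # study-mean of the permuted covariate is invariant -> partial tau with
  # the nuisance terms stays centered. Structural check via a tracer:
  y <- c(1:6, 101:106)
  st <- rep(c("A", "B"), each = 6)
  idx <- split(seq_along(y), st)
  set.seed(77)
  for (i in 1:25) {
    yp <- y
    for (ix in idx) yp[ix] <- y[ix][sample.int(length(ix))]
    expect_setequal(yp[idx$A], 1:6)
    expect_setequal(yp[idx$B], 101:106)
  }
})

test_that("permutation p-values are valid under within-study exchangeability", {
  set.seed(78)
  n <- 30
  st <- rep(c("A", "B", "C"), each = 10)
  pvals <- replicate(120, {
    x <- rnorm(n) + c(A = 0, B = 1, C = 3)[st]
    y <- rnorm(n) + c(A = 2, B = 0, C = 1)[st]  # study effects, no link
    permutation_association_test(x, y, st, P = 39)$p
  })
  expect_lte(mean(pvals <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 120))
  # roughly uniform: median near 0.5
  expect_gt(median(pvals), 0.3)
  expect_lt(median(pvals), 0.75)
})

test_that("Fisher enrichment agrees with hypergeometric enumeration", {
  universe <- paste0("g", 1:40)
  ann <- list(half = paste0("g", 1:20), rest = paste0("g", 21:40))
  res <- fisher_enrichment(paste0("g", 1:20), ann, universe)
  res <- res[res$pathway == "half", ]
  expect_equal(res$odds_ratio, Inf)
  # exhaustive two-tailed hypergeometric oracle: sum of all tables with
  # probability <= that of the observed table
  dens <- dhyper(0:20, 20, 20, 20)
  oracle <- sum(dens[dens <= dens[21] * (1 + 1e-7)])
  expect_equal(res$p, oracle, tolerance = 1e-12)

  # pathways disjoint from the universe are dropped
  ann2 <- list(half = paste0("g", 1:20), ghost = paste0("x", 1:5))
  res2 <- fisher_enrichment(paste0("g", 1:20), ann2, universe)
  expect_identical(res2$pathway, "half")

  # the universe is intersected with annotated families
  expect_error(fisher_enrichment("zzz", ann, universe), "subset")
})

test_that("random gene sets give roughly uniform enrichment p-values", {
  set.seed(79)
  universe <- paste0("g", 1:200)
  ann <- lapply(1:30, function(i) sample(universe, 40))
  names(ann) <- paste0("pw", 1:30)
  ps <- replicate(10, {
    fisher_enrichment(sample(universe, 50), ann, universe)$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(median(ps), 0.25)
})

test_that("association screen ties families, covariates and q-values together", {
  set.seed(80)
  sim <- simulate_dataset(ccoda_sim_config(genes = 6, n_total = 20, seed = 81))
  resid <- fit_study_model(
    counts_to_log_rpkg(counts_matrix(sim$counts)), sim$design
  )$residuals
  covars <- tibble::tibble(
    sample_id = sim$design$sample_id,
    driver = resid[1, ] + rnorm(20, sd = 0.01),
    noise = rnorm(20)
  )
  out <- ccoda_associate(resid, covars, sim$design, P = 199, seed = 82)
  expect_equal(nrow(out), 12L)
  hit <- out[out$family_id == rownames(resid)[1] & out$covariate == "driver", ]
  expect_equal(hit$p, 1 / 200)
  expect_true(hit$significant)
})

test_that("family-set subsampling is balanced and seeded", {
  pools <- list(a = paste0("a", 1:30), b = paste0("b", 1:50))
  out <- subsample_family_sets(pools, size = 20, seed = 83)
  expect_equal(lengths(out), c(a = 20L, b = 20L))
  expect_true(all(out$a %in% pools$a))
  expect_identical(out, subsample_family_sets(pools, size = 20, seed = 83))
  expect_error(subsample_family_sets(pools, size = 40), "at least")
})
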