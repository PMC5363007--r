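make_disp <- function(mu_gy, k_y) {
  ys <- colnames(mu_gy)
  structure(list(mu_gy = mu_gy,
                 k_gy = matrix(NA_real_, nrow(mu_gy), ncol(mu_gy),
                               dimnames = dimnames(mu_gy)),
                 k_y = k_y, design = NULL),
            class = "ccoda_dispersion")
}

two_study_design <- function(n_per = 4) {
  data.frame(sample_id = paste0("s", seq_len(2 * n_per)),
             study_id = rep(c("A", "B"), each = n_per))
}

test_that("null counts respect the NB parameters and the seed contract", {
  mu <- matrix(c(0, 20, 0, 20), 2, 2,
               dimnames = list(c("g0", "g1"), c("A", "B")))
  disp <- make_disp(mu, c(A = 2, B = 2))
  d <- two_study_design()
  reps <- simulate_null_counts(disp, d, B = 400, seed = 21)
  expect_length(reps, 400)
  expect_equal(dim(reps[[1]]), c(2L, 8L))
  # zero mean produces all-zero counts
  expect_true(all(vapply(reps, function(r) all(r["g0", ] == 0), logical(1))))
  # NB mean identity within Monte-Carlo error
  draws <- unlist(lapply(reps, function(r) r["g1", ]))
  se <- sqrt((20 + 20^2 / 2) / length(draws))
  expect_lt(abs(mean(draws) - 20), 3 * se)
  # bit-reproducible under the same seed
  again <- simulate_null_counts(disp, d, B = 5, seed = 21)
  expect_identical(reps[1:5], again)
})

test_that("huge k approaches the Poisson limit (variance ~ mean)", {
  mu <- matrix(50, 1, 1, dimnames = list("g", "A"))
  disp <- make_disp(mu, c(A = 1e6))
  d <- data.frame(sample_id = paste0("s", 1:2), study_id = "A")
  reps <- simulate_null_counts(disp, d, B = 5000, seed = 3)
  draws <- unlist(reps)
  expect_equal(var(draws) / mean(draws), 1, tolerance = 0.06)
})

test_that("null_statistics equals the real-data pipeline replicate by replicate", {
  mu <- matrix(c(5, 40, 6, 50), 2, 2,
               dimnames = list(c("g1", "g2"), c("A", "B")))
  disp <- make_disp(mu, c(A = 1, B = 0.7))
  d <- two_study_design()
  reps <- simulate_null_counts(disp, d, B = 3, seed = 5)
  null <- null_statistics(reps, d, afl = 1000, ge = 1, pseudocount = 1)
  expect_s3_class(null, "ccoda_null")
  expect_equal(null$B, 3L)
  manual <- sapply(reps, function(r) {
    fit_study_model(counts_to_log_rpkg(r, 1000, 1, 1), d)$V_eps
  })
  expect_equal(unname(null$stats), unname(manual), tolerance = 1e-12)
  # fused path agrees with the list path under the same seed
  fused <- ccoda:::null_ensemble_fused(disp, d, B = 3, afl = 1000, ge = 1,
                                       pseudocount = 1, seed = 5)
  expect_equal(fused$stats, null$stats, tolerance = 1e-12)
})

test_that("two-tailed p matches brute-force enumeration on a toy ensemble", {
  stats <- matrix(c(1.0, 1.2, 0.8, 1.1, 0.9), 1,
                  dimnames = list("g", NULL))
  null <- ccoda:::new_ccoda_null(stats)
  for (V in c(0.5, 0.95, 1.0, 1.3, 2.5)) {
    m0 <- mean(stats)
    brute <- (sum(((stats - m0) / m0)^2 >= ((V - m0) / m0)^2) + 1) / 6
    expect_equal(pvalue_two_tailed(setNames(V, "g"), null)$p, brute)
  }
  # V exactly at the null mean: every null deviation ties or exceeds
  expect_equal(pvalue_two_tailed(setNames(mean(stats), "g"), null)$p, 1)
})

test_that("p has the 1/(B+1) floor and discrete support", {
  set.seed(31)
  stats <- matrix(runif(750, 1, 2), 1, dimnames = list("g", NULL))
  null <- ccoda:::new_ccoda_null(stats)
  out <- pvalue_two_tailed(setNames(100, "g"), null)
  expect_equal(out$p, 1 / 751)
  grid <- sapply(seq(0.5, 3, by = 0.05), function(V) {
    pvalue_two_tailed(setNames(V, "g"), null)$p
  })
  expect_true(all(abs(grid * 751 - round(grid * 751)) < 1e-9))
  expect_true(all(grid >= 1 / 751 & grid <= 1))
})

test_that("squared-relative-deviation ordering equals |V - null mean| ordering", {
  set.seed(32)
  stats <- matrix(rgamma(200, 4, 2), 1, dimnames = list("g", NULL))
  null <- ccoda:::new_ccoda_null(stats)
  m0 <- mean(stats)
  vs <- seq(0.1, 5, length.out = 60)
  p_formula <- sapply(vs, function(V) pvalue_two_tailed(setNames(V, "g"), null)$p)
  p_abs <- sapply(vs, function(V) {
    (sum(abs(stats - m0) >= abs(V - m0)) + 1) / (ncol(stats) + 1)
  })
  expect_equal(p_formula, p_abs)
})

test_that("degenerate null mean gives p = 1 with a flag", {
  stats <- matrix(0, 1, 10, dimnames = list("g", NULL))
  null <- ccoda:::new_ccoda_null(stats)
  out <- pvalue_two_tailed(setNames(0.5, "g"), null)
  expect_equal(out$p, 1)
  expect_identical(out$flag, "degenerate_null")
})

test_that("observed V sits inside the null band ~95% of the time under H0", {
  set.seed(33)
  g <- 300; n <- 60; k <- 0.8
  mu <- rlnorm(g, 2.94, 1.5)
  cnt <- matrix(rnbinom(g * n, size = k, mu = mu), g, n,
                dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  d <- data.frame(sample_id = colnames(cnt),
                  study_id = rep(c("A", "B"), each = 30))
  disp <- estimate_gene_k(cnt, d)
  disp$k_y <- c(A = k, B = k)
  null <- ccoda:::null_ensemble_fused(disp, d, B = 200, afl = 1000, ge = 1,
                                      pseudocount = 1, seed = 34)
  V <- residual_variance(fit_study_model(counts_to_log_rpkg(cnt), d))
  lo <- apply(null$stats, 1, quantile, 0.025)
  hi <- apply(null$stats, 1, quantile, 0.975)
  coverage <- mean(V >= lo & V <= hi)
  expect_gt(coverage, 0.90)
  expect_lte(coverage, 1)
})

test_that("cluster-bootstrap adjustment is the stated affine map", {
  sim <- simulate_dataset(ccoda_sim_config(genes = 60, n_total = 24, seed = 41))
  cnt <- counts_matrix(sim$counts)
  logr <- counts_to_log_rpkg(cnt)
  disp <- estimate_gene_k(cnt, sim$design)
  disp$k_y <- sim$k_y
  null <- ccoda:::null_ensemble_fused(disp, sim$design, B = 80, afl = 1000,
                                      ge = 1, pseudocount = 1, seed = 42)
  adj <- cluster_bootstrap_adjust(null, logr, sim$design, B = 80, seed = 43)
  ok <- setdiff(adj$family_id, adj$fallback)
  idx <- match(ok, adj$family_id)
  # adjusted mean and sd equal the parametric null's, by construction
  expect_equal(rowMeans(adj$stats[idx, ]), null$mean[idx], tolerance = 1e-9)
  expect_equal(apply(adj$stats[idx, ], 1, sd), null$sd[idx], tolerance = 1e-9)
  # same seed reproduces the same adjusted ensemble (the affine map is a
  # deterministic, rank-preserving function of the resamples)
  adj2 <- cluster_bootstrap_adjust(null, logr, sim$design, B = 80, seed = 43)
  expect_equal(adj2$stats, adj$stats)
  # residual-scaling denominator stays the parametric one
  expect_equal(adj$mean_root, null$mean_root)
})

test_that("an affine map with positive slope preserves rank order", {
  boot <- c(3, 1, 2, 5, 4)
  mapped <- (boot - mean(boot)) / sd(boot) * 2.5 + 10
  expect_identical(order(mapped), order(boot))
})
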