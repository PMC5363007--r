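test_that("simulated datasets honor the configuration and the seed", {
  cfg <- ccoda_sim_config(genes = 120, n_total = 61, prop_true_pos = 0,
                          seed = 61)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$labels$label == "null"))
  m <- counts_matrix(sim$counts)
  expect_equal(dim(m), c(120L, 61L))
  expect_equal(sort(table(sim$design$study_id), decreasing = TRUE),
               sort(table(c(rep("study1", 21), rep("study2", 20),
                            rep("study3", 20))), decreasing = TRUE),
               ignore_attr = TRUE)
  sim2 <- simulate_dataset(cfg)
  expect_identical(counts_matrix(sim2$counts), m)
  expect_identical(sim2$k_y, sim$k_y)

  cfg2 <- ccoda_sim_config(genes = 100, n_total = 30, prop_true_pos = 0.43,
                           var_invar_ratio = 2, seed = 62)
  sim3 <- simulate_dataset(cfg2)
  tab <- table(sim3$labels$label)
  expect_equal(unname(tab["variable"] + tab["invariable"]), 43)
  expect_gt(tab["variable"], tab["invariable"])
})

test_that("variable true positives are genuinely overdispersed", {
  set.seed(63)
  mu <- 30; k <- 0.6; z <- 4
  null_draws <- rnbinom(1e4, size = k, mu = mu)
  var_draws <- rnbinom(1e4, size = k / z, mu = mu)
  invar_draws <- rnbinom(1e4, size = k * z, mu = mu)
  expect_gt(var(var_draws), var(null_draws))
  expect_lt(var(invar_draws), var(null_draws))
  # NB variance identity mu + mu^2/k within MC error
  expect_equal(var(null_draws), mu + mu^2 / k, tolerance = 0.1)
})

test_that("error-rate bookkeeping against labels is exact for an oracle", {
  labels <- tibble::tibble(
    family_id = paste0("g", 1:10),
    label = c(rep("null", 6), rep("variable", 2), rep("invariable", 2))
  )
  oracle <- tibble::tibble(family_id = labels$family_id,
                           p = c(rep(1, 6), rep(1e-6, 4)))
  er <- evaluate_error_rates(labels, oracle)
  expect_equal(er$alpha[er$class == "overall"], 0)
  expect_equal(er$power, c(1, 1, 1))
  # a blind test: alpha 1, power 1 at p_cut 1
  er2 <- evaluate_error_rates(labels, dplyr::mutate(oracle, p = 0.5), p_cut = 0.5)
  expect_equal(er2$alpha[1], 1)
})

test_that("realized-FDR cutoff search matches its definition", {
  # 100 calls in one direction: 95 true positives then 5 false positives
  q <- seq(0.001, 0.1, length.out = 100)
  truth <- c(rep(TRUE, 95), rep(FALSE, 5))
  # at the largest q the realized FDR is 5/100 = 5%
  expect_equal(ccoda:::largest_q_cutoff(q, truth, 0.05), max(q))
  # tightening the target drops the admissible cutoff below the first FP
  expect_lt(ccoda:::largest_q_cutoff(q, truth, 0.01), q[96])
  # all-null direction: FDR is 1 everywhere, no cutoff exists
  expect_true(is.na(ccoda:::largest_q_cutoff(q, rep(FALSE, 100), 0.05)))
  expect_true(is.na(ccoda:::largest_q_cutoff(numeric(0), logical(0), 0.05)))
})

test_that("calibration returns ordered cutoffs with replicate detail", {
  cal <- suppressWarnings(calibrate_empirical_fdr(
    fdr_levels = c(0.05, 0.25), ratios = c(0.5, 2), reps = 1L,
    n_total = 60L, genes = 250L, B = 60L, seed = 64
  ))
  expect_named(cal, c("fdr", "direction", "cutoff"))
  expect_equal(nrow(cal), 4L)
  reps <- attr(cal, "replicates")
  expect_equal(nrow(reps), 8L)
  # cutoffs grow with the FDR level within each direction
  for (dir in c("variable", "invariable")) {
    cuts <- cal$cutoff[cal$direction == dir]
    lev <- cal$fdr[cal$direction == dir]
    if (!anyNA(cuts)) expect_true(all(diff(cuts[order(lev)]) >= 0))
  }
})
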