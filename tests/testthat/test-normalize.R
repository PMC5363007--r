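test_that("AFL imputation fills gaps with the family mean and nothing else", {
  afl <- tibble::tibble(
    family_id = c("K1", "K2", "K3"),
    s1 = c(900, 500, NA),
    s2 = c(NA, 600, NA),
    s3 = c(1100, 700, NA)
  )
  out <- impute_afl(afl, default = 800)
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(900, 1000, 1100))
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(500, 600, 700))
  expect_equal(unlist(out[3, -1], use.names = FALSE), rep(800, 3))
  expect_error(impute_afl(afl), "K3")
})

test_that("genome equivalents follow total_bp / ags", {
  info <- data.frame(sample_id = c("a", "b"),
                     total_reads = c(1.5e7, 1.5e7),
                     read_length = c(90, 90),
                     ags = c(4.5e6, 9e6))
  ge <- genome_equivalents(info)
  expect_equal(unname(ge["a"]), 300)
  expect_equal(unname(ge["b"]), 150)  # doubling AGS halves GE
  info$ags <- info$total_reads * info$read_length
  expect_equal(unname(genome_equivalents(info)), c(1, 1))
  info$ags[1] <- 0
  expect_error(genome_equivalents(info), "positive")
})

test_that("log-RPKG matches its definition and identities", {
  m <- matrix(10, 1, 1, dimnames = list("g", "s"))
  # pseudocount tending to zero recovers count/(AFL kb)/GE
  out <- counts_to_log_rpkg(m, afl = 1000, ge = 5, pseudocount = 1e-12)
  expect_equal(unlist(out[1, -1], use.names = FALSE), log(2),
               tolerance = 1e-10)
  z <- matrix(0, 1, 1, dimnames = list("g", "s"))
  expect_equal(unlist(counts_to_log_rpkg(z, 1000, 1, 1)[1, -1],
                      use.names = FALSE), 0)

  # multiplying all GE by c shifts every log-RPKG by -log(c)
  set.seed(1)
  cnt <- matrix(rpois(12, 6), 3, 4,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ge1 <- stats::setNames(c(2, 3, 4, 5), colnames(cnt))
  a <- counts_to_log_rpkg(cnt, 800, ge1, 1)
  b <- counts_to_log_rpkg(cnt, 800, ge1 * 7, 1)
  expect_equal(as.matrix(b[, -1]), as.matrix(a[, -1]) - log(7))

  # strictly monotone in the count for fixed AFL/GE
  cnts <- sapply(0:20, function(k) {
    unlist(counts_to_log_rpkg(matrix(k, 1, 1, dimnames = list("g", "s")),
                              500, 2, 1)[1, -1])
  })
  expect_true(all(diff(cnts) > 0))
})

test_that("marker normalization is a per-sample ratio", {
  m <- matrix(c(8, 4, 2, 6, 16, 8, 4, 12), 4, 2,
              dimnames = list(c("gene", "m1", "m2", "m3"), c("s1", "s2")))
  out <- marker_normalize(m, c("m1", "m2", "m3"))
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(2, 2))
  # scaling one sample leaves its normalized column unchanged
  m2 <- m; m2[, 2] <- m2[, 2] * 13
  out2 <- marker_normalize(m2, c("m1", "m2", "m3"))
  expect_equal(as.matrix(out2[, -1]), as.matrix(out[, -1]))
  m3 <- m; m3[c("m1", "m2", "m3"), 1] <- 0
  expect_error(marker_normalize(m3, c("m1", "m2", "m3")), "s1")
})

test_that("rarefaction hits the target depth and is unbiased", {
  set.seed(42)
  cnt <- matrix(rpois(30, 40), 10, 3,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  depth <- min(colSums(cnt)) - 25
  out <- counts_matrix(rarefy_counts(cnt, depth, seed = 1))
  expect_true(all(colSums(out) == depth))
  expect_true(all(out <= cnt))

  # depth equal to the column total is the identity
  same <- counts_matrix(rarefy_counts(cnt[, 1, drop = FALSE], colSums(cnt)[1]))
  expect_equal(same, cnt[, 1, drop = FALSE])

  expect_error(rarefy_counts(cnt, max(colSums(cnt)) + 1), "shallower")

  # Monte-Carlo mean of the rarefied count ~= depth * proportion
  col <- c(g1 = 100, g2 = 50, g3 = 350)
  draws <- sapply(1:1000, function(i) {
    counts_matrix(rarefy_counts(matrix(col, 3, 1,
      dimnames = list(names(col), "s")), 100, seed = i))[, 1]
  })
  expect_equal(rowMeans(draws), 100 * col / sum(col), tolerance = 0.05)
})
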