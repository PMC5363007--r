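# Shared fixture builders; everything is generated in code.

tiny_counts <- function() {
  tibble::tibble(
    family_id = c("K00001", "K00002", "K00003"),
    s1 = c(3, 0, 12),
    s2 = c(1, 9, 4),
    s3 = c(5, 2, 0),
    s4 = c(2, 7, 8)
  )
}

tiny_design <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:4),
    study_id = c("A", "A", "B", "B"),
    total_reads = rep(1.5e7, 4),
    read_length = rep(90, 4),
    ags = rep(4.5e6, 4)
  )
}

write_tsv_fixture <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

counts_matrix <- function(x) ccoda:::abund_matrix(x)

# residual-rank oracle for the partial Kendall tau: Kendall tau-b of the
# residuals of rank(x) and rank(y) after regressing out the study
# indicators (a classical approximation the matrix-inversion partial
# correlation should agree with closely)
partial_tau_oracle <- function(x, y, study) {
  f <- factor(study)
  rx <- rank(x); ry <- rank(y)
  ex <- stats::residuals(stats::lm(rx ~ f))
  ey <- stats::residuals(stats::lm(ry ~ f))
  stats::cor(ex, ey, method = "kendall")
}
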