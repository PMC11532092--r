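# 3x3 matrix implied by the reported per-class sensitivities (85.7%,
# 37.5%, 80.3%) and FISH class sizes (14, 16, 66): diagonal (12, 6, 53),
# off-diagonal mass placed arbitrarily (only the diagonal and the row
# sums are determined by those figures).
reportedMatrix <- function() {
  m <- diag(c(12L, 6L, 53L))
  m[1, 3] <- 2L   # FISH amp called negative
  m[2, 3] <- 10L  # FISH polysomy called negative
  m[3, 1] <- 3L
  m[3, 2] <- 10L
  dimnames(m) <- list(rev(metStatusLevels()), rev(metStatusLevels()))
  m
}

test_that("confusion matrices count aligned label pairs", {
  cs <- confusionSummary(rep("AMPLIFICATION", 3), rep("AMPLIFICATION", 3))
  expect_equal(diag(confusionCounts(cs)), c(AMPLIFICATION = 3,
                                            POLYSOMY = 0, NEGATIVE = 0))
  expect_equal(nSamples(cs), 3L)
  # empty input -> zero matrix
  cs0 <- confusionSummary(character(0), character(0))
  expect_equal(sum(confusionCounts(cs0)), 0)
  expect_equal(nSamples(cs0), 0L)
  # permutation invariance
  f <- c("AMPLIFICATION", "POLYSOMY", "NEGATIVE", "NEGATIVE")
  g <- c("AMPLIFICATION", "NEGATIVE", "NEGATIVE", "POLYSOMY")
  perm <- c(3, 1, 4, 2)
  expect_identical(confusionCounts(confusionSummary(f, g)),
                   confusionCounts(confusionSummary(f[perm], g[perm])))
  expect_error(confusionSummary(f, g[1:2]), "equal length")
})

test_that("one-vs-rest metrics reproduce the reported per-class values", {
  cs <- confusionFromCounts(reportedMatrix())
  expect_equal(pct(oneVsRest(cs, "AMPLIFICATION")[["sensitivity"]]), 85.7)
  expect_equal(pct(oneVsRest(cs, "POLYSOMY")[["sensitivity"]]), 37.5)
  expect_equal(pct(oneVsRest(cs, "NEGATIVE")[["sensitivity"]]), 80.3)
  # perfect diagonal -> (1, 1) everywhere
  perfect <- confusionFromCounts(diag(c(5L, 5L, 5L)))
  for (cl in metStatusLevels()) {
    expect_equal(unname(oneVsRest(perfect, cl)), c(1, 1))
  }
  # undefined denominators warn and return NA instead of crashing
  m <- matrix(0L, 3, 3); m[3, 3] <- 4L
  expect_warning(s <- oneVsRest(confusionFromCounts(m), "AMPLIFICATION"),
                 "undefined")
  expect_true(is.na(s[["sensitivity"]]))
})

test_that("overall agreement carries the exact Clopper-Pearson interval", {
  cs <- confusionFromCounts(reportedMatrix())
  oa <- overallAgreement(cs)
  expect_equal(oa$concordant, 71L)
  expect_equal(pct(oa$proportion), 74.0)
  expect_equal(pct(oa$ci_low), 64.0)
  expect_equal(pct(oa$ci_high), 82.4)
  # boundary: zero successes pin the lower limit at 0
  m0 <- matrix(0L, 3, 3); m0[1, 2] <- 5L
  oa0 <- overallAgreement(confusionFromCounts(m0))
  expect_equal(oa0$proportion, 0)
  expect_equal(oa0$ci_low, 0)
  expect_error(overallAgreement(confusionFromCounts(matrix(0L, 3, 3))),
               "empty")
})

test_that("agreement equals the prevalence-weighted mean of sensitivities", {
  set.seed(13)
  for (rep in 1:25) {
    m <- matrix(rpois(9, 8), 3, 3)
    cs <- confusionFromCounts(m)
    sens <- vapply(rev(metStatusLevels()), function(cl) {
      suppressWarnings(oneVsRest(cs, cl)[["sensitivity"]])
    }, 0)
    prev <- rowSums(confusionCounts(cs)) / nSamples(cs)
    expect_equal(overallAgreement(cs)$proportion,
                 sum(prev * sens, na.rm = TRUE))
  }
})

test_that("GCN strata use half-open bins with an open-ended top bin", {
  out <- agreementByGcn(c(1.2, 3, 7),
                        c("NEGATIVE", "POLYSOMY", "AMPLIFICATION"),
                        c("NEGATIVE", "NEGATIVE", "AMPLIFICATION"))
  expect_equal(out$n, c(1L, 1L, 1L))
  expect_equal(out$agreement, c(1, 0, 1))
  # left edge inclusive, right edge exclusive
  out2 <- agreementByGcn(c(2, 5), c("NEGATIVE", "POLYSOMY"),
                         c("NEGATIVE", "POLYSOMY"))
  expect_equal(out2$n, c(0L, 1L, 1L))
  expect_true(is.na(out2$agreement[1]))
  expect_error(agreementByGcn(1, "NEGATIVE", "NEGATIVE", c(5, 2)),
               "strictly increasing")
})

test_that("collapsing to binary conserves counts and merges confusions", {
  cs <- confusionFromCounts(reportedMatrix())
  b <- collapseToBinary(cs)
  expect_equal(sum(b), 96)
  expect_equal(b[1, 1], 12L)
  expect_equal(b[2, 2], 6L + 53L + 10L + 10L)  # poly/neg confusions merge
  # agreement never decreases on collapse
  expect_gte(sum(diag(b)) / sum(b),
             overallAgreement(cs)$proportion)
  # off-diagonal mass only between the merged classes -> binary perfect
  m <- diag(c(4L, 0L, 0L)); m[2, 3] <- 7L; m[3, 2] <- 5L
  b2 <- collapseToBinary(confusionFromCounts(m))
  expect_equal(sum(diag(b2)) / sum(b2), 1)
})

test_that("half-up percentage rounding matches reported precision", {
  expect_equal(pct(71 / 96), 74.0)
  expect_equal(pct(261 / 317, 2), 82.33)
  expect_equal(pct(0.005, 0), 1)   # half rounds up, not to even
  expect_equal(pct(0.12345, 2), 12.35)
})
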