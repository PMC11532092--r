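test_that("rocCutoff maximises Youden's J over observed values", {
  # any t in (1.1, 2.0] separates perfectly; smallest observed is 2.0
  expect_equal(as.numeric(rocCutoff(c(1.0, 1.1, 2.0, 2.5),
                                    c(FALSE, FALSE, TRUE, TRUE))), 2.0)
  # perfect separation at the smallest positive
  expect_equal(as.numeric(rocCutoff(c(1, 2, 3, 0),
                                    c(TRUE, TRUE, TRUE, FALSE))), 1)
  # inseparable tie: threshold 5 with J = 0
  t5 <- rocCutoff(c(5, 5), c(TRUE, FALSE))
  expect_equal(as.numeric(t5), 5)
  expect_equal(attr(t5, "youden"), 0)
  expect_error(rocCutoff(c(1, 2), c(TRUE, TRUE)), "degenerate")
})

test_that("rocCutoff matches the naive counting oracle on random data", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    v <- round(rnorm(n, 2, 1), 2)
    pos <- runif(n) < 0.4
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[n] <- FALSE
    expect_equal(as.numeric(rocCutoff(v, pos)), bruteYouden(v, pos))
  }
})

test_that("fitAmpGates fits each denominator independently, amp vs rest", {
  m <- rbind(c(6.0, 2, 2, 2, 2, 2, 2),
             c(8.0, 2, 2, 2, 2, 2, 2),
             c(2.0, 2, 2, 2, 2, 2, 2),
             c(2.2, 2, 2, 2, 2, 2, 2))
  colnames(m) <- panelGenes()
  fish <- c("AMPLIFICATION", "AMPLIFICATION", "NEGATIVE", "POLYSOMY")
  # MET/CYP3A4 in {3, 4} for amp, {1, 1.1} for the rest -> cutoff 3
  g <- fitAmpGates(m, fish, "CYP3A4")
  expect_equal(g[["CYP3A4"]], 3.0)
  # two-gene fit equals the two single-gene fits
  g2 <- fitAmpGates(m, fish, c("CYP3A4", "BRAF"))
  expect_equal(g2[["CYP3A4"]], fitAmpGates(m, fish, "CYP3A4")[["CYP3A4"]])
  expect_equal(g2[["BRAF"]], fitAmpGates(m, fish, "BRAF")[["BRAF"]])
})

test_that("fitPolysomyCutoff separates polysomy from negative MET GCN", {
  expect_equal(fitPolysomyCutoff(c(3.1, 3.5, 2.0, 2.2),
                                 c("POLYSOMY", "POLYSOMY",
                                   "NEGATIVE", "NEGATIVE")), 3.1)
  expect_equal(fitPolysomyCutoff(c(5, 2), c("POLYSOMY", "NEGATIVE")), 5)
  # amplification samples are excluded before fitting
  expect_equal(fitPolysomyCutoff(c(9, 3.1, 2.0),
                                 c("AMPLIFICATION", "POLYSOMY",
                                   "NEGATIVE")), 3.1)
  expect_error(fitPolysomyCutoff(c(3, 4), c("POLYSOMY", "POLYSOMY")),
               "degenerate")
})

test_that("train picks the minimal separating subset with agreement 1", {
  # only MET/CYP3A4 separates amp; MET GCN separates polysomy
  n <- 12
  m <- matrix(2, n, 7, dimnames = list(NULL, panelGenes()))
  fish <- c(rep("AMPLIFICATION", 3), rep("POLYSOMY", 3), rep("NEGATIVE", 6))
  m[1:3, "MET"] <- c(6, 7, 8)
  m[1:3, setdiff(panelGenes(), c("MET", "CYP3A4"))] <-
    m[1:3, "MET"]  # all other ratios are exactly 1 for amp cases too
  m[4:6, "MET"] <- c(4, 4.5, 5)
  m[4:6, setdiff(panelGenes(), "MET")] <- m[4:6, "MET"]
  res <- suppressMessages(trainRatioGateModel(m, fish))
  expect_equal(trainingAgreement(res), 1.0)
  expect_equal(names(gateThresholds(fittedModel(res))), "CYP3A4")
  # log covers all 63 nonempty subsets and the winner attains the max
  log <- candidateLog(res)
  expect_equal(nrow(log), 63L)
  expect_equal(max(log$agreement), trainingAgreement(res))
})

test_that("training is deterministic and errors on a missing class", {
  set.seed(11)
  coh <- randomTrainingCohort(25)
  r1 <- suppressMessages(trainRatioGateModel(coh$gcn, coh$fish))
  r2 <- suppressMessages(trainRatioGateModel(coh$gcn, coh$fish))
  expect_identical(candidateLog(r1), candidateLog(r2))
  expect_identical(gateThresholds(fittedModel(r1)),
                   gateThresholds(fittedModel(r2)))
  expect_error(
    suppressMessages(trainRatioGateModel(
      coh$gcn, rep(c("NEGATIVE", "POLYSOMY"), length.out = 25))),
    "degenerate.*AMPLIFICATION")
})

test_that("fitted polysomy cutoff lands between the generated classes", {
  # well-separated zero-noise cohort: cutoff must fall in the gap between
  # the largest negative and the smallest polysomy MET GCN
  coh <- simulateCohort(cohortConfig(n = 150, gcn_noise_sd = 0,
                                     purity_range = c(1, 1),
                                     polysomy_range = c(5L, 6L),
                                     seed = 5))
  truth <- as.character(truthStatus(coh))
  met <- gcnAssay(coh)["MET", ]
  res <- suppressMessages(trainRatioGateModel(coh, truth))
  cut <- polysomyThreshold(fittedModel(res))
  expect_gt(cut, max(met[truth == "NEGATIVE"]))
  expect_lte(cut, min(met[truth == "POLYSOMY"]))
})
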