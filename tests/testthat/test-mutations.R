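variantRow <- function(...) {
  defaults <- list(patient_id = "P1", gene = "EGFR", site = "L858R",
                   form = "missense", ref_base = "T", alt_base = "G",
                   vaf = 0.25, pop_freq = NA_real_, sift = 0.01,
                   polyphen2 = 0.99)
  args <- modifyList(defaults, list(...))
  as.data.frame(args, stringsAsFactors = FALSE)
}

test_that("the three filter rules fire in order with correct counts", {
  v <- rbind(
    variantRow(patient_id = "P1", pop_freq = 0.002),          # rule 1
    variantRow(patient_id = "P2", vaf = 0.005),               # rule 2
    variantRow(patient_id = "P3", sift = 0.30, polyphen2 = 0.20),  # rule 3
    variantRow(patient_id = "P4", sift = 0.30, polyphen2 = NA),    # kept
    variantRow(patient_id = "P5", sift = NA, polyphen2 = 0.20),    # kept
    variantRow(patient_id = "P6"))                            # kept
  out <- filterVariants(v)
  expect_equal(out$removed, c(germline = 1L, low_vaf = 1L, benign = 1L))
  expect_setequal(out$retained$patient_id, c("P4", "P5", "P6"))
  # boundary semantics: pop_freq 0.001 and vaf 0.01 survive;
  # sift 0.05 is not benign, polyphen2 0.446 is
  keep <- filterVariants(rbind(
    variantRow(pop_freq = 0.001), variantRow(vaf = 0.01),
    variantRow(sift = 0.05, polyphen2 = 0.2)))
  expect_equal(nrow(keep$retained), 3L)
  drop <- filterVariants(variantRow(sift = 0.051, polyphen2 = 0.446))
  expect_equal(nrow(drop$retained), 0L)
})

test_that("filtering is idempotent and the retained set is order-free", {
  set.seed(21)
  v <- simulateVariantTable(60, seed = 21)
  out <- filterVariants(v)
  again <- filterVariants(out$retained)
  expect_equal(again$removed, c(germline = 0L, low_vaf = 0L, benign = 0L))
  expect_equal(nrow(again$retained), nrow(out$retained))
  # applying the predicates in any order retains the same rows
  r1 <- !(!is.na(v$pop_freq) & v$pop_freq > 0.001)
  r2 <- !(!is.na(v$vaf) & v$vaf < 0.01)
  r3 <- !(!is.na(v$sift) & !is.na(v$polyphen2) &
            v$sift > 0.05 & v$polyphen2 <= 0.446)
  expect_equal(out$retained$patient_id, v$patient_id[r1 & r2 & r3])
  expect_error(filterVariants(variantRow(vaf = 1.5)), "row")
})

test_that("gene frequencies deduplicate patients and use the full cohort", {
  v <- rbind(variantRow(patient_id = "P1"),
             variantRow(patient_id = "P1", site = "T790M"),
             variantRow(patient_id = "P1", site = "del19"))
  gf <- geneFrequencies(v, 10)
  expect_equal(gf$patients, 1L)
  expect_equal(gf$pct, 10)
  expect_equal(nrow(geneFrequencies(v[0, ], 10)), 0L)
  # 261 mutated patients of 317 -> 82.33%
  many <- do.call(rbind, lapply(1:261, function(i) {
    variantRow(patient_id = paste0("P", i))
  }))
  expect_equal(anyMutationFrequency(many, 317)$pct, 82.33)
})

test_that("substitutions collapse to the six pyrimidine-reference classes", {
  expect_equal(as.character(classifySubstitution("C", "T")), "C>T")
  expect_equal(as.character(classifySubstitution("G", "A")), "C>T")
  # brute-force over all 12 ordered pairs: agreement with the lookup
  # oracle, and exactly 2 pairs per class
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- as.character(classifySubstitution(pairs$ref, pairs$alt))
  want <- mapply(bruteSubstitution, pairs$ref, pairs$alt)
  expect_equal(got, unname(want))
  expect_true(all(table(got) == 2))
  # reverse-complement invariance
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(got, as.character(
    classifySubstitution(comp[pairs$ref], comp[pairs$alt])))
  expect_error(classifySubstitution("C", "C"), "differ")
  expect_error(classifySubstitution("N", "A"), "invalid base")
})

test_that("EGFR site summary buckets per-patient site counts", {
  v <- rbind(
    variantRow(patient_id = "P1", site = "L858R"),
    variantRow(patient_id = "P2", site = "L858R"),
    variantRow(patient_id = "P2", site = "T790M"),
    variantRow(patient_id = "P3", site = "del19"),
    variantRow(patient_id = "P3", site = "T790M"),
    variantRow(patient_id = "P3", site = "C797S"),
    variantRow(patient_id = "P3", site = "L718Q"))
  s <- egfrSiteSummary(v)
  expect_equal(s$n_mutant, 3L)
  expect_equal(unname(s$site_count_pct), c(33.3, 33.3, 33.3))
  expect_equal(s$site_pct[["T790M"]], pct(2 / 3, 2))
  # all single-site -> bucket "1" is 100%
  s1 <- egfrSiteSummary(rbind(variantRow(patient_id = "P1"),
                              variantRow(patient_id = "P2")))
  expect_equal(unname(s1$site_count_pct), c(100, 0, 0))
})

test_that("association tests pick chi-squared or Fisher by expected counts", {
  # reported cohort table: gender vs MET amplification -> p = 1.000
  gender <- matrix(c(7, 43, 7, 39), 2)
  res <- associationTest(gender)
  expect_equal(res$method, "chisq")  # all expected counts >= 5
  expect_equal(res$p.value, 1.0)
  # symmetric table -> p = 1 regardless of branch
  expect_equal(associationTest(matrix(c(5, 5, 5, 5), 2))$p.value, 1.0)
  # sparse table routes to Fisher
  sparse <- matrix(c(1, 9, 8, 2), 2)
  expect_equal(associationTest(sparse)$method, "fisher")
  expect_error(associationTest(matrix(0, 2, 2)), "empty")
})

test_that("2x2 Fisher agrees with hypergeometric enumeration", {
  set.seed(17)
  for (rep in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    p <- associationTest(tab, method = "fisher")$p.value
    expect_equal(p, fisherEnum2x2(tab), tolerance = 1e-12)
  }
})

test_that("small 2x3 Fisher matches full enumeration with fixed margins", {
  enum2x3 <- function(tab) {
    r <- rowSums(tab); cns <- colSums(tab); n <- sum(tab)
    dens <- function(m) {
      exp(sum(lfactorial(r)) + sum(lfactorial(cns)) - lfactorial(n) -
            sum(lfactorial(m)))
    }
    dobs <- dens(tab)
    total <- 0
    for (a in 0:min(r[1], cns[1])) for (b in 0:min(r[1] - a, cns[2])) {
      cc <- r[1] - a - b
      if (cc < 0 || cc > cns[3]) next
      m <- rbind(c(a, b, cc), cns - c(a, b, cc))
      if (any(m < 0)) next
      if (dens(m) <= dobs * (1 + 1e-7)) total <- total + dens(m)
    }
    total
  }
  set.seed(19)
  for (rep in 1:10) {
    tab <- matrix(rpois(6, 2), 2, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- associationTest(tab, method = "fisher")$p.value
    expect_equal(p, enum2x3(tab), tolerance = 1e-7)
  }
})

test_that("pairwise comparisons report unadjusted p-values per group pair", {
  # identical group proportions -> all p near 1
  tab <- matrix(c(10, 10, 10, 10, 10, 10), 3,
                dimnames = list(metStatusLevels(), NULL))
  out <- pairwiseComparisons(tab)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$p.value > 0.99))
  expect_true(all(out$adjustment == "none"))
  # one fully mutated group versus fully unmutated groups
  tab2 <- matrix(c(6, 0, 0, 0, 6, 6), 3)
  out2 <- pairwiseComparisons(tab2)
  involving <- out2$group1 == "group1" | out2$group2 == "group1"
  expect_true(all(out2$p.value[involving] < 0.05))
  # reconstructed L858R table: omnibus chi-squared p < 0.01
  l858r <- matrix(c(7, 7, 11, 5, 17, 49), 2)
  expect_lt(associationTest(l858r)$p.value, 0.01)
})
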