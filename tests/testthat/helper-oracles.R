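# Independent oracles: naive-loop implementations used to cross-check the
# package's vectorised code. They share no code path with the package.

# Brute-force Youden cutoff: direct counting over every observed value,
# smallest threshold among ties.
bruteYouden <- function(values, positives) {
  best_j <- -Inf
  best_t <- NA_real_
  for (t in sort(unique(values))) {
    sens <- sum(values >= t & positives) / sum(positives)
    spec <- sum(values < t & !positives) / sum(!positives)
    j <- sens + spec - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  best_t
}

# Brute-force search over all 63 denominator subsets with per-gene
# brute-force Youden thresholds and a brute-force polysomy cutoff,
# returning the best 3-class agreement found. fish is a character vector.
bruteBestAgreement <- function(m, fish) {
  genes <- candidateDenominators()
  met <- m[, "MET"]
  ratios <- sapply(genes, function(g) m[, "MET"] / m[, g])
  pos <- fish == "AMPLIFICATION"
  thr <- sapply(genes, function(g) bruteYouden(ratios[, g], pos))
  best <- 0
  for (k in seq_along(genes)) {
    for (gs in combn(genes, k, simplify = FALSE)) {
      amp <- rep(TRUE, length(met))
      for (g in gs) amp <- amp & ratios[, g] >= thr[[g]]
      elig <- !amp & fish %in% c("POLYSOMY", "NEGATIVE")
      if (!any(fish[elig] == "POLYSOMY") ||
          !any(fish[elig] == "NEGATIVE")) {
        elig <- fish %in% c("POLYSOMY", "NEGATIVE")
      }
      cutoff <- bruteYouden(met[elig], fish[elig] == "POLYSOMY")
      ngs <- ifelse(amp, "AMPLIFICATION",
                    ifelse(met >= cutoff, "POLYSOMY", "NEGATIVE"))
      best <- max(best, mean(ngs == fish))
    }
  }
  best
}

# Random paired cohort for optimality checks: arbitrary positive copy
# numbers, labels guaranteed to cover all three classes.
randomTrainingCohort <- function(n) {
  m <- matrix(exp(rnorm(n * 7, log(2), 0.4)), n, 7,
              dimnames = list(NULL, panelGenes()))
  fish <- sample(metStatusLevels(), n, replace = TRUE)
  fish[1:3] <- metStatusLevels()  # force all classes present
  list(gcn = m, fish = fish)
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p for a
# 2x2 table (sum of probabilities of tables, at the observed margins, no
# more probable than the observed one).
fisherEnum2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  dobs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= dobs * (1 + 1e-7)])
}

# Reverse-complement substitution collapse by direct table lookup.
bruteSubstitution <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (ref %in% c("A", "G")) {
    ref <- comp[[ref]]
    alt <- comp[[alt]]
  }
  paste0(ref, ">", alt)
}
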