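#' Configuration for the synthetic paired-cohort generator
#'
#' Bundles and validates the generator parameters. Defaults mirror the
#' reference study conditions: class mix 14/96 amplification, 16/96
#' polysomy, 66/96 negative; tumor purity uniform on [0.2, 0.9]; focal
#' MET amplification at 6-30 tumor copies; polysomy at 3-6 copies of the
#' whole chromosome; additive Gaussian noise (sd 0.15 copies) on bulk
#' NGS copy number; 50 scored FISH nuclei per sample.
#'
#' @param n Cohort size.
#' @param class_probs Probabilities for (AMPLIFICATION, POLYSOMY,
#'   NEGATIVE), summing to 1.
#' @param purity_range Tumor-purity interval within (0, 1].
#' @param focal_met_range Integer range of tumor MET copies for
#'   amplified cases.
#' @param polysomy_range Integer range of whole-chromosome-7 copies for
#'   polysomy cases.
#' @param gcn_noise_sd Additive Gaussian sd on bulk copy number
#'   (copies); 0 switches the generator into the fully deterministic
#'   noise-free regime (see [simulateCohort()]).
#' @param nuclei_per_sample FISH nuclei scored per sample (>= 50).
#' @param seed Integer seed governing all draws.
#' @return Validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(n = 96L,
                         class_probs = c(AMPLIFICATION = 14, POLYSOMY = 16,
                                         NEGATIVE = 66) / 96,
                         purity_range = c(0.2, 0.9),
                         focal_met_range = c(6L, 30L),
                         polysomy_range = c(3L, 6L),
                         gcn_noise_sd = 0.15,
                         nuclei_per_sample = 50L,
                         seed = 1L) {
  cfg <- list(n = as.integer(n), class_probs = class_probs,
              purity_range = purity_range,
              focal_met_range = as.integer(focal_met_range),
              polysomy_range = as.integer(polysomy_range),
              gcn_noise_sd = gcn_noise_sd,
              nuclei_per_sample = as.integer(nuclei_per_sample),
              seed = as.integer(seed))
  if (cfg$n <= 0L) stop("invalid config: n must be positive")
  if (length(cfg$class_probs) != 3L || any(cfg$class_probs < 0) ||
      abs(sum(cfg$class_probs) - 1) > 1e-9) {
    stop("invalid config: class_probs must be 3 nonnegative values summing to 1")
  }
  names(cfg$class_probs) <- c("AMPLIFICATION", "POLYSOMY", "NEGATIVE")
  if (length(cfg$purity_range) != 2L || cfg$purity_range[1] <= 0 ||
      cfg$purity_range[2] > 1 || cfg$purity_range[1] > cfg$purity_range[2]) {
    stop("invalid config: purity_range must be an interval within (0, 1]")
  }
  for (fld in c("focal_met_range", "polysomy_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 1L) {
      stop("invalid config: ", fld, " must be a nonempty positive range")
    }
  }
  if (cfg$gcn_noise_sd < 0) stop("invalid config: gcn_noise_sd must be >= 0")
  if (cfg$nuclei_per_sample < 50L) {
    stop("invalid config: nuclei_per_sample must be >= 50")
  }
  class(cfg) <- "cohortConfig"
  cfg
}

## Tumor genotype for one sample: copies of each panel gene plus the
## chromosome-7 centromere (CEP7). Negative: diploid. Polysomy: the whole
## chromosome (all genes and CEP7) at k copies. Amplification: MET alone
## raised to m copies on a background chromosome count of 2 or 3.
.drawGenotype <- function(cls, cfg) {
  genes <- panelGenes()
  if (cls == "NEGATIVE") {
    copies <- setNames(rep(2, length(genes)), genes)
    cep7 <- 2
  } else if (cls == "POLYSOMY") {
    k <- sample(seq(cfg$polysomy_range[1], cfg$polysomy_range[2]), 1L)
    copies <- setNames(rep(k, length(genes)), genes)
    cep7 <- k
  } else {
    bg <- sample(2:3, 1L)
    m <- sample(seq(cfg$focal_met_range[1], cfg$focal_met_range[2]), 1L)
    copies <- setNames(rep(bg, length(genes)), genes)
    copies["MET"] <- m
    cep7 <- bg
  }
  list(copies = copies, cep7 = cep7)
}

#' Simulate a paired NGS + FISH cohort
#'
#' Draws, per sample: a truth class, a tumor purity, and a tumor
#' genotype (diploid; whole-chromosome-7 gain raising every panel gene
#' and CEP7 together; or focal MET gain leaving the other genes near
#' background). Bulk NGS copy number per gene is the purity-weighted
#' mixture of tumor and normal copies plus additive Gaussian noise,
#' floored at 0.1. FISH per-nucleus MET and CEP7 counts are Poisson with
#' means equal to the nucleus's (tumor or normal) copy numbers, floored
#' at one signal; each nucleus is a tumor nucleus with probability equal
#' to the purity, so normal-cell contamination dilutes both assays.
#'
#' When \code{gcn_noise_sd} is 0 the generator runs in the fully
#' deterministic noise-free regime used for analytic closure checks:
#' bulk copy numbers carry no Gaussian term and the FISH means are the
#' exact purity-weighted expectations (no Poisson sampling), so labels
#' follow analytically from the genotype.
#'
#' Output is fully determined by \code{config$seed}; per-sample
#' sub-seeds are drawn up-front, so cohorts sharing a seed share their
#' sample prefix regardless of \code{n}.
#'
#' @param config A [cohortConfig()].
#' @return A [MetPanelCohort-class] with the \code{"gcn"} assay,
#'   \code{colData} columns \code{truth}, \code{purity},
#'   \code{fish_mean_met}, \code{fish_mean_cep7}, and the config plus
#'   per-nucleus counts (stochastic regime only) in \code{metadata()}.
#' @examples
#' coh <- simulateCohort(cohortConfig(n = 20, seed = 42))
#' table(truthStatus(coh))
#' @export
simulateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  set.seed(config$seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, config$n,
                             replace = TRUE)
  genes <- panelGenes()
  gcn <- matrix(NA_real_, length(genes), config$n,
                dimnames = list(genes, sprintf("S%03d", seq_len(config$n))))
  truth <- character(config$n)
  purity <- numeric(config$n)
  mean_met <- numeric(config$n)
  mean_cep7 <- numeric(config$n)
  noise_free <- config$gcn_noise_sd == 0
  nuclei <- if (noise_free) NULL else vector("list", config$n)

  for (i in seq_len(config$n)) {
    set.seed(sample_seeds[i])
    cls <- sample(names(config$class_probs), 1L, prob = config$class_probs)
    rho <- stats::runif(1L, config$purity_range[1], config$purity_range[2])
    geno <- .drawGenotype(cls, config)
    bulk <- rho * geno$copies + (1 - rho) * 2
    if (!noise_free) {
      bulk <- bulk + stats::rnorm(length(bulk), 0, config$gcn_noise_sd)
    }
    gcn[, i] <- pmax(bulk, 0.1)
    truth[i] <- cls
    purity[i] <- rho
    if (noise_free) {
      mean_met[i] <- rho * geno$copies[["MET"]] + (1 - rho) * 2
      mean_cep7[i] <- rho * geno$cep7 + (1 - rho) * 2
    } else {
      nn <- config$nuclei_per_sample
      is_tumor <- stats::runif(nn) < rho
      met_mu <- ifelse(is_tumor, geno$copies[["MET"]], 2)
      cep_mu <- ifelse(is_tumor, geno$cep7, 2)
      met_ct <- pmax(stats::rpois(nn, met_mu), 1L)
      cep_ct <- pmax(stats::rpois(nn, cep_mu), 1L)
      nuclei[[i]] <- cbind(met_count = met_ct, cep7_count = cep_ct)
      mean_met[i] <- mean(met_ct)
      mean_cep7[i] <- mean(cep_ct)
    }
  }
  fish <- data.frame(sample_id = colnames(gcn), mean_met = mean_met,
                     mean_cep7 = mean_cep7)
  coh <- MetPanelCohort(gcn, fish = fish, truth = truth,
                        metadata = list(config = config, nuclei = nuclei))
  SummarizedExperiment::colData(coh)$purity <- purity
  coh
}

#' Simulate a cohort concentrated in the discordance-prone copy zone
#'
#' Low-purity, low-copy draws (purity 0.2-0.45; focal MET 5-8 copies;
#' polysomy 3-4 copies; class mix 40/40/20) place the bulk MET copy
#' number predominantly in [2, 5) — the zone where NGS/FISH calls
#' disagree — for stress-testing [agreementByGcn()].
#'
#' @param config A [cohortConfig()] supplying \code{n}, noise and seed;
#'   class mix, purity and copy ranges are overridden as above.
#' @return A [MetPanelCohort-class].
#' @export
simulateDiscordanceZone <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  cfg <- cohortConfig(
    n = config$n,
    class_probs = c(AMPLIFICATION = 0.4, POLYSOMY = 0.4, NEGATIVE = 0.2),
    purity_range = c(0.2, 0.45),
    focal_met_range = c(5L, 8L),
    polysomy_range = c(3L, 4L),
    gcn_noise_sd = config$gcn_noise_sd,
    nuclei_per_sample = config$nuclei_per_sample,
    seed = config$seed)
  simulateCohort(cfg)
}

.EGFR_SITES <- c(del19 = 0.4842, L858R = 0.4684, T790M = 0.1789,
                 A750P = 0.0263, C797S = 0.0211, E709K = 0.0105,
                 L718Q = 0.0105)
.FORM_PROBS <- c(missense = 0.62, nonsense = 0.10, nonstop = 0.02,
                 frameshift_inframe = 0.18, splicing = 0.08)
.SUBST_PROBS <- c("C>T" = 0.411, "C>A" = 0.15, "C>G" = 0.09,
                  "T>C" = 0.17, "T>A" = 0.08, "T>G" = 0.10)

## Default per-gene mutation probabilities: the most frequently mutated
## genes of the reference osimertinib-resistance cohort.
.DEFAULT_GENE_PROBS <- c(EGFR = 0.5994, TP53 = 0.4385, NRG1 = 0.0946,
                         PIK3CA = 0.0631, ATM = 0.0536, APC = 0.0442,
                         ARID1A = 0.0442, BRAF = 0.0410, NTRK1 = 0.0410,
                         POLE = 0.0410, KRAS = 0.0379)

## One clean annotation block: never triggers any filter rule. Whenever
## SIFT reads benign (> 0.05), PolyPhen2 reads damaging (> 0.446), so
## the both-benign conjunction cannot fire; a quarter of records lack
## one score (unknown significance).
.cleanScores <- function() {
  vaf <- max(stats::rbeta(1L, 2, 6), 0.01)
  pop <- if (stats::runif(1L) < 0.8) NA_real_ else stats::runif(1L, 0, 0.001)
  u <- stats::runif(1L)
  if (u < 0.25) {
    sift <- if (stats::runif(1L) < 0.5) NA_real_ else stats::runif(1L)
    poly <- if (is.na(sift)) stats::runif(1L) else NA_real_
  } else if (u < 0.75) {
    sift <- stats::runif(1L, 0, 0.05)
    poly <- stats::runif(1L, 0.447, 1)
  } else {
    sift <- stats::runif(1L, 0.051, 1)
    poly <- stats::runif(1L, 0.447, 1)
  }
  list(vaf = vaf, pop_freq = pop, sift = sift, polyphen2 = poly)
}

#' Simulate an annotated somatic-variant table
#'
#' Per patient, Bernoulli draws decide which genes are mutated; EGFR
#' patients carry 1, 2 or 3 distinct sites (probabilities 0.658, 0.263,
#' 0.079) sampled from the hotspot spectrum (del19, L858R, T790M, ...).
#' Mutation forms and pyrimidine-reference substitution classes follow
#' the landscape of the reference cohort (62\% missense, 41\% C>T).
#' Filter-rule-violating records — germline-frequency, low-VAF and
#' both-predictions-benign — are injected at configurable rates so the
#' variant filter has work to do; at rate 0 every record survives
#' [filterVariants()].
#'
#' @param cohort_size Number of patients.
#' @param gene_probs Named per-gene mutation probabilities (default: the
#'   top recurrently mutated genes of the reference cohort).
#' @param violation_rates Named rates \code{germline}, \code{low_vaf},
#'   \code{benign} in [0, 1] (default 0.05 each), applied mutually
#'   exclusively per record.
#' @param seed Integer seed.
#' @return data.frame of variant records (see [filterVariants()] for
#'   the column contract).
#' @export
simulateVariantTable <- function(cohort_size,
                                 gene_probs = .DEFAULT_GENE_PROBS,
                                 violation_rates = c(germline = 0.05,
                                                     low_vaf = 0.05,
                                                     benign = 0.05),
                                 seed = 1L) {
  if (any(gene_probs < 0 | gene_probs > 1)) {
    stop("invalid probability: gene_probs must lie in [0, 1]")
  }
  vr <- violation_rates[c("germline", "low_vaf", "benign")]
  if (anyNA(vr) || any(vr < 0) || sum(vr) > 1) {
    stop("invalid probability: violation_rates must be named, ",
         "nonnegative, and sum to at most 1")
  }
  set.seed(as.integer(seed))
  rows <- list()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in seq_len(cohort_size)) {
    pid <- sprintf("P%04d", p)
    mutated <- names(gene_probs)[stats::runif(length(gene_probs)) <
                                   gene_probs]
    for (g in mutated) {
      if (g == "EGFR") {
        nsite <- sample(c(1L, 2L, 3L), 1L, prob = c(0.658, 0.263, 0.079))
        sites <- sample(names(.EGFR_SITES), nsite, prob = .EGFR_SITES)
      } else {
        sites <- paste0(g, ".site", sample.int(3L, 1L))
      }
      for (s in sites) {
        form <- sample(names(.FORM_PROBS), 1L, prob = .FORM_PROBS)
        if (form %in% c("missense", "nonsense", "nonstop")) {
          cls <- sample(names(.SUBST_PROBS), 1L, prob = .SUBST_PROBS)
          ref <- substr(cls, 1L, 1L)
          alt <- substr(cls, 3L, 3L)
          if (stats::runif(1L) < 0.5) {  # opposite strand
            ref <- comp[[ref]]
            alt <- comp[[alt]]
          }
        } else {
          ref <- NA_character_
          alt <- NA_character_
        }
        sc <- .cleanScores()
        u <- stats::runif(1L)
        if (u < vr[["germline"]]) {
          sc$pop_freq <- stats::runif(1L, 0.0011, 0.05)
        } else if (u < vr[["germline"]] + vr[["low_vaf"]]) {
          sc$vaf <- stats::runif(1L, 1e-4, 0.0099)
        } else if (u < sum(vr)) {
          sc$sift <- stats::runif(1L, 0.051, 1)
          sc$polyphen2 <- stats::runif(1L, 0, 0.446)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, gene = g, site = s, form = form,
          ref_base = ref, alt_base = alt, vaf = sc$vaf,
          pop_freq = sc$pop_freq, sift = sc$sift,
          polyphen2 = sc$polyphen2)
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(patient_id = character(), gene = character(),
                      site = character(), form = character(),
                      ref_base = character(), alt_base = character(),
                      vaf = numeric(), pop_freq = numeric(),
                      sift = numeric(), polyphen2 = numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
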