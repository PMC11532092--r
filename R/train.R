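#' ROC-derived cutoff (Youden's J) over observed values
#'
#' Picks the threshold for the rule \code{score >= t} that maximises
#' Youden's J = sensitivity + specificity - 1, searching over the
#' observed score values only (so fitted thresholds are always
#' reproducible data values). Among J-ties the smallest threshold is
#' returned.
#'
#' @param values Numeric vector of finite scores.
#' @param positives Logical vector, same length: TRUE for the positive
#'   class.
#' @return The selected threshold, with the achieved J as attribute
#'   \code{"youden"}.
#' @examples
#' rocCutoff(c(1.0, 1.1, 2.0, 2.5), c(FALSE, FALSE, TRUE, TRUE))  # 2.0
#' @export
rocCutoff <- function(values, positives) {
  if (length(values) != length(positives)) {
    stop("values and positives must have equal length")
  }
  positives <- as.logical(positives)
  if (any(!is.finite(values))) stop("values must be finite")
  if (!any(positives) || !any(!positives)) {
    stop("degenerate labels: need at least one positive and one negative")
  }
  cand <- sort(unique(values))
  sens <- vapply(cand, function(t) mean(values[positives] >= t), 0)
  spec <- vapply(cand, function(t) mean(values[!positives] < t), 0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1L]  # candidates ascending: smallest tie
  structure(cand[best], youden = j[best])
}

#' Fit amplification-gate thresholds for a set of denominator genes
#'
#' For each denominator gene independently, fits the MET/gene ratio
#' cutoff separating FISH-amplified samples from the pooled
#' polysomy/negative rest via [rocCutoff()]. Thresholds are per-gene
#' ROC fits; which genes to combine (by conjunction) is the enumerated
#' dimension of [trainRatioGateModel()], not a joint optimisation.
#'
#' @inheritParams metRatio
#' @param fish_labels FISH gold-standard labels, coercible by
#'   [metStatus()], aligned with the samples of \code{gcn}.
#' @param genes Character vector of denominator genes to fit.
#' @return Named numeric vector of thresholds (with per-gene
#'   \code{"youden"} attributes dropped).
#' @export
fitAmpGates <- function(gcn, fish_labels, genes) {
  fish <- metStatus(fish_labels)
  genes <- toupper(genes)
  pos <- fish == "AMPLIFICATION"
  vapply(genes, function(g) as.numeric(rocCutoff(metRatio(gcn, g), pos)),
         0)
}

#' Fit the MET-GCN polysomy cutoff
#'
#' ROC cutoff on MET copy number separating FISH POLYSOMY (positive)
#' from FISH NEGATIVE samples; other labels are excluded before fitting.
#'
#' @param met_gcn Numeric vector of MET copy numbers.
#' @param fish_labels Aligned FISH labels.
#' @return The fitted threshold.
#' @export
fitPolysomyCutoff <- function(met_gcn, fish_labels) {
  fish <- metStatus(fish_labels)
  keep <- fish %in% c("POLYSOMY", "NEGATIVE")
  if (!any(fish[keep] == "POLYSOMY") || !any(fish[keep] == "NEGATIVE")) {
    stop("degenerate labels: need both POLYSOMY and NEGATIVE samples")
  }
  as.numeric(rocCutoff(met_gcn[keep], fish[keep] == "POLYSOMY"))
}

## Evaluate one candidate gate subset; returns the fitted pieces and the
## full-cohort 3-class calls. The polysomy cutoff is refitted inside each
## candidate on the samples its gates leave non-amplified ("among the
## other cases"); if those lack a class, fall back to all FISH
## polysomy/negative samples (non-degenerate by the train precondition).
.evalCandidate <- function(ratios, met, fish, genes, gates) {
  amp <- rep(TRUE, length(met))
  for (g in genes) amp <- amp & (ratios[, g] >= gates[[g]])
  elig <- !amp & fish %in% c("POLYSOMY", "NEGATIVE")
  have_both <- any(fish[elig] == "POLYSOMY") && any(fish[elig] == "NEGATIVE")
  if (!have_both) elig <- fish %in% c("POLYSOMY", "NEGATIVE")
  cutoff <- as.numeric(rocCutoff(met[elig], fish[elig] == "POLYSOMY"))
  ngs <- ifelse(amp, "AMPLIFICATION",
                ifelse(met >= cutoff, "POLYSOMY", "NEGATIVE"))
  fish_amp <- fish == "AMPLIFICATION"
  list(cutoff = cutoff,
       agreement = mean(ngs == as.character(fish)),
       amp_sensitivity = if (any(fish_amp)) {
         mean(ngs[fish_amp] == "AMPLIFICATION")
       } else NA_real_)
}

#' Train a ratio-gate model by exhaustive subset enumeration
#'
#' Re-derives a [RatioGateModel-class] from a paired NGS + FISH cohort
#' using the two-step procedure: (1) per-gene ROC cutoffs (Youden's J on
#' observed ratio values) separating FISH amplification from the rest;
#' (2) exhaustive enumeration of all 63 nonempty subsets of the six
#' candidate denominator genes, each combined by conjunction, with the
#' MET-GCN polysomy cutoff refitted within each candidate on the samples
#' its gates call non-amplified. The candidate with the highest overall
#' three-class agreement with FISH wins; ties break by higher
#' amplification sensitivity, then fewer gates, then the
#' lexicographically smallest gene subset. The search is exhaustive and
#' deterministic.
#'
#' Agreement is evaluated on the training cohort itself (no
#' cross-validation), so the reported agreement is in-sample.
#'
#' @inheritParams fitAmpGates
#' @param genes Candidate denominator genes (default all six).
#' @return A [TrainingResult-class].
#' @examples
#' set.seed(1)
#' coh <- simulateCohort(cohortConfig(n = 60, gcn_noise_sd = 0,
#'   purity_range = c(1, 1), polysomy_range = c(5, 6), seed = 1))
#' res <- trainRatioGateModel(coh, truthStatus(coh))
#' trainingAgreement(res)
#' @export
trainRatioGateModel <- function(gcn, fish_labels,
                                genes = candidateDenominators()) {
  fish <- metStatus(fish_labels)
  m <- .gcnSamplesByGenes(gcn)
  if (length(fish) != nrow(m)) {
    stop("fish_labels length must match the number of samples")
  }
  missing_cls <- setdiff(metStatusLevels(), as.character(unique(fish)))
  if (length(missing_cls)) {
    stop("degenerate labels: FISH class(es) absent from cohort: ",
         paste(missing_cls, collapse = ", "))
  }
  genes <- toupper(genes)
  all_gates <- fitAmpGates(m, fish, genes)
  ratios <- vapply(genes, function(g) metRatio(m, g),
                   numeric(nrow(m)))
  met <- m[, "MET"]

  subsets <- unlist(lapply(seq_along(genes), function(k) {
    utils::combn(sort(genes), k, simplify = FALSE)
  }), recursive = FALSE)

  log_rows <- lapply(subsets, function(gs) {
    gates <- all_gates[gs]
    ev <- .evalCandidate(ratios, met, fish, gs, gates)
    data.frame(
      genes = paste(gs, collapse = ","),
      n_gates = length(gs),
      thresholds = paste(sprintf("%s=%.10g", gs, gates), collapse = ","),
      polysomy_cutoff = ev$cutoff,
      agreement = ev$agreement,
      amp_sensitivity = ev$amp_sensitivity)
  })
  log_df <- do.call(rbind, log_rows)

  ord <- order(-log_df$agreement, -log_df$amp_sensitivity,
               log_df$n_gates, log_df$genes)
  best <- log_df[ord[1L], ]
  best_genes <- strsplit(best$genes, ",")[[1L]]
  model <- RatioGateModel(all_gates[best_genes],
                          polysomyGcnThreshold = best$polysomy_cutoff)
  message("trainRatioGateModel: agreement is in-sample ",
          "(trained and evaluated on the same cohort)")
  new("TrainingResult", model = model, agreement = best$agreement,
      candidateLog = log_df)
}
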