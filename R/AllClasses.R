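#' @import methods
#' @importFrom stats setNames
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## Seven chromosome-7 genes on the targeted panel. MET is the numerator of
## every ratio gate; the other six are candidate denominators.
.PANEL_GENES <- c("MET", "EGFR", "BRAF", "CDK6", "PMS2", "ABCB1", "CYP3A4")
.DENOM_GENES <- setdiff(.PANEL_GENES, "MET")

## Canonical status levels in increasing severity; confusion matrices are
## displayed in the reverse (AMPLIFICATION first) order.
.MET_LEVELS <- c("NEGATIVE", "POLYSOMY", "AMPLIFICATION")
.MET_DISPLAY <- rev(.MET_LEVELS)

#' MET status level vocabulary
#'
#' The three-level categorical outcome of MET copy-number calling:
#' \code{NEGATIVE < POLYSOMY < AMPLIFICATION}. The total order supports
#' monotonicity reasoning: raising MET copy number can only move a call up
#' this order.
#'
#' @return Character vector of the three levels in increasing order.
#' @examples
#' metStatusLevels()
#' @export
metStatusLevels <- function() .MET_LEVELS

#' Coerce labels to the ordered MET status factor
#'
#' @param x Character vector (or factor) of status labels.
#' @return Ordered factor with levels \code{NEGATIVE < POLYSOMY <
#'   AMPLIFICATION}.
#' @examples
#' metStatus(c("NEGATIVE", "AMPLIFICATION"))
#' @export
metStatus <- function(x) {
  x <- toupper(as.character(x))
  bad <- !is.na(x) & !(x %in% .MET_LEVELS)
  if (any(bad)) {
    stop("unknown MET status label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = .MET_LEVELS, ordered = TRUE)
}

#' Candidate denominator genes for ratio gates
#'
#' @return The six chromosome-7 panel genes usable as ratio-gate
#'   denominators (all panel genes except MET).
#' @examples
#' candidateDenominators()
#' @export
candidateDenominators <- function() .DENOM_GENES

#' Chromosome-7 panel genes
#'
#' @return The seven panel gene symbols, MET first.
#' @export
panelGenes <- function() .PANEL_GENES

#' Ratio-gate model for MET status calling
#'
#' A \code{RatioGateModel} holds a conjunction of amplification gates —
#' rules of the form \eqn{CN(MET)/CN(gene) \ge t_{gene}} — plus a MET
#' copy-number cutoff separating polysomy from negative among samples the
#' gates do not call amplified. All comparisons are inclusive
#' (\eqn{\ge}).
#'
#' @slot gates Named numeric vector: denominator gene symbol to ratio
#'   threshold (dimensionless, > 0). MET is never a denominator.
#' @slot polysomyGcnThreshold Single positive numeric: MET copy number at
#'   or above which a non-amplified sample is called POLYSOMY.
#' @seealso [publishedModel()], [classifyNgs()], [trainRatioGateModel()]
#' @exportClass RatioGateModel
setClass("RatioGateModel",
  representation(gates = "numeric", polysomyGcnThreshold = "numeric"))

setValidity("RatioGateModel", function(object) {
  g <- object@gates
  msgs <- character()
  if (length(g) == 0L) msgs <- c(msgs, "gates must be nonempty")
  if (is.null(names(g)) || any(!nzchar(names(g)))) {
    msgs <- c(msgs, "gates must be a named numeric vector")
  } else {
    if (anyDuplicated(names(g))) msgs <- c(msgs, "duplicate gate genes")
    bad <- setdiff(names(g), .DENOM_GENES)
    if (length(bad)) {
      msgs <- c(msgs, paste0("invalid denominator gene(s): ",
                             paste(bad, collapse = ", ")))
    }
  }
  if (any(!is.finite(g)) || any(g <= 0)) {
    msgs <- c(msgs, "gate thresholds must be finite and > 0")
  }
  p <- object@polysomyGcnThreshold
  if (length(p) != 1L || !is.finite(p) || p <= 0) {
    msgs <- c(msgs, "polysomyGcnThreshold must be a single finite value > 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RatioGateModel
#'
#' @param gates Named numeric vector of ratio thresholds, names drawn from
#'   [candidateDenominators()]. Gene names are upper-cased.
#' @param polysomyGcnThreshold MET copy-number cutoff for the polysomy
#'   gate.
#' @return A validated [RatioGateModel-class] object.
#' @examples
#' RatioGateModel(c(CYP3A4 = 1.5), polysomyGcnThreshold = 3)
#' @export
RatioGateModel <- function(gates, polysomyGcnThreshold) {
  gates <- setNames(as.numeric(gates), toupper(names(gates)))
  new("RatioGateModel", gates = gates,
      polysomyGcnThreshold = as.numeric(polysomyGcnThreshold))
}

#' The published ratio-gate model
#'
#' The gate model reported for the 96-patient paired NGS/FISH cohort:
#' a sample is called AMPLIFICATION when MET/CYP3A4 >= 1.12 and
#' MET/CDK6 >= 1.20 and MET/BRAF >= 1.53 all hold; among the remaining
#' samples, MET GCN >= 2.8 is called POLYSOMY, below that NEGATIVE.
#'
#' @return A constant [RatioGateModel-class]; every call returns an equal
#'   object.
#' @examples
#' publishedModel()
#' @export
publishedModel <- function() {
  RatioGateModel(c(CYP3A4 = 1.12, CDK6 = 1.20, BRAF = 1.53),
                 polysomyGcnThreshold = 2.8)
}

#' @describeIn RatioGateModel-class named vector of gate thresholds
#' @param x A \code{RatioGateModel}.
#' @export
gateThresholds <- function(x) {
  stopifnot(is(x, "RatioGateModel"))
  x@gates
}

#' @describeIn RatioGateModel-class MET-GCN polysomy cutoff
#' @export
polysomyThreshold <- function(x) {
  stopifnot(is(x, "RatioGateModel"))
  x@polysomyGcnThreshold
}

setMethod("show", "RatioGateModel", function(object) {
  cat("RatioGateModel with", length(object@gates), "amplification gate(s)\n")
  for (g in names(object@gates)) {
    cat(sprintf("  MET/%s >= %g\n", g, object@gates[[g]]))
  }
  cat(sprintf("  polysomy: MET GCN >= %g\n", object@polysomyGcnThreshold))
})

#' FISH-versus-NGS confusion summary
#'
#' A 3x3 contingency table of per-sample calls, rows the FISH
#' (gold-standard) label and columns the NGS call, both ordered
#' AMPLIFICATION, POLYSOMY, NEGATIVE.
#'
#' @slot counts 3x3 nonnegative integer matrix.
#' @slot n Total sample count (sum of all cells).
#' @seealso [confusionSummary()], [overallAgreement()], [oneVsRest()]
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
  representation(counts = "matrix", n = "integer"))

setValidity("ConfusionSummary", function(object) {
  m <- object@counts
  msgs <- character()
  if (!all(dim(m) == c(3L, 3L))) msgs <- c(msgs, "counts must be 3x3")
  if (!identical(rownames(m), .MET_DISPLAY) ||
      !identical(colnames(m), .MET_DISPLAY)) {
    msgs <- c(msgs, "dimnames must be AMPLIFICATION, POLYSOMY, NEGATIVE")
  }
  if (any(m < 0) || any(m != round(m))) {
    msgs <- c(msgs, "cells must be nonnegative integers")
  }
  if (sum(m) != object@n) msgs <- c(msgs, "n must equal the cell sum")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ConfusionSummary", function(object) {
  cat("ConfusionSummary (rows FISH, columns NGS), n =", object@n, "\n")
  print(object@counts)
})

#' @describeIn ConfusionSummary-class the 3x3 count matrix (rows FISH,
#'   columns NGS)
#' @param x A \code{ConfusionSummary}.
#' @export
confusionCounts <- function(x) {
  stopifnot(is(x, "ConfusionSummary"))
  x@counts
}

#' @describeIn ConfusionSummary-class total number of paired samples
#' @export
nSamples <- function(x) {
  stopifnot(is(x, "ConfusionSummary"))
  x@n
}

#' Result of gate-model training
#'
#' Returned by [trainRatioGateModel()]: the best model found by exhaustive
#' enumeration of denominator-gene subsets, its in-sample three-class
#' agreement with FISH, and the full per-candidate log (one row per
#' nonempty subset of the six candidate denominators, 63 rows).
#'
#' @slot model The winning [RatioGateModel-class].
#' @slot agreement In-sample three-class agreement of \code{model} with
#'   the FISH labels, in [0, 1].
#' @slot candidateLog data.frame with one row per evaluated subset:
#'   \code{genes} (comma-separated), \code{n_gates}, \code{thresholds}
#'   (comma-separated \code{gene=value}), \code{polysomy_cutoff},
#'   \code{agreement}, \code{amp_sensitivity}.
#' @exportClass TrainingResult
setClass("TrainingResult",
  representation(model = "RatioGateModel", agreement = "numeric",
                 candidateLog = "data.frame"))

setValidity("TrainingResult", function(object) {
  msgs <- character()
  if (length(object@agreement) != 1L ||
      object@agreement < 0 || object@agreement > 1) {
    msgs <- c(msgs, "agreement must be a single value in [0, 1]")
  }
  if (nrow(object@candidateLog) &&
      abs(object@agreement - max(object@candidateLog$agreement)) > 1e-12) {
    msgs <- c(msgs, "agreement must equal the best candidate's agreement")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TrainingResult", function(object) {
  cat("TrainingResult:", nrow(object@candidateLog),
      "candidate gate subsets evaluated\n")
  cat(sprintf("  best agreement with FISH: %.4f (in-sample)\n",
              object@agreement))
  show(object@model)
})

#' @describeIn TrainingResult-class the winning model
#' @param x A \code{TrainingResult}.
#' @export
fittedModel <- function(x) {
  stopifnot(is(x, "TrainingResult"))
  x@model
}

#' @describeIn TrainingResult-class in-sample agreement of the winning
#'   model
#' @export
trainingAgreement <- function(x) {
  stopifnot(is(x, "TrainingResult"))
  x@agreement
}

#' @describeIn TrainingResult-class per-candidate enumeration log
#' @export
candidateLog <- function(x) {
  stopifnot(is(x, "TrainingResult"))
  x@candidateLog
}

#' Paired NGS + FISH cohort container
#'
#' A \code{MetPanelCohort} extends
#' \linkS4class{SummarizedExperiment}: the \code{"gcn"} assay holds the
#' panel-gene copy-number matrix (genes x samples, diploid baseline 2),
#' and \code{colData} carries per-sample FISH mean signal counts
#' (\code{fish_mean_met}, \code{fish_mean_cep7}), the simulation truth
#' label (\code{truth}) and tumor purity when the object came from
#' [simulateCohort()].
#'
#' @seealso [simulateCohort()], [classifyNgs()], [classifyFish()]
#' @exportClass MetPanelCohort
setClass("MetPanelCohort", contains = "SummarizedExperiment")

setValidity("MetPanelCohort", function(object) {
  msgs <- character()
  if (!"gcn" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "must carry a 'gcn' assay")
  } else {
    g <- SummarizedExperiment::assay(object, "gcn")
    if (!"MET" %in% rownames(g)) msgs <- c(msgs, "gcn assay must include MET")
    vals <- g[!is.na(g)]
    if (length(vals) && (any(!is.finite(vals)) || any(vals <= 0))) {
      msgs <- c(msgs, "present copy numbers must be finite and > 0")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetPanelCohort
#'
#' @param gcn Numeric matrix of copy numbers, genes x samples (gene
#'   symbols as rownames, upper-cased on ingestion) or samples x genes
#'   with a warning-free transpose when sample ids are rownames. A
#'   data.frame with a \code{sample_id} column (as returned by
#'   [readGcnTable()]) is also accepted.
#' @param fish Optional data.frame with columns \code{sample_id},
#'   \code{mean_met}, \code{mean_cep7}, matched to samples by id.
#' @param truth Optional character/factor of simulation truth labels.
#' @param ... Further arguments passed to the
#'   \code{SummarizedExperiment} constructor (e.g. \code{metadata}).
#' @return A [MetPanelCohort-class].
#' @export
MetPanelCohort <- function(gcn, fish = NULL, truth = NULL, ...) {
  if (is.data.frame(gcn)) gcn <- .gcnFrameToMatrix(gcn)
  rownames(gcn) <- toupper(rownames(gcn))
  cd <- S4Vectors::DataFrame(row.names = colnames(gcn))
  if (!is.null(fish)) {
    idx <- match(colnames(gcn), fish$sample_id)
    cd$fish_mean_met <- fish$mean_met[idx]
    cd$fish_mean_cep7 <- fish$mean_cep7[idx]
  }
  if (!is.null(truth)) cd$truth <- metStatus(truth)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(gcn = gcn), colData = cd, ...)
  new("MetPanelCohort", se)
}

## samples x genes data.frame (sample_id column) -> genes x samples matrix
.gcnFrameToMatrix <- function(df) {
  stopifnot("sample_id" %in% names(df))
  genes <- setdiff(names(df), "sample_id")
  m <- t(as.matrix(df[, genes, drop = FALSE]))
  colnames(m) <- df$sample_id
  rownames(m) <- toupper(genes)
  storage.mode(m) <- "double"
  m
}

#' @describeIn MetPanelCohort-class genes x samples copy-number matrix
#' @param x A \code{MetPanelCohort}.
#' @export
gcnAssay <- function(x) {
  stopifnot(is(x, "MetPanelCohort"))
  SummarizedExperiment::assay(x, "gcn")
}

#' @describeIn MetPanelCohort-class simulation truth labels (or NULL)
#' @export
truthStatus <- function(x) {
  stopifnot(is(x, "MetPanelCohort"))
  cd <- SummarizedExperiment::colData(x)
  if ("truth" %in% names(cd)) cd$truth else NULL
}

#' @describeIn MetPanelCohort-class per-sample FISH means as a data.frame
#'   (or NULL when absent)
#' @export
fishTable <- function(x) {
  stopifnot(is(x, "MetPanelCohort"))
  cd <- SummarizedExperiment::colData(x)
  if (!all(c("fish_mean_met", "fish_mean_cep7") %in% names(cd))) return(NULL)
  data.frame(sample_id = colnames(x),
             mean_met = cd$fish_mean_met,
             mean_cep7 = cd$fish_mean_cep7,
             row.names = NULL)
}
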