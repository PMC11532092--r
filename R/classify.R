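## Coerce the various accepted GCN inputs to a samples x genes matrix.
.gcnSamplesByGenes <- function(gcn) {
  if (is(gcn, "MetPanelCohort")) {
    m <- t(gcnAssay(gcn))
  } else if (is.data.frame(gcn)) {
    m <- t(.gcnFrameToMatrix(gcn))
  } else if (is.matrix(gcn)) {
    m <- gcn
    colnames(m) <- toupper(colnames(m))
  } else {
    stop("gcn must be a MetPanelCohort, a matrix or a data.frame")
  }
  if (!"MET" %in% colnames(m)) stop("missing gene: MET")
  m
}

#' MET/denominator copy-number ratio
#'
#' The NGS analogue of the FISH MET/CEP7 ratio: the MET copy number
#' divided by the copy number of another chromosome-7 panel gene. Under
#' whole-chromosome gain all panel genes rise together and the ratio
#' stays near 1; under focal MET gain the ratio rises with the
#' amplification level.
#'
#' @param gcn A [MetPanelCohort-class], a samples x genes numeric matrix,
#'   or a data.frame with a \code{sample_id} column and gene columns.
#' @param denom_gene Denominator gene symbol (one of
#'   [candidateDenominators()]).
#' @return Numeric vector of per-sample ratios, named by sample.
#' @examples
#' metRatio(cbind(MET = 8, CYP3A4 = 2), "CYP3A4")   # 4
#' @export
metRatio <- function(gcn, denom_gene) {
  m <- .gcnSamplesByGenes(gcn)
  denom_gene <- toupper(denom_gene)
  if (!denom_gene %in% colnames(m)) stop("missing gene: ", denom_gene)
  d <- m[, denom_gene]
  if (any(!is.na(d) & d <= 0)) {
    stop("undefined ratio: nonpositive ", denom_gene, " copy number")
  }
  m[, "MET"] / d
}

#' Call MET status from panel copy numbers with a ratio-gate model
#'
#' A sample is called AMPLIFICATION when every gate in the model is
#' satisfied (MET/gene ratio >= the gate's threshold, a pure
#' conjunction); otherwise POLYSOMY when the MET copy number is at or
#' above the model's polysomy cutoff; otherwise NEGATIVE. All
#' comparisons are inclusive. Samples missing any gate gene are a hard
#' error: a silently degraded call would corrupt downstream concordance
#' statistics.
#'
#' @inheritParams metRatio
#' @param model A [RatioGateModel-class]; defaults to [publishedModel()].
#' @return Ordered [metStatus()] factor, one call per sample, named by
#'   sample where names are available.
#' @examples
#' gcn <- rbind(S1 = c(MET = 8, CYP3A4 = 2, CDK6 = 2, BRAF = 2),
#'              S2 = c(MET = 3, CYP3A4 = 2.8, CDK6 = 2.9, BRAF = 2.9),
#'              S3 = c(MET = 2, CYP3A4 = 2, CDK6 = 2, BRAF = 2))
#' classifyNgs(gcn)
#' @export
classifyNgs <- function(gcn, model = publishedModel()) {
  stopifnot(is(model, "RatioGateModel"))
  m <- .gcnSamplesByGenes(gcn)
  gates <- gateThresholds(model)
  absent <- setdiff(c("MET", names(gates)), colnames(m))
  if (length(absent)) {
    stop("missing gene(s) required by the model: ",
         paste(absent, collapse = ", "))
  }
  need <- m[, c("MET", names(gates)), drop = FALSE]
  if (anyNA(need)) {
    bad <- rownames(need)[apply(is.na(need), 1L, any)]
    stop("missing copy numbers for gate gene(s) in sample(s): ",
         paste(bad, collapse = ", "))
  }
  amp <- rep(TRUE, nrow(m))
  for (g in names(gates)) {
    amp <- amp & (metRatio(m, g) >= gates[[g]])
  }
  met <- m[, "MET"]
  out <- ifelse(amp, "AMPLIFICATION",
                ifelse(met >= polysomyThreshold(model),
                       "POLYSOMY", "NEGATIVE"))
  names(out) <- rownames(m)
  metStatus(out)
}
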