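#' MET/CEP7 FISH signal ratio
#'
#' The ratio of mean MET signals to mean CEP7 (chromosome-7 centromere)
#' signals per nucleus, the quantity that separates focal MET gain from
#' whole-chromosome gain: focal amplification raises MET signals without
#' raising the centromere count, polysomy raises both together.
#'
#' @param mean_met Numeric vector of mean MET signals per nucleus.
#' @param mean_cep7 Numeric vector of mean CEP7 signals per nucleus;
#'   must be > 0.
#' @return \code{mean_met / mean_cep7}, recycled elementwise.
#' @examples
#' fishRatio(10, 4)   # 2.5
#' @export
fishRatio <- function(mean_met, mean_cep7) {
  if (any(!is.finite(mean_cep7)) || any(mean_cep7 <= 0)) {
    stop("undefined MET/CEP7 ratio: mean_cep7 must be finite and > 0")
  }
  mean_met / mean_cep7
}

#' Gold-standard FISH classification of MET status
#'
#' Applies the dual-probe FISH criteria: AMPLIFICATION when the MET/CEP7
#' ratio is >= 2; otherwise POLYSOMY when the mean MET signal count per
#' nucleus is >= 5 (ratio < 2 "synchronously"); otherwise NEGATIVE. Both
#' cutoffs are inclusive.
#'
#' @inheritParams fishRatio
#' @param ratio_cutoff MET/CEP7 ratio at or above which a sample is
#'   amplified (default 2).
#' @param gcn_cutoff Mean MET signal count at or above which a
#'   non-amplified sample is polysomy (default 5).
#' @return Ordered [metStatus()] factor, one call per sample.
#' @examples
#' classifyFish(c(10, 6, 4), c(4, 4, 4))
#' @export
classifyFish <- function(mean_met, mean_cep7, ratio_cutoff = 2,
                         gcn_cutoff = 5) {
  r <- fishRatio(mean_met, mean_cep7)
  out <- ifelse(r >= ratio_cutoff, "AMPLIFICATION",
                ifelse(mean_met >= gcn_cutoff, "POLYSOMY", "NEGATIVE"))
  metStatus(out)
}

#' Summarise per-nucleus FISH counts into per-sample means
#'
#' Collapses a long-format per-nucleus count table into the per-sample
#' mean MET and CEP7 signal counts used by [classifyFish()]. At least 50
#' non-overlapping nuclei per sample are required, matching standard
#' dual-probe scoring practice; any stored means are ignored in favour of
#' the recomputed ones (single source of truth).
#'
#' @param nuclei data.frame with columns \code{sample_id},
#'   \code{met_count} (nonnegative integers) and \code{cep7_count}
#'   (positive integers).
#' @param min_nuclei Minimum nuclei per sample (default 50).
#' @return data.frame with columns \code{sample_id}, \code{n_nuclei},
#'   \code{mean_met}, \code{mean_cep7}.
#' @export
fishFromNuclei <- function(nuclei, min_nuclei = 50L) {
  req <- c("sample_id", "met_count", "cep7_count")
  miss <- setdiff(req, names(nuclei))
  if (length(miss)) {
    stop("per-nucleus table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(nuclei$met_count < 0)) stop("met_count must be nonnegative")
  if (any(nuclei$cep7_count <= 0)) stop("cep7_count must be positive")
  sp <- split(nuclei, nuclei$sample_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(sample_id = d$sample_id[1L], n_nuclei = nrow(d),
               mean_met = mean(d$met_count),
               mean_cep7 = mean(d$cep7_count))
  }))
  rownames(out) <- NULL
  short <- out$n_nuclei < min_nuclei
  if (any(short)) {
    stop("fewer than ", min_nuclei, " nuclei for sample(s): ",
         paste(out$sample_id[short], collapse = ", "))
  }
  out
}
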