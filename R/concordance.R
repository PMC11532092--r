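#' Round half-up and format a proportion as a percentage
#'
#' Percentages are reported with half-up rounding (so 73.9583\% prints
#' as 74.0 at one decimal), matching clinical-report conventions rather
#' than R's banker's rounding.
#'
#' @param p Proportion(s) in [0, 1].
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s).
#' @examples
#' pct(71 / 96)        # 74.0
#' pct(261 / 317, 2)   # 82.33
#' @export
pct <- function(p, digits = 1L) {
  floor(p * 100 * 10^digits + 0.5) / 10^digits
}

#' Build a FISH-versus-NGS confusion summary
#'
#' @param fish_labels,ngs_labels Equal-length label vectors (coercible by
#'   [metStatus()]), aligned by sample.
#' @return A [ConfusionSummary-class] with rows the FISH label and
#'   columns the NGS call, both ordered AMPLIFICATION, POLYSOMY,
#'   NEGATIVE.
#' @examples
#' confusionSummary(rep("AMPLIFICATION", 3), rep("AMPLIFICATION", 3))
#' @export
confusionSummary <- function(fish_labels, ngs_labels) {
  if (length(fish_labels) != length(ngs_labels)) {
    stop("fish_labels and ngs_labels must have equal length")
  }
  f <- factor(as.character(metStatus(fish_labels)), levels = .MET_DISPLAY)
  g <- factor(as.character(metStatus(ngs_labels)), levels = .MET_DISPLAY)
  m <- table(FISH = f, NGS = g)
  m <- matrix(as.integer(m), 3L, 3L,
              dimnames = list(.MET_DISPLAY, .MET_DISPLAY))
  new("ConfusionSummary", counts = m, n = sum(m))
}

#' Construct a ConfusionSummary from known cell counts
#'
#' Convenience constructor for reconstructed matrices (e.g. a diagonal
#' implied by printed per-class sensitivities and class sizes).
#'
#' @param counts 3x3 matrix of nonnegative integers, rows FISH and
#'   columns NGS, both in AMPLIFICATION, POLYSOMY, NEGATIVE order.
#' @return A [ConfusionSummary-class].
#' @export
confusionFromCounts <- function(counts) {
  counts <- matrix(as.integer(round(counts)), 3L, 3L,
                   dimnames = list(.MET_DISPLAY, .MET_DISPLAY))
  new("ConfusionSummary", counts = counts, n = sum(counts))
}

#' One-vs-rest sensitivity and specificity for a status class
#'
#' Sensitivity is the fraction of FISH-\code{cls} samples that NGS also
#' calls \code{cls}; specificity the fraction of FISH-not-\code{cls}
#' samples that NGS calls not-\code{cls}. A zero denominator yields NA
#' with a warning rather than an error.
#'
#' @param x A [ConfusionSummary-class].
#' @param cls One of [metStatusLevels()].
#' @return Named numeric: \code{sensitivity}, \code{specificity} (as
#'   fractions).
#' @examples
#' m <- diag(c(12, 6, 53)); m[1, 3] <- 2; m[2, 3] <- 10; m[3, 1] <- 13
#' oneVsRest(confusionFromCounts(m), "AMPLIFICATION")
#' @export
oneVsRest <- function(x, cls) {
  stopifnot(is(x, "ConfusionSummary"))
  cls <- match.arg(toupper(cls), .MET_DISPLAY)
  m <- x@counts
  row_sum <- sum(m[cls, ])
  rest <- setdiff(.MET_DISPLAY, cls)
  rest_n <- sum(m[rest, ])
  sens <- if (row_sum > 0) m[cls, cls] / row_sum else {
    warning("sensitivity undefined: no FISH ", cls, " samples")
    NA_real_
  }
  spec <- if (rest_n > 0) sum(m[rest, rest]) / rest_n else {
    warning("specificity undefined: no FISH non-", cls, " samples")
    NA_real_
  }
  c(sensitivity = sens, specificity = spec)
}

#' Overall FISH/NGS agreement with exact binomial confidence interval
#'
#' The fraction of samples where the NGS call equals the FISH label
#' (trace / n), with a two-sided 95\% Clopper-Pearson exact binomial
#' interval. The exact interval is used because agreement counts are
#' small-n binomial outcomes where asymptotic intervals undercover.
#'
#' @param x A [ConfusionSummary-class].
#' @param conf_level Confidence level (default 0.95).
#' @return List with \code{proportion}, \code{ci_low}, \code{ci_high}
#'   (fractions), \code{concordant} and \code{n}.
#' @examples
#' s <- confusionFromCounts(diag(c(12, 6, 53)) +
#'   matrix(c(0, 0, 2, 1, 0, 9, 13, 0, 0), 3))
#' overallAgreement(s)
#' @export
overallAgreement <- function(x, conf_level = 0.95) {
  stopifnot(is(x, "ConfusionSummary"))
  n <- x@n
  if (n == 0L) stop("empty summary: n = 0")
  k <- sum(diag(x@counts))
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(proportion = k / n, ci_low = ci[1L], ci_high = ci[2L],
       concordant = k, n = n)
}

#' FISH/NGS agreement stratified by MET copy number
#'
#' Bins samples by their NGS MET copy number into half-open bins
#' \code{[e_i, e_{i+1})} delimited by \code{bin_edges}, with an initial
#' \code{(-Inf, e_1)} bin and a terminal \code{[e_last, Inf)} bin, and
#' reports per-bin sample count and FISH/NGS agreement. Default edges
#' (2, 5) separate the near-diploid zone, the 2-5 zone where NGS/FISH
#' discordance concentrates, and the high-copy zone where the two
#' assays agree.
#'
#' @param met_gcn Numeric vector of MET copy numbers.
#' @param fish_labels,ngs_labels Aligned label vectors.
#' @param bin_edges Strictly increasing numeric edges (default
#'   \code{c(2, 5)}).
#' @return data.frame with columns \code{bin}, \code{n},
#'   \code{agreement} (NA for empty bins).
#' @export
agreementByGcn <- function(met_gcn, fish_labels, ngs_labels,
                           bin_edges = c(2, 5)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  if (length(met_gcn) != length(fish_labels) ||
      length(met_gcn) != length(ngs_labels)) {
    stop("met_gcn and label vectors must have equal length")
  }
  conc <- as.character(metStatus(fish_labels)) ==
    as.character(metStatus(ngs_labels))
  idx <- findInterval(met_gcn, bin_edges) + 1L
  edges <- c(-Inf, bin_edges, Inf)
  labels <- vapply(seq_len(length(edges) - 1L), function(i) {
    sprintf("[%g, %g)", edges[i], edges[i + 1L])
  }, "")
  out <- data.frame(bin = labels, n = 0L, agreement = NA_real_)
  for (i in seq_along(labels)) {
    in_bin <- idx == i
    out$n[i] <- sum(in_bin)
    if (out$n[i] > 0L) out$agreement[i] <- mean(conc[in_bin])
  }
  out
}

#' Collapse a 3x3 confusion summary to positive-vs-rest
#'
#' Merges the two non-positive classes (rows and columns) into a single
#' "rest" group, conserving all counts; confusions between the merged
#' classes become concordant rest/rest cells, so collapsing never
#' lowers agreement.
#'
#' @param x A [ConfusionSummary-class].
#' @param positive_class The class kept separate (default
#'   AMPLIFICATION, the clinically actionable call).
#' @return 2x2 integer matrix with dimnames \code{c(positive, "REST")},
#'   rows FISH and columns NGS.
#' @export
collapseToBinary <- function(x, positive_class = "AMPLIFICATION") {
  stopifnot(is(x, "ConfusionSummary"))
  positive_class <- match.arg(toupper(positive_class), .MET_DISPLAY)
  m <- x@counts
  rest <- setdiff(.MET_DISPLAY, positive_class)
  out <- matrix(0L, 2L, 2L,
                dimnames = list(c(positive_class, "REST"),
                                c(positive_class, "REST")))
  out[1L, 1L] <- m[positive_class, positive_class]
  out[1L, 2L] <- sum(m[positive_class, rest])
  out[2L, 1L] <- sum(m[rest, positive_class])
  out[2L, 2L] <- sum(m[rest, rest])
  out
}
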