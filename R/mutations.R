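.VARIANT_COLS <- c("patient_id", "gene", "site", "form", "ref_base",
                   "alt_base", "vaf", "pop_freq", "sift", "polyphen2")
.MUTATION_FORMS <- c("missense", "nonsense", "nonstop",
                     "frameshift_inframe", "splicing")
.SUBSTITUTION_CLASSES <- c("C>T", "C>A", "C>G", "T>C", "T>A", "T>G")

## Validate a variant table; row indices are reported on failure so a
## malformed record can be located in the source file.
.checkVariants <- function(records) {
  miss <- setdiff(.VARIANT_COLS, names(records))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("vaf", "pop_freq", "sift", "polyphen2")) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad)) {
      stop("malformed record: ", col, " outside [0, 1] at row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  both <- !is.na(records$ref_base) & !is.na(records$alt_base)
  bad <- which(both & records$ref_base == records$alt_base)
  if (length(bad)) {
    stop("malformed record: ref_base equals alt_base at row(s) ",
         paste(bad, collapse = ", "))
  }
  invisible(records)
}

#' Filter annotated somatic variants
#'
#' Applies the three post-annotation filters, in order: (1) germline
#' removal — population allele frequency > 0.001; (2) low support —
#' VAF < 0.01; (3) predicted harmless — removed only when BOTH
#' predictions are present and benign (SIFT > 0.05 AND PolyPhen2
#' <= 0.446). A variant with either score missing survives rule 3: the
#' retained set is deleterious, likely deleterious or of unknown
#' significance. The retained set is order-independent (each rule is a
#' pure predicate) but the per-rule removal counts follow the stated
#' order.
#'
#' @param records data.frame of annotated variants with columns
#'   \code{patient_id, gene, site, form, ref_base, alt_base, vaf,
#'   pop_freq, sift, polyphen2} (scores in [0, 1], NA when missing).
#' @param max_pop_freq Germline population-frequency cutoff (default
#'   0.001, i.e. 0.1\%).
#' @param min_vaf Minimum variant allele frequency (default 0.01).
#' @param sift_benign SIFT score strictly above which a call is benign
#'   (default 0.05).
#' @param polyphen_benign PolyPhen2 score at or below which a call is
#'   benign (default 0.446).
#' @return List: \code{retained} (the surviving rows) and \code{removed}
#'   (named integer vector \code{germline}, \code{low_vaf},
#'   \code{benign}).
#' @examples
#' v <- data.frame(patient_id = "P1", gene = "EGFR", site = "L858R",
#'   form = "missense", ref_base = "T", alt_base = "G", vaf = 0.3,
#'   pop_freq = NA_real_, sift = 0.01, polyphen2 = 0.99)
#' filterVariants(v)$removed
#' @export
filterVariants <- function(records, max_pop_freq = 0.001, min_vaf = 0.01,
                           sift_benign = 0.05, polyphen_benign = 0.446) {
  .checkVariants(records)
  germline <- !is.na(records$pop_freq) & records$pop_freq > max_pop_freq
  r <- records[!germline, , drop = FALSE]
  low_vaf <- !is.na(r$vaf) & r$vaf < min_vaf
  r <- r[!low_vaf, , drop = FALSE]
  benign <- !is.na(r$sift) & !is.na(r$polyphen2) &
    r$sift > sift_benign & r$polyphen2 <= polyphen_benign
  retained <- r[!benign, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       removed = c(germline = sum(germline), low_vaf = sum(low_vaf),
                   benign = sum(benign)))
}

#' Per-gene mutation frequencies
#'
#' Fraction of the cohort with at least one retained variant in each
#' gene, deduplicated within patient, as percentages rounded half-up to
#' two decimals.
#'
#' @param retained data.frame of retained variants (\code{patient_id},
#'   \code{gene} required).
#' @param cohort_size Total number of patients in the cohort (the
#'   denominator; patients without variants do not appear in
#'   \code{retained}).
#' @return data.frame with columns \code{gene}, \code{patients},
#'   \code{pct}, sorted by descending frequency.
#' @seealso [anyMutationFrequency()]
#' @export
geneFrequencies <- function(retained, cohort_size) {
  if (cohort_size <= 0) stop("cohort_size must be > 0")
  if (nrow(retained) == 0L) {
    return(data.frame(gene = character(), patients = integer(),
                      pct = numeric()))
  }
  counts <- tapply(retained$patient_id, retained$gene,
                   function(p) length(unique(p)))
  out <- data.frame(gene = names(counts),
                    patients = as.integer(counts),
                    pct = pct(as.integer(counts) / cohort_size, 2L))
  out <- out[order(-out$patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of patients carrying any retained variant
#'
#' @inheritParams geneFrequencies
#' @return List: \code{patients} (count with >= 1 retained variant) and
#'   \code{pct} (percentage, two decimals, half-up).
#' @examples
#' # 261 of 317 patients mutated -> 82.33%
#' v <- data.frame(patient_id = paste0("P", 1:261), gene = "EGFR")
#' anyMutationFrequency(v, 317)
#' @export
anyMutationFrequency <- function(retained, cohort_size) {
  if (cohort_size <= 0) stop("cohort_size must be > 0")
  k <- length(unique(retained$patient_id))
  list(patients = k, pct = pct(k / cohort_size, 2L))
}

#' Pyrimidine-reference substitution class
#'
#' Collapses each single-base substitution to its pyrimidine-reference
#' representative (a substitution and its reverse complement are the
#' same biological event read from opposite strands), giving the six
#' classes C>T, C>A, C>G, T>C, T>A, T>G.
#'
#' @param ref_base,alt_base Character vectors of single upper-case DNA
#'   bases, pairwise unequal.
#' @return Factor over the six substitution classes.
#' @examples
#' classifySubstitution("G", "A")   # C>T (reverse-complement collapse)
#' @export
classifySubstitution <- function(ref_base, alt_base) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  ok <- ref_base %in% names(comp) & alt_base %in% names(comp)
  if (any(!ok)) {
    stop("invalid base(s): ",
         paste(unique(c(ref_base, alt_base)[!c(ok, ok)]), collapse = ", "))
  }
  if (any(ref_base == alt_base)) stop("ref_base must differ from alt_base")
  flip <- ref_base %in% c("A", "G")
  ref2 <- ifelse(flip, comp[ref_base], ref_base)
  alt2 <- ifelse(flip, comp[alt_base], alt_base)
  factor(paste0(ref2, ">", alt2), levels = .SUBSTITUTION_CLASSES)
}

#' EGFR mutation-site summary
#'
#' Among patients with at least one retained EGFR variant: the fraction
#' of patients carrying each site, and the distribution of per-patient
#' distinct site counts in the buckets 1, 2, and more than 2.
#'
#' @param retained data.frame of retained variants.
#' @param gene Gene to summarise (default \code{"EGFR"}).
#' @return List: \code{n_mutant} (patients with >= 1 variant in the
#'   gene), \code{site_pct} (named percentages of mutant patients
#'   carrying each site, descending), \code{site_count_pct} (named
#'   percentages for buckets \code{"1"}, \code{"2"}, \code{">2"}).
#' @export
egfrSiteSummary <- function(retained, gene = "EGFR") {
  d <- retained[retained$gene == gene, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(list(n_mutant = 0L, site_pct = numeric(0),
                site_count_pct = c("1" = NA_real_, "2" = NA_real_,
                                   ">2" = NA_real_)))
  }
  per_patient <- tapply(d$site, d$patient_id,
                        function(s) unique(as.character(s)))
  n_mut <- length(per_patient)
  site_counts <- table(unlist(per_patient))
  site_pct <- pct(as.numeric(site_counts) / n_mut, 2L)
  names(site_pct) <- names(site_counts)
  site_pct <- site_pct[order(-site_pct, names(site_pct))]
  k <- vapply(per_patient, length, 0L)
  buckets <- c("1" = sum(k == 1L), "2" = sum(k == 2L), ">2" = sum(k > 2L))
  list(n_mutant = n_mut,
       site_pct = site_pct,
       site_count_pct = pct(buckets / n_mut, 1L))
}

#' Association between mutation carriage and MET status groups
#'
#' Tests a K x 2 contingency table (status groups x mutated/unmutated)
#' with Pearson's chi-squared test, falling back to Fisher's exact test
#' (Freeman-Halton for K > 2) whenever any expected cell count is below
#' 5. Two-sided throughout; for 2 x 2 chi-squared tables the Yates
#' continuity correction applies.
#'
#' @param tab Matrix of nonnegative integer counts (groups x 2).
#' @param method \code{"auto"} (expected-count rule), or force
#'   \code{"fisher"} / \code{"chisq"}.
#' @return List: \code{p.value}, \code{method} (the test actually used).
#' @examples
#' associationTest(matrix(c(7, 43, 7, 39), 2))   # p = 1
#' @export
associationTest <- function(tab, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (length(tab) == 0L || sum(tab) == 0) stop("empty contingency table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain nonnegative integer counts")
  }
  if (method == "auto") {
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    method <- if (any(expected < 5)) "fisher" else "chisq"
  }
  p <- if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }
  list(p.value = p, method = method)
}

#' Pairwise mutation/status comparisons across the three MET groups
#'
#' Runs [associationTest()] on each pair of MET-status groups of a 3 x 2
#' mutated/unmutated table. P-values are reported unadjusted (flagged in
#' the output): each pairwise contrast is interpreted at face value.
#'
#' @param tab 3 x 2 matrix, rows the MET-status groups (rownames kept),
#'   columns mutated/unmutated counts.
#' @return data.frame with columns \code{group1}, \code{group2},
#'   \code{p.value}, \code{method}, \code{adjustment} (always
#'   \code{"none"}).
#' @export
pairwiseComparisons <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 3L) stop("expected a 3-group table")
  if (is.null(rownames(tab))) rownames(tab) <- paste0("group", 1:3)
  pairs <- utils::combn(rownames(tab), 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    res <- associationTest(tab[pr, , drop = FALSE])
    data.frame(group1 = pr[1L], group2 = pr[2L], p.value = res$p.value,
               method = res$method, adjustment = "none")
  }))
  rownames(out) <- NULL
  out
}
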