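---
title: "Ratio-gate calling of MET amplification: model, training and simulation"
author: "MetGate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-gate calling of MET amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MetGate)
```

## The problem and the two assays

A bulk tumor sample can carry extra copies of *MET* for two very
different reasons: focal amplification of the *MET* locus (a targetable
driver event) or gain of the whole of chromosome 7 (polysomy, which
raises every chromosome-7 gene together and does not predict response to
MET inhibition). Dual-color FISH distinguishes them by counting *MET*
and CEP7 (chromosome-7 centromere) signals in at least 50 tumor nuclei:

* **AMPLIFICATION** — mean *MET*/CEP7 ratio ≥ 2;
* **POLYSOMY** — mean *MET* signals per nucleus ≥ 5 with ratio < 2;
* **NEGATIVE** — otherwise.

`classifyFish()` implements exactly these rules; both cutoffs are
inclusive, matching the ≥ signs of the clinical definition. The label
set is ordered NEGATIVE < POLYSOMY < AMPLIFICATION, and raising the mean
*MET* count with CEP7 fixed can never move a call down that order — a
property the test suite asserts over grids of observations.

The NGS side has no centromere probe. The insight the package encodes is
that the other chromosome-7 genes on a targeted panel (*EGFR*, *BRAF*,
*CDK6*, *PMS2*, *ABCB1*, *CYP3A4*) play the role of CEP7: under
polysomy, CN(*MET*)/CN(gene) stays near 1 for all of them, while under
focal amplification every such ratio rises. A **ratio-gate model**
(`RatioGateModel`) is a conjunction of per-gene ratio thresholds plus a
*MET* GCN cutoff applied to the samples the gates leave non-amplified.
`publishedModel()` is the fixed reference instance
(CYP3A4 1.12, CDK6 1.20, BRAF 1.53; GCN 2.8).

### Boundary semantics

All gate comparisons are inclusive and copy numbers are compared at full
floating precision — no rounding happens before a comparison. A
consequence worth knowing: a quotient that is *mathematically* equal to
a threshold may still sit one ulp below it in double arithmetic
(3.36/3.0 < 1.12 in IEEE doubles). Boundary tests therefore use exactly
representable quotients (power-of-two denominators); user data is
unaffected because measured copy numbers never land on thresholds
exactly.

## Training: per-ratio ROC cutoffs, then exhaustive enumeration

`trainRatioGateModel()` re-derives a gate model from any paired
NGS + FISH cohort in the two-step form:

1. **Per-gene ROC cutoffs.** For each candidate denominator
   independently, `rocCutoff()` selects the threshold for the rule
   *ratio ≥ t* that maximises Youden's J = sensitivity + specificity − 1,
   with FISH AMPLIFICATION as the positive class and the pooled
   polysomy/negative samples as the rest. Only observed values are
   candidate thresholds, so fitted cutoffs are always reproducible data
   points; J-ties resolve to the smallest threshold. Youden's J is the
   standard single-number criterion for collapsing an ROC curve to one
   operating point; fitting each gene independently (rather than jointly
   optimising a threshold grid) is the only reading under which
   "per-ratio ROC, then enumerate combinations" is a well-defined
   procedure, and it is what the package implements.
2. **Subset enumeration.** All 63 nonempty subsets of the six candidate
   denominators are evaluated. Within each candidate the gates are
   combined by conjunction, and the *MET* GCN polysomy cutoff is
   *refitted* on the samples that candidate's gates call non-amplified
   (intersected with FISH polysomy/negative) — mirroring the "among the
   other cases" structure of the final classifier. If a candidate's
   gates swallow all polysomy or all negative samples, the cutoff falls
   back to the full polysomy/negative set, which the training
   precondition guarantees is non-degenerate.

The winning candidate maximises overall three-class agreement with FISH;
ties break by (in order) higher amplification sensitivity — the
clinically primary class — then fewer gates, then the lexicographically
smallest gene subset. The search is exhaustive and fully deterministic,
and an independent naive-loop brute-force search in the test suite
confirms on random cohorts that no candidate ever beats the returned
model. There is no cross-validation: the procedure trains and evaluates
on the same cohort, as the reference workflow did, and the function says
so in a message; reported agreement is in-sample.

## Concordance statistics

`confusionSummary()` tabulates FISH (rows) against NGS (columns) in
AMPLIFICATION/POLYSOMY/NEGATIVE order. From it:

* `oneVsRest()` — per-class sensitivity (recall) and specificity
  (fraction of non-class samples called non-class). Undefined
  denominators yield `NA` with a warning, not an error, so empty classes
  in small strata do not crash reports.
* `overallAgreement()` — trace/n with a two-sided 95% Clopper–Pearson
  exact binomial interval (`stats::binom.test`). The exact interval was
  chosen because agreement counts are small-n binomial outcomes for
  which Wald and Wilson intervals undercover; the suite verifies ≥ 94%
  empirical coverage at n = 96 across p ∈ {0.2, 0.5, 0.74}.
* `agreementByGcn()` — agreement within half-open *MET* GCN bins.
  Default edges (2, 5) isolate the 2–5 copy zone, where the two assays
  genuinely disagree (low-level gains diluted by normal cells), from the
  ≥ 5 zone where concordance is complete.
* `collapseToBinary()` — merges polysomy and negative into one group,
  conserving counts; polysomy/negative confusions become concordant, so
  collapsing never lowers agreement. The combined agreement is always
  computed from the matrix; no attempt is made to match any externally
  reported combined figure that is inconsistent with its own matrix.

Percentages are rounded half-up (one decimal by default, two where
burden-style figures conventionally carry two), via `pct()`.

## Variant filtering and landscape summaries

`filterVariants()` applies three ordered rules to an annotated variant
table: population allele frequency > 0.001 (germline), VAF < 0.01 (below
the assay's reliable support), and *both-benign* in-silico prediction —
removed only when SIFT > 0.05 **and** PolyPhen2 ≤ 0.446 are both
present. A variant missing either score survives rule 3: the retained
set is deleterious, likely deleterious or of unknown significance. The
retained set is order-independent (each rule is a pure predicate); the
per-rule removal counts follow the stated order, which is normative. The
PolyPhen2 column is named generically; the HDIV score is the intended
input.

`classifySubstitution()` collapses base substitutions to the six
pyrimidine-reference classes (a substitution and its reverse complement
are one event read from opposite strands). `associationTest()` uses
Pearson's chi-squared test, switching to Fisher's exact test
(Freeman–Halton for 3×2) whenever any expected cell count is below 5 —
the classical rule, since the reference analysis names both tests
without stating one. Chi-squared on 2×2 tables keeps the Yates
continuity correction, which is what reproduces the reference cohort's
gender-association p of 1.000. `pairwiseComparisons()` reports the three
group-pair tests **unadjusted**, flagged as such in the output: the
reference pairwise p-values are only consistent with no multiplicity
adjustment, so adjusted values could not be compared against them.

## The synthetic cohort generator

`simulateCohort()` emulates the data-generating process the classifier
assumes, not any particular dataset:

| parameter | default | meaning |
|---|---|---|
| `n` | 96 | cohort size (the paired-cohort scale) |
| `class_probs` | 14/96, 16/96, 66/96 | amplification / polysomy / negative mix |
| `purity_range` | [0.2, 0.9] | tumor-cell fraction, uniform |
| `focal_met_range` | [6, 30] | tumor *MET* copies in amplified cases |
| `polysomy_range` | [3, 6] | whole-chromosome-7 copies in polysomy cases |
| `gcn_noise_sd` | 0.15 | additive Gaussian sd on bulk GCN (copies) |
| `nuclei_per_sample` | 50 | FISH nuclei scored |

Amplified genotypes raise *MET* alone on a background chromosome count
of 2 or 3 (shared by the other genes and CEP7 — a focal event on a
possibly trisomic chromosome); polysomy raises all seven genes and CEP7
together. Bulk NGS copy number is the purity-weighted mixture
ρ·tumor + (1−ρ)·2 plus Gaussian noise, floored at 0.1; the noise sd of
0.15 copies was chosen once so that, at low purity, discordant calls
concentrate in the 2–5 copy zone, the qualitative regime the method is
known to struggle in. FISH counts are Poisson per nucleus with means
equal to that nucleus's copy numbers (tumor with probability ρ, normal
otherwise) and a floor of one signal — hybridisation rarely yields zero
visible signals. FISH labels are computed from all simulated nuclei,
tumor and normal alike, so normal contamination dilutes both assays.

Setting `gcn_noise_sd = 0` switches to the fully deterministic
**noise-free regime**: no Gaussian term, and FISH means equal their
analytic expectations instead of Poisson draws. This is a deliberate
design choice: the zero-noise configuration exists to verify analytic
closure (labels follow exactly from genotypes), and Poisson nucleus
noise would break closure at the ratio-2 boundary (the floor at one
signal biases the CEP7 mean upward, so an m/background ratio of exactly
2 would fall below 2 in expectation). End-to-end recovery runs use
purity 1 and `polysomy_range = c(5, 6)`, because polysomy at 3–4
chromosome copies is *by the FISH definition itself* negative (mean
*MET* < 5) — that deliberate mismatch between genotype and FISH label is
the discordance mechanism, and is exercised separately by
`simulateDiscordanceZone()`, which concentrates bulk *MET* GCN in
[2, 5) via low purity and low copy gains.

All randomness flows from one integer seed; per-sample sub-seeds are
drawn up-front so cohorts with the same seed share their sample prefix
regardless of `n`. A single seeded run is byte-reproducible.

`simulateVariantTable()` plants per-gene mutation probabilities
(defaults: the recurrently mutated genes of an osimertinib-resistance
cohort, *EGFR* 0.5994 down to *KRAS* 0.0379), EGFR site-count buckets
(0.658 / 0.263 / 0.079 for 1 / 2 / >2 sites), a 62% missense form mix
and a 41% C>T-dominated substitution spectrum, and injects
filter-violating records (germline frequency, low VAF, both-benign) at
configurable rates — at rate 0, `filterVariants()` provably removes
nothing.

### What passing on synthetic data does and does not show

The generator reproduces the *structure* the method assumes — focal
versus whole-chromosome geometry, purity dilution, measurement noise —
but not everything real panels produce: no GC/coverage waves or
baseline batch effects in the copy-number estimates, no subclonal
heterogeneity or copy-neutral LOH, no correlated noise between genes,
and FISH truth in real tissue is scored on selected tumor nuclei by a
pathologist, not on a Bernoulli mixture. Green tests therefore certify
the algorithmic contracts (rule fidelity, optimality of the
enumeration, exactness of the statistics), not clinical performance;
the specific published thresholds can only be validated on the original
patient cohort, which is not publicly deposited.

## Problem sizes and numerical choices

The test suite runs cohorts of 150–400 samples and 50 random training
cohorts of ≤ 40 samples for the brute-force optimality check — sizes at
which every check is exact and the whole suite completes in well under a
minute. Thresholds are compared with `>=` at full precision;
`rocCutoff()` treats J-differences below 1e-12 as ties (resolved to the
smallest threshold) to keep selection stable under floating-point
reordering. Model JSON is written with 17 significant digits so
thresholds round-trip bit-exactly. Degenerate inputs fail loudly and
early: missing gate genes, single-class label vectors, sub-50-nuclei
FISH samples and malformed table cells are errors naming the offending
gene, class, sample or row — never silent coercions — because a silently
degraded call would corrupt every downstream concordance statistic.
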