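---
title: "Quantifying homologous recombination deficiency: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying homologous recombination deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdquant)
```

## The problem

Tumors that cannot repair double-strand breaks by homologous
recombination (HR) accumulate characteristic genomic damage: large
tracts of loss of heterozygosity, allelic imbalance spreading in from
the telomeres, abrupt large-scale copy-state transitions, a distinctive
single-base-substitution spectrum (SBS3, and to a lesser degree SBS8),
rearrangement signatures, and small deletions whose breakpoints carry
microhomology — the footprint of the error-prone end-joining that
substitutes for HR. HRD status matters clinically because HR-deficient
tumors tend to respond to platinum agents and PARP inhibitors.
`hrdquant` computes these readouts from standard whole-genome-derived
inputs, aggregates them through the published HRDetect logistic model,
and links the resulting classifications to treatment outcomes.

## Scar scores

The three scar components are counted on an allele-specific copy-number
profile (`total_cn`, `minor_cn` per segment; internal coordinates are
0-based half-open so interval arithmetic is unambiguous, while SEG-like
and VCF inputs keep their native 1-based conventions at the file
boundary).

* **LOH**: merged regions with `minor_cn == 0`, longer than
  `loh_min_mb` (default 15 Mb, strict), excluding regions spanning an
  entire chromosome. Homozygous deletions (`total_cn == 0`) count by
  default (`loh_include_homdel`) since the minor allele is absent; the
  flag exists because some pipelines exclude them.
* **TAI**: merged allelic-imbalance regions (`2*minor_cn != total_cn`)
  that touch a telomere (position 0 or the chromosome end), do not span
  the centromere, and reach `tai_min_mb` (default 11 Mb, inclusive).
  "Span" means covering the whole centromere interval; a region ending
  inside the centromere still counts, since the relevant exclusion is an
  imbalance continuing across the centromere into the other arm.
* **LST**: per arm (split at the centromere midpoint, with
  centromere-straddling segments truncated at the split — a
  deterministic arm assignment), segments shorter than `lst_smooth_mb`
  (default 3 Mb) are removed and equal-state flanks re-joined, iterated
  to a fixed point; then junctions between differing copy states count
  when both flanks are at least `lst_min_seg_mb` (default 10 Mb) and the
  gap between them is below the smoothing scale.

The defaults are the canonical published definitions behind the
commercial myChoice-style score (Abkevich-style LOH, Birkbak/Timms-style
TAI, Popova-style LST); every size lives in `hrd_config()` because the
literature varies. The HRD index is the plain arithmetic sum with no
ploidy correction, and the high-HRD call is inclusive at 34.

## Signature refitting

SBS-96 catalogs use the pyrimidine-strand convention: a variant at a
purine reference base is reverse-complemented together with its flanks.
Variants whose immediate flank falls off the contig are rejected and
counted rather than guessed. SV-32 catalogs cross clustered /
non-clustered with DEL/DUP/INV in five size bins plus translocations.
Clustering uses a transparent nearest-breakpoint rule — a breakpoint is
clustered when another variant's breakpoint lies within
`sv_cluster_dist_bp` (default 1 Mb) on the same chromosome — rather than
a piecewise-constant rate-fitting approach; the rule and distance are
configurable, and the simple rule is exactly testable.

Exposures are estimated two ways:

* **NNLS** (primary): `argmin ||c − S e||₂, e ≥ 0` by the Lawson–Hanson
  active-set algorithm. Deterministic, and the scale on which the SBS3
  positivity cutoff (proportion > 0.05, strict) is defined. The cutoff is
  interpreted on the proportion scale (exposures normalized to sum 1),
  the natural reading for a unit-free threshold of 0.05.
* **MCMC** (optional): random-walk Metropolis on softmax-parameterized
  proportions under `count_j ~ Poisson(N·(S p)_j)` with a uniform prior
  on the simplex (the softmax Jacobian, `Σ log p_i`, is included in the
  target). Half the chain is burn-in; an acceptance rate outside
  [0.1, 0.6] raises a tuning warning. On catalogs of a few thousand
  mutations the posterior means track NNLS within a few hundredths,
  which is the role the sampler plays here: corroboration with
  uncertainty, not the headline estimate.

Both estimators exist because refitting pipelines in this field use
both; NNLS is the default because the classification cutoff is defined
on it and determinism makes cohort reports reproducible bit for bit.

## Microhomology deletions

For a deletion the package measures the longest prefix of the deleted
sequence matching the reference just 3' of the deletion and the longest
suffix matching just 5', and reports the maximum. Taking both sides
makes the value invariant to left- vs right-alignment of the call, which
differs between variant callers. The HRDetect feature is the fraction of
deletions longer than 3 bp with homology of at least `mh_min_len`
(default 1 — any overlap counts, since no minimum length is standard);
deletions of 3 bp or less never enter the denominator. Records are taken
as the caller emitted them, with no de-duplication.

## HRDetect aggregation

Raw features are transformed per feature as
`z = (ln(x + ε) − mean)/sd`. The log transform is the natural log with
offset `log_epsilon` (default 1), required because exposures and the
microhomology fraction can be exactly 0; the choice is recorded with the
model so scores are only compared under identical preprocessing.
Normalization parameters can be fitted on the analyzed cohort (the
default, giving each transformed feature mean 0 and sd 1 across the
cohort) or supplied fixed for single-sample scoring; both modes exist
because reusing a training cohort's normalization is equally defensible
and the two give different absolute scores. The logistic model itself —
intercept −3.364, coefficients 1.611, 0.091, 1.153, 0.847, 0.667, 2.398
for SBS3, SBS8, SV3, SV5, HRD index and microhomology fraction — is used
exactly as published, never refit. All coefficients are positive, so the
score is strictly increasing in every feature. CHORD, an externally
trained random forest, is deliberately not reimplemented; its 0.5
threshold is only carried as an annotation for externally supplied
probabilities.

## Survival endpoints

TTPp runs from platinum initiation to the end of platinum treatment; a
missing end date falls back to the next treatment line's start (event in
both cases), and failing that the patient is censored at last follow-up.
With several platinum lines the first is analyzed by default
(`line_policy`), with a per-line mode available, since models adjust for
the number of platinum lines and no single convention dominates. OS runs
from first-line start to death or censoring. Times are months at a fixed
30.44 days/month so date fixtures are exact. Kaplan–Meier, log-rank and
Cox models are computed with the survival package; Cox uses Breslow tie
handling (simple, and the generators produce effectively tie-free
continuous times, so the Breslow/Efron distinction is immaterial here)
with Newton–Raphson convergence at 1e-9 over at most 50 iterations.
Complete separation or non-convergence is an error with diagnostics, not
a silently enormous coefficient; covariates that are constant in the
data are reported with log-HR 0.

## Cohort statistics

The trimodal-threshold diagnostic fits a three-component univariate
Gaussian mixture by EM (unequal variances) from a k-means initialization
under a fixed seed, and reports the boundary between the two upper
components — the point where weighted posterior membership switches —
plus the smallest integer classified with the top component. This is the
construction by which a trimodal HRD-score distribution yields an
integer threshold like 34; the published 34 remains the config default
and the fit is a diagnostic. EM is implemented directly (about thirty
lines for the univariate case) with component collapse (sd below 1e-6)
an explicit error.

Expression percentiles use strictly-below counting
(`100·#(ref < x)/#ref`), the convention under which a gene expressed
below every reference sample sits at the 0th percentile — counting ties
as below could never produce 0. Wilcoxon rank-sum tests use exact
enumeration when both groups have at most 10 untied observations and the
tie-corrected normal approximation otherwise, with Holm step-down
adjustment across comparisons.

## The synthetic cohort: what it does and does not emulate

Every generator is constructive and seed-deterministic, so ground truth
is exact and tests are non-flaky:

* `simulate_profile()` plants scar events in pre-computed slots —
  telomeric slots for TAI, interior slots for LOH and LST — separated by
  4 Mb isolation margins (wider than the 3 Mb smoothing scale), on a
  diploid heterozygous background. Planted counts are therefore exactly
  the scores the scar module must return.
* `simulate_snvs()` draws channel counts from a multinomial signature
  mixture and places each variant at a locus whose trinucleotide context
  matches, on a synthetic reference tiling all 64 trinucleotides, so the
  rebuilt catalog equals the drawn counts exactly.
* `simulate_deletions()` engineers breakpoint homology into exactly the
  target number of >3 bp deletions and guarantees zero homology in the
  rest, with ≤3 bp distractors.
* `simulate_svs()` lays out non-clustered variants beyond the clustering
  distance and chains clustered ones inside it; a lone clustered draw is
  demoted (clustering requires a neighbour) and the returned truth
  reflects the emitted set.
* `simulate_cohort()` draws exponential progression times with the
  HRD-positive hazard multiplied by the chosen hazard ratio. Censoring
  is uniform on (0, b) and *independent* of the event time, with b
  solved numerically per risk group so the marginal censoring
  probability equals `censor_fraction`; censoring drawn dependent on the
  event time would be informative and would bias the very Cox recovery
  the generator exists to validate.

What the generators do **not** emulate: tumor purity and subclonality,
noisy segmentation, caller-specific artifacts, overlapping or ambiguous
scar events, signature bleed between correlated signatures, non-unit
chromosomes (all toy chromosomes share one length), covariate-dependent
censoring, or cohort-level correlation between HRD status and the
mutation features. Passing tests therefore demonstrate that the
*implementations* are correct under controlled conditions, not that the
scores are robust to real-data noise — which is the generators' purpose.

The default study conditions used by the test-suite and the acceptance
script are: 100 simulated profiles for scar-oracle equivalence; 10,000
mutations and 20 seeds for exposure recovery; 50 replicates of 300
patients with a true hazard ratio of 0.35, a 6-month baseline median and
20% censoring for Cox recovery; and 200 replicates of 100 patients at a
hazard ratio of 1 for the log-rank type-I error. These sizes give each
statistical check comfortable resolution at its stated tolerance.

## Numerical choices and degenerate inputs

* Empty catalogs produce all-zero exposures and proportions (no 0/0).
* An empty deletion set, or one with no eligible deletion, has
  microhomology fraction 0 by definition.
* Readers reject invariant violations (overlapping segments, end-before-
  start dates, REF/reference disagreement) rather than repairing them;
  the single documented repair is the minor/major allele swap on input,
  a warning, because upstream callers disagree on column order.
* Flank bases beyond a contig are treated as non-matching in the
  microhomology scan, never as wildcards.
* `fit_normalization()` refuses constant features by name — a constant
  feature has no z-scale and would otherwise divide by zero downstream.

## Interfaces

The package is a library: tibble-in/tibble-out functions composed with
the pipe, `run_sample()`/`run_cohort()` for orchestration,
`write_cohort_report()` for byte-stable TSV/JSON artefacts with the full
configuration echoed into every report, and `tidy()`/`glance()`/
`autoplot()` methods on fitted objects. No shell entry point is shipped;
an analysis package of this shape is driven from R scripts, and
`scripts/acceptance.R` shows the pattern end to end.

## Known limitations

The scar definitions are one defensible reading of briefly specified
conventions; where the literature is silent (the TAI minimum size, the
centromere handling, one- vs two-sided microhomology) the choice is
explicit, configurable and documented above. The MCMC sampler targets
exposure proportions with a fixed total and does not model
overdispersion. The survival layer covers right-censoring only — no
time-varying covariates, competing risks or proportional-hazards
diagnostics. And the synthetic cohort validates implementations, not
biology: conclusions about real tumors require real profiles.
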