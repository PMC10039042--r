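# hrdquant

Quantification of homologous recombination deficiency (HRD) from
whole-genome-sequencing-derived inputs, and association of HRD status with
platinum response. The package is aimed at cancer-genomics analysts who
have per-sample allele-specific copy-number segments, somatic small-variant
and structural-variant calls, and a clinical treatment history, and who
want reproducible HRD scores, signature exposures and survival
associations — plus a synthetic-cohort generator with exact ground truth
for validating every stage.

## What it computes

**Genomic scar scores.** From an allele-specific copy-number profile:

* *LOH* — count of loss-of-heterozygosity regions (minor allele copy
  number 0) longer than 15 Mb that do not span a whole chromosome;
* *TAI* — count of allelic-imbalance regions (unequal allele copy
  numbers) anchored at a telomere, not crossing the centromere, at least
  11 Mb;
* *LST* — count of copy-state junctions between segments of at least
  10 Mb after smoothing away segments shorter than 3 Mb;
* *HRD index* = LOH + TAI + LST, classified high at **≥ 34**.

**Signature exposures.** SBS-96 trinucleotide catalogs (pyrimidine-strand
convention) and SV-32 rearrangement catalogs (clustered / non-clustered ×
type × size bin) are refit against a signature reference matrix by
non-negative least squares (primary, deterministic) or by MCMC under a
Poisson likelihood (posterior means and credible intervals). High SBS3
exposure is a proportion **> 0.05**.

**Microhomology deletions.** Among deletions longer than 3 bp, the
fraction whose breakpoints share flanking sequence homology (both flanks
scanned; max taken, so the measure is alignment-invariant).

**HRDetect.** The six features (SBS3, SBS8, SV3, SV5, HRD index,
microhomology fraction) are transformed as `z = (ln(x + 1) − mean)/sd`
(cohort-fitted or fixed normalization) and aggregated through the
published logistic model

```
score = 1 / (1 + exp(−(−3.364 + 1.611·z1 + 0.091·z2 + 1.153·z3
                               + 0.847·z4 + 0.667·z5 + 2.398·z6)))
```

with positivity at score **> 0.7**. A CHORD probability column, when
supplied externally, is annotated at its 0.5 threshold but never computed.

**Survival layer.** Time to progression on platinum (TTPp: platinum start
to treatment end, or next-line start when the end date is missing, else
censored at last follow-up) and overall survival, with Kaplan–Meier
curves, log-rank tests and Cox proportional-hazards models (Breslow
ties), months at 30.44 days.

**Cohort statistics.** Pearson correlation of HRD index vs SBS3, a
three-component Gaussian-mixture fit locating the integer high-HRD
cutoff in a trimodal score distribution, expression percentiles against a
reference cohort (strictly-below counting), and Wilcoxon rank-sum tests
with Holm step-down correction.

## Worked example

```r
library(hrdquant)

genome   <- make_toy_genome(8, 200)                       # 8 chromosomes, 200 Mb
sbs_sigs <- simulate_signature_matrix("sbs", seed = 42)   # synthetic reference
sv_sigs  <- simulate_signature_matrix("sv",  seed = 43)

prof <- simulate_profile(genome, n_loh = 3, n_tai = 2, n_lst = 4, seed = 7)
snv  <- simulate_snvs(sbs_sigs, c(0.6, 0.2, 0.2, rep(0, 7)), 5000, seed = 8)
dels <- simulate_deletions(20, 0.4, 5, seed = 9)
svs  <- simulate_svs(sv_sigs, rep(1/6, 6), 150, seed = 10)

run_sample("S1", prof$segments, snv$snvs, dels$deletions, svs$svs,
           c(snv$reference, dels$reference), sbs_sigs, sv_sigs, genome)
#> # A tibble: 1 × 14
#>   sample   loh   tai   lst hrd_index  sbs3   sbs8    sv3   sv5 mh_fraction ...
#> 1 S1         3     2     4         9 0.193 0.0177 0.157 0.104         0.4
```

The scar counts equal the planted truth (3, 2, 4; HRD index 9), the SBS3
proportion recovers the generating mixture weight on the third signature
(0.193 vs 0.2 with 5000-draw sampling noise), and the microhomology
fraction is exactly the engineered 0.4. `run_cohort()` then adds
cohort-normalized HRDetect scores, classification flags and — given a
clinical table — KM/log-rank/Cox associations; `write_cohort_report()`
emits byte-stable TSV/JSON with the full configuration echoed.

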