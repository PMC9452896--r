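---
title: "Methods: quantification, normalization and paired differential expression in mirbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, normalization and paired differential expression in mirbundle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbundle)
```

## The problem

Engineered human skeletal muscle constructs ("myobundles", MB) secrete
extracellular vesicles (EVs) whose small-RNA cargo — mature microRNAs
(miRs), roughly 15–25 nt — may carry muscle-to-organ signals. A typical
experiment cultures myobundles from a few donors under control and
electrical-stimulation conditions (here labeled CTL, CLFS, IHFS), then
sequences UMI-tagged small-RNA libraries from both the tissue and its
secreted EVs. The analysis questions are: which miRs differ between tissue
and vesicles within a condition, which respond to stimulation within each
compartment, which correlate between the paired compartments, which are
present in only one compartment ("informative missingness"), and which
pathways the differential set over-represents.

`mirbundle` implements this full analysis as a tested, reusable pipeline.
Every stage can be exercised on synthetic data with planted truth, so the
statistical machinery is validated without access to any particular
sequencing run.

## Quantification model

Input is a coordinate-sorted SAM of adapter-trimmed small-RNA reads whose
UMI is embedded in the read name (by default the last `_`-delimited token),
plus a miRBase-style GFF3 of mature-miR loci. Counting proceeds in four
rules:

1. **Multimap retention.** A read is kept only if it maps to at most 13
   genomic locations (`NH` tag, or read-id multiplicity when the tag is
   absent). The boundary is inclusive: `NH = 13` is kept.
2. **Seed anchoring.** The seed (mature positions 2–8 from the 5' end) must
   perfectly match the annotated seed coordinates. Since a read's positions
   2–8 are pinned by its 5' terminus, we implement this as exact equality
   of the read and annotation 5' termini (`end` on the minus strand). The
   biological rationale: Drosha/Dicer processing fixes the 5' end of a
   mature miR far more tightly than the 3' end. A looser reading — the read
   merely covers the seed interval — is available as
   `seed_mode = "cover"`, but the anchored reading is the default because
   it is stricter and reproducible.
3. **3' tolerance.** The read's 3' terminus may differ from the annotated
   terminus by at most 2 nt, in either direction (templated trimming or
   extension, the common isomiR pattern). 3 nt is rejected.
4. **UMI deduplication.** Molecules are distinct
   `(chrom, strand, start, end, UMI)` tuples. We use exact tuple matching,
   not directional/edit-distance UMI clustering: exact matching is fully
   verifiable against a brute-force oracle and is the conservative
   baseline. Clustering collapses sequencing errors in UMIs at the cost of
   an extra model; it is noted as an extension point.

A read may carry several alignment records; each record is evaluated
independently, so a retained multimapper can legitimately contribute to
different loci. A read overlapping two mature records on the same hairpin
(-5p/-3p) can satisfy at most one 5' anchor, so no fractional counting is
needed.

## Filtering and normalization

Low expressors are removed before any factor computation: a miR is kept
iff its CPM (computed with library sizes only) reaches 0.5 in at least two
samples ("more than one sample"). The dropped ids are retained, because
the preferential-expression stage inspects them.

Three normalization strategies are implemented:

* **TMM** (`tmm_factors()`): per sample against a reference (the sample
  whose upper quartile of scaled counts is closest to the mean upper
  quartile), gene-wise M and A values over genes positive in both samples
  are doubly trimmed (30% tails on M, 5% on A) and combined by an
  inverse-asymptotic-variance weighted mean; factors are rescaled to
  geometric mean 1. All constants are arguments.
* **Median-of-ratios** (`median_of_ratios_factors()`): DESeq-style size
  factors over genes positive in all samples. This package deliberately
  does not implement a variance-stabilizing transformation; the
  median-of-ratios factors feed the same NB engine as TMM so that the
  normalization comparison isolates the normalization, not the test.
* **TPM** (`tpm_normalize()`): counts over feature length, column-scaled
  to one million. Mature miRs are nearly length-uniform (~22 nt), so TPM
  differs from CPM mostly in composition handling — which is exactly the
  weakness the normalization comparison is designed to expose.

## Paired differential expression

The design encodes within-subject pairing as subject fixed effects:
`~ subject + group`, where `group` is compartment (MB vs EV within one
treatment) or treatment (within one compartment). With 3 subjects and two
groups this is a 6 × 4 design with 2 residual df per miR.

**Dual normalization.** Between-population contrasts (MB vs EV) are run on
the jointly filtered and normalized matrix; between-treatment contrasts
are run per compartment on separately filtered and normalized MB-only and
EV-only matrices. Tissue and vesicle libraries have radically different
composition, so a joint normalization would distort within-compartment
treatment contrasts; conversely the MB-vs-EV contrast must share one scale.

**Dispersion.** A common NB dispersion maximizes the summed Cox–Reid
adjusted profile likelihood over a log-spaced grid (1e-4 to 4) with
golden-section refinement; it is estimated once per normalization context
under the saturated group-means design and reused for that context's
contrasts. Tagwise maximizers are shrunk toward the common value on the
log scale with prior weight 10 against the residual df.

**Fitting and testing.** Per-miR NB log-link GLMs are fit by IRLS
(convergence: max relative coefficient change < 1e-8, cap 50 iterations;
fitted means initialized at `(y + mean(y))/2`; the linear predictor is
clamped to ±30; a secondary deviance-plateau criterion accepts boundary
fits where a group has all-zero counts). The quasi-likelihood F-test
divides the contrast's deviance drop by a per-miR quasi-dispersion
(residual deviance / residual df) squeezed toward the mean quasi-dispersion
with prior df 10, and refers the statistic to F(df_contrast,
df_residual + prior df). This fixed-prior squeeze is a deliberate
simplification of the published QL framework (which estimates the prior df
by moment matching); with 2 residual df the fixed prior is stable and
mildly conservative, which the calibration tests quantify (empirical
type-I error ≈ 0.04 at nominal 0.05 on null NB data).

**No multiplicity adjustment by default.** With n = 3 subjects this class
of study is discovery-oriented; unadjusted p-values at 0.05 are reported,
and a Benjamini–Hochberg column is available behind `add_fdr = TRUE`.

## Correlation and preferential expression

`compartment_correlation()` pairs each subject's MB and EV samples within
a treatment and reports Pearson r on TMM-normalized counts with the exact
t-transform p-value on n − 2 df. With n = 3 pairs this has one degree of
freedom: p-values are fragile, |r| = 1 yields an infinite t (reported as
the smallest positive double and flagged `boundary`), and calibration
claims are made only at larger n — the package's null-calibration test
uses n = 20. By default the pipeline computes correlations only for miRs
significant in the matching DE contrast; `mir_subset = NULL` computes all.

`preferential_expression()` operationalizes informative missingness: a miR
passing the low-expressor filter in one compartment's matrix but not the
other's is flagged for that compartment. Flagged miRs are tested on raw
counts with a repeated-measures comparison across all subject × treatment
units. With exactly two within-unit levels (MB, EV) the RM-ANOVA F is the
square of the paired t statistic, so the omnibus test is implemented as a
paired t-test over the 9 units and labeled RM-ANOVA-equivalent; where it
is significant, per-treatment paired t-tests (3 pairs each) follow.
Zero-variance differences are flagged undefined rather than erroring.

## Over-representation analysis

`ora_hypergeometric()` tests a significant set against user-supplied
pathway → miR sets (GMT-like TSV) with the one-sided hypergeometric upper
tail, using the full pre-filter miR set as the universe. Pathways are
ranked by observed count with p breaking ties, matching the convention of
reporting "top pathways by observed miRs". Unadjusted p by default, BH
behind a flag.

## The synthetic-data generator

`simulate_counts()` emulates the study design: 3 subjects × {MB, EV} ×
{CTL, CLFS, IHFS}, 991 miRs (the size of a typical processed mature-miR
set), library sizes uniform in 12–20 million (sequencing depth ~16 M),
log-normal baseline abundances (sdlog 2, spanning ~4 orders of magnitude),
NB counts at dispersion 0.1. Planted structure:

* fold changes of `2^planted_log2fc` in a target compartment/treatment for
  a `frac_de` fraction of miRs (default 10%);
* compartment-exclusive miRs (default 2% per side), zeroed absolutely in
  the other compartment — the strongest form of informative missingness; a
  leaky variant (`exclusive_leak`) stresses the filter;
* MB–EV correlation induced by subject effects shared between a subject's
  two compartments, with the shared fraction set by `planted_corr`
  (chosen over a copula for transparency: pairing in the real experiment
  is a subject-level property).

What the generator does **not** model: sequence content (coordinates
suffice for the counting rules), GC/length biases, adapter artifacts,
hairpin structure, and compositional coupling between compartments beyond
the subject effects. Passing calibration on these simulations therefore
validates the statistical machinery under a correctly specified NB model,
not robustness to every real-data pathology.

`simulate_alignments()` builds toy SAM/GFF3 fixtures engineered to hit
every acceptance/rejection reason (multimap cutoffs, 5' shifts, 3' shifts,
duplicate UMIs, unmapped records) and bundles true counts computed by an
independent plain-loop application of the counting rules.

`calibration_experiment()` isolates the NB sampling layer for the DE
calibrations — subject random effects are switched off there because they
are a distinct (log-normal, non-NB) variance component whose handling is
exercised by the correlation machinery instead.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere (native GFF3/SAM); any
  half-open arithmetic is internal.
* Problem sizes in the validation suite: 2000 null miRs for type-I/KS
  checks, 5000 miRs (500 planted) for power/recovery, 50 random fixtures
  of up to 500 reads for the quantifier oracle, 500 replicates of length
  50 for correlation recovery. These sizes give Monte-Carlo standard
  errors comfortably inside the asserted bands.
* Ties in TMM trimming are broken by first-occurrence rank; empty trim
  windows fall back to a unit factor.
* The TPM arm of the normalization comparison rescales TPM to each
  sample's depth and rounds to pseudo-counts so all three arms share one
  engine; this is one defensible reading of "DE on TPM-normalized data",
  which is otherwise underspecified (TPM is a transform, not a test).
* All-groups F-tests per compartment are available
  (`run_all_contrasts(all_groups = TRUE)`) alongside the default pairwise
  contrasts, since either reading of "between each treatment condition" is
  plausible.

## Known limitations

* Exact-match UMI handling slightly overcounts molecules when UMIs carry
  sequencing errors.
* The common-dispersion QL engine has no trend over abundance; strongly
  abundance-dependent dispersion would be mis-moderated.
* Pearson p-values at n = 3 are reported for fidelity to the paired
  design but should be treated as descriptive.
* The normalization comparison's median-of-ratios arm stands in for a
  full DESeq2-style analysis (no VST, no Wald test), so it compares
  normalizations, not packages.
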