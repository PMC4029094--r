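---
title: "Hybrid qPCR/SNP-array copy-number calling for KIR3DL1/KIR3DS1: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid qPCR/SNP-array copy-number calling for KIR3DL1/KIR3DS1: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*KIR3DL1* and *KIR3DS1* are paralogous natural-killer-cell receptor genes that
occupy the same slot of the KIR locus on chr19q13.4, so their copy numbers
trade off against each other; a genotype is a joint group written `s-l`
(KIR3DS1 copies - KIR3DL1 copies).  The locus is effectively invisible to
standard GWAS pipelines — SNP probes in the region produce more than three
intensity clusters and are discarded by genotype callers — while per-sample
qPCR copy-number assays are accurate but far too expensive at the sample
sizes modern association studies need.

`kircnv` implements the hybrid strategy: call copy number carefully by
multiplexed qPCR in a modest training cohort, then *impute* copy number into
the much larger SNP-array cohort by supervised classification on raw array
intensities, carrying calling uncertainty through to the association tests by
multiple imputation.  Because the original raw data are not publicly
deposited, the package ships a synthetic-data generator that reproduces the
statistical structure of all three inputs, so every stage is testable
end to end.

## qPCR preprocessing

Each 384-well plate carries up to 96 samples in four replicate wells, four
calibrator samples of known groups (two `1-2`, two `2-1`) and one water
well.  Each well is multiplexed over three dye channels: the two target
genes and the diploid reference gene *STAT6*.  Per well,

\[ \Delta Ct_{\text{gene}} = Ct_{\text{STAT6}} - Ct_{\text{gene}}, \]

so larger values mean more target copies; per sample, the replicate median
is taken.  Replicate-level missingness (no crossing within 40 cycles) is
tracked per channel.

Three rules handle pathological readouts:

* **Reference non-amplification.**  Samples whose reference channel failed
  in all four wells are excluded — their ratios are meaningless.
* **Hard zeros.**  A target gene missing in three or more of four wells is
  called zero copies outright, before any clustering.  With one or two
  missing wells, the median of the remaining wells is used (the replicate
  summary is a median throughout, so this is the natural completion).
* **Plate outliers.**  Whole plates can be excluded.  Where an analyst would
  judge a plate "noisy" by eye, `qc_filter()` applies a reproducible rule: a
  plate is dropped when the robust SD (1.4826 × MAD) of its per-gene
  delta-Ct exceeds `plate_sd_factor` (default 2.5) times the cross-plate
  median robust SD, or when its two anchor clusters fail to separate (mean
  silhouette < 0.25).  The robust SD is pooled *within* the plate's two
  anchor clusters: the raw-scale MAD is dominated by how many one- versus
  two-copy samples happen to sit on the plate (a ~1-cycle bimodal spread),
  and would flag plates for composition rather than noise.  Both thresholds
  are configurable.

### Cross-plate normalization

Delta-Ct distributions shift and stretch between plates (master-mix and
instrument effects act approximately affinely on the scale), so plates
cannot be pooled raw.  Per plate and gene, a 1-D k-medoids partition
(`k = 2`, exact PAM with deterministic initial medoids at the 25th/75th
percentile points) locates the two most populous, most distinguishable
groups — one and two copies.  Since delta-Ct increases with copy number, the
lower-median cluster is the one-copy group.  The linear map

\[ x \mapsto 1 + \frac{x - m_1}{m_2 - m_1} \]

sends the cluster medians to 1 and 2 on every plate.  Because the map is
re-derived per plate from its own anchors, any per-plate affine distortion
of the raw scale cancels exactly; the tests assert invariance to 1e-9.
Negative normalized values are then clamped to 0 (their expected zero-copy
state).  Clamping happens *before* the mixture fit — the normalized scatter
the mixture sees is non-negative — which is an assumption, not something
the assay dictates; the pre-clamp values are kept in `*_preclamp` columns.
Samples repeated across plates collapse to their per-gene median, with a
reproducibility report of the per-sample spread.

Anchoring needs at least `2 * min_group_size` values per plate and gene
(default `min_group_size = 5`).  The requirement is deliberately on the
total, not per cluster: on a realistic 91-sample plate the two-copy
*KIR3DS1* cluster holds only ~5 samples, and a per-cluster floor would
reject half of all plates.

The dye-to-gene assignment is a configuration option
(`dye_map`, default FAM = KIR3DS1, CY5 = KIR3DL1, the assay-design
convention) because multiplexed probe sets can be conjugated either way
round; nothing downstream depends on the choice beyond column naming.

## Joint copy-number calling

On the normalized plane, group `s-l` is expected at coordinates `(s, l)`.
Eight groups are modelled — `0-2`, `1-1`, `2-0` (total two, common) and
`2-1`, `1-2`, `0-1`, `1-0`, `3-0` (rarer) — as a mixture of eight bivariate
Gaussians with full per-component covariances, because the two genes'
delta-Ct errors are correlated within a well (shared reference subtraction)
and the correlation visibly tilts the clusters.  `0-0` is not a component:
both genes hard-zeroed is a no-call, flagged upstream.

The EM fit is deterministic:

* **Initialization** assigns each point to its nearest expected centre
  (a single k-means step from the fixed centres), giving initial weights
  (floored at 1e-3 so rare groups stay alive), means, and within-cluster
  covariances.
* **Hard-zero masks.**  A sample hard-zeroed for one gene enters the fit
  with pseudo-coordinate 0 for that gene and a mask restricting its
  responsibilities to components with zero copies of that gene.  It thus
  informs the zero-group parameters without being free to migrate — this
  reconciles calling zeros *before* clustering with zero-containing groups
  still appearing in the fitted model.  Masked entries are exactly 0 and
  each posterior row sums to 1.
* **Numerical safeguards.**  Component covariance eigenvalues are floored at
  `var_floor = 1e-4` (normalized units²); eigenvalue clipping is the exact
  constrained M-step, so the masked-mixture log-likelihood is non-decreasing
  every iteration (asserted in the tests).  A component whose weight falls
  below 1e-6 keeps its initialization parameters rather than being deleted:
  the group set is biologically fixed.  Convergence is `|Δ log L| < 1e-8`
  or 500 iterations.

Each sample gets eight posterior probabilities and a MAP call.
`draw_imputations()` converts posteriors into `m` (default 10) plausible
hard-call datasets by independent categorical draws, so downstream analyses
can run per dataset and pool, propagating call uncertainty.

## Imputation into SNP-array samples

Illumina arrays report two allele intensities X, Y per SNP, summarised as
`R = X + Y` (total signal, tracks total copy number) and
`theta = (2/pi) * atan2(Y, X)` in [0, 1] (allelic angle, tracks the
KIR3DL1:KIR3DS1 ratio).  The `atan2` convention is the platform standard;
it is stated explicitly in `compute_r_theta()` so it can be swapped if a
source encodes the ratio differently.

Candidate SNPs are screened by regressing copy number (per gene, within
each imputed call dataset) on R and theta jointly and taking the overall
F-test p-value; the m p-values are combined by their median (robust, and
the per-dataset fits differ only through call uncertainty).  A constant
response yields p = 1 by convention.

Classification is k-nearest-neighbour on z-scored features (R and theta are
on incommensurate scales; unstandardized Euclidean distance would be
dominated by R).  knn is used rather than unsupervised clustering of the
SNP signals because the clusters overlap along R and sit at slightly
different positions in cases and controls (the cohorts were processed in
different centres); a supervised method anchored on the qPCR labels does
not need to re-identify clusters.  Votes are deterministic: majority among
the k neighbours, ties broken by smaller summed neighbour distance, then by
the more frequent training class, then lexicographically.  Model selection
(`select_knn_model()`) minimises the mean leave-one-out error over the
imputed label datasets across candidate SNP subsets and a k grid, with ties
to smaller subsets and smaller k.  `training_size_curve()` repeats LOOCV on
random training subsets (default 25 repeats per size) to show how many
qPCR-typed samples the imputation actually needs.  Features are z-scored
once on the full sample set entering each LOOCV rather than per fold;
at these n the difference is negligible and the neighbour geometry can be
computed once and reused across the m label datasets.

## Association testing

Within each imputed dataset, disease status is regressed on the copy-number
factor by logistic regression — joint groups with reference `0-2`, or
marginal per-gene copy numbers with references `2` (KIR3DL1) and `0`
(KIR3DS1), the most common configurations.  Per-group log-odds are pooled
by Rubin's rules (total variance `W + (1 + 1/m) B`; Barnard–Rubin degrees
of freedom, which at these m and n are indistinguishable from the classic
formula).  The "overall" test is a pooled multivariate Wald (D1-style) test
on all non-reference coefficients; published overall p-values computed by
other MI software are therefore approximated, not matched digit for digit.
Crude odds ratios with Woolf intervals
(`exp(log OR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`) are provided for
verifying printed tables; zero cells leave the OR undefined (blank) rather
than continuity-corrected.  Reported per-group counts are MAP-call counts.

Epitope interaction is addressed two ways: re-running the association
within carriers of the partner ligand (HLA-Bw4 for KIR3DL1; the
isoleucine-80 subset HLA-Bw4-80I for KIR3DS1 — 80I carriers are a subset of
Bw4 carriers), and a case-only chi-square test of independence between KIR
presence/absence (or the three observed joint presence patterns) and
epitope carriage among cases, which is more powerful when the two loci are
independent in the population.  The per-dataset Pearson statistics (no
continuity correction) are pooled by their mean and referred to the
chi-square distribution with the table's df — a pragmatic rule; published
pooled p-values are reproduced to about ±0.01, as verified on the bundled
printed tables.

## The synthetic-data generator

`kir_sim_config()` fixes the study conditions the pipeline is validated
under; defaults are chosen once, from published quantities where available:

* **Cohort.**  747 cases / 727 controls (the qPCR cohort size); group
  frequencies from the published SNP-cohort totals
  (7316, 3678, 454, 222, 172, 193, 46, 25)/12106 — the only printed
  frequency source.  Case frequencies can be tilted by per-group odds
  ratios; the default is the null.
* **Plates.**  384-well plates with four replicate wells per sample, four
  calibrators (`1-2`, `1-2`, `2-1`, `2-1`) and one water well, i.e. 91
  study samples per plate; 1474 samples then occupy 17 plates, matching the
  post-QC study layout.
* **qPCR noise.**  Per-well delta-Ct noise SD 0.08 cycles and per-plate
  affine distortion with slope in [0.8, 1.2] and offset in [-0.5, 0.5].
  These magnitudes are not published; they were set so that adjacent
  integer groups separate by roughly 8 sample-level SDs, the separation the
  published normalized scatter displays.  Zero-copy genes drop out with
  probability 1 per well (absent template does not amplify); one-copy genes
  with probability 0.01.
* **SNP clusters.**  `R = 0.30 + 0.45 × (total copies)` with SD 0.15;
  `theta = 0.10 + 0.80 × l/(s+l)` with SD 0.05, truncated to [0, 1]; case
  clusters shifted by (+0.05, +0.02) to emulate the between-centre batch
  effect.  Per-group SNP-cluster variances are not published; these values
  were fixed once so that the full-sample LOOCV error lands near the
  published ≈2%, with the residual confusions concentrated where the
  published analysis reports them — same-theta, adjacent-R groups
  (`2-0` vs `3-0`).  All are configurable.
* **Epitopes.**  Bw4 carriage 0.60 and Bw4-80I-given-Bw4 0.62, matching the
  published carrier-subset sizes (886/1474 and 550/886).

Reproducibility: one top-level seed; the cohort, plate and SNP generators
use fixed offsets from it, so regenerating any single table is
deterministic.

What the generator does *not* emulate: raw amplification curves and probe
chemistry, linkage disequilibrium between KIR genes, allele-level HLA
structure, genuine ImmunoChip cluster shapes (clusters are Gaussian here),
or samples shared between plates beyond what the plate layout produces.
Passing tests therefore demonstrate that the algorithms recover the
structure they assume, at realistic noise — not that they are robust to
every artefact of real plates or arrays.

## Problem sizes used in the checks

The bundled acceptance checks run the default 1474-sample/17-plate cohort
through the full qPCR-to-mixture path; the learning-curve checks use
training subsets of 295 and 590 samples (25 random subsets each, k = 8);
null calibration uses 1000 replicates of a 300 + 300 cohort with m = 5
imputations and posteriors computed under the generating mixture (refitting
the EM inside every replicate would test the same thing at far greater
cost); the published-scale precision check uses one 6744 + 5362 null cohort
with m = 10.  The marginal three-level KIR3DL1 grouping is used for
calibration because the rarest joint groups (frequency ≈0.2%) produce empty
cells and separation in per-imputation logistic fits at calibration-sized
cohorts, which would measure Wald-asymptotics failure rather than the
pooling being tested.

## Known limitations

* The plate-outlier rule is a reproducible surrogate for a visual judgement;
  its thresholds (2.5 × median robust SD, silhouette 0.25) are sensible
  defaults, not estimated quantities.
* The mixture assumes Gaussian components on the normalized scale; heavy
  contamination within a plate is only partially absorbed by the covariance
  floor and should be caught by QC instead.
* Posteriors for hard-zero samples are defined over the compatible groups
  via the mask construction — a modelling choice; the data alone do not
  dictate how a non-amplifying gene's sample should share probability
  between, say, `0-2` and `0-1`.
* knn imputation inherits any systematic difference between training and
  target arrays; the case/control batch shift is handled by training on
  both cohorts jointly (the tests verify combined training beats
  single-cohort training under the shift), but a *new* batch would need its
  own calibration.
* The case-only interaction test is valid only under KIR-HLA independence
  in the population; the chi-square mean-pooling rule is approximate.
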