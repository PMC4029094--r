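# kircnv

Hybrid qPCR/SNP-array copy-number genotyping of the *KIR3DL1*/*KIR3DS1*
locus, with uncertainty-aware case-control association testing.

## The problem

*KIR3DL1* and *KIR3DS1* are paralogous natural-killer-cell receptor genes
that share one slot of the KIR locus (chr19q13.4), so their copy numbers
trade off; a genotype is a joint group `s-l` (KIR3DS1 copies - KIR3DL1
copies), one of `0-2, 1-1, 2-0, 2-1, 1-2, 0-1, 1-0, 3-0`.  SNP probes in
the region form more than three intensity clusters and are discarded by
standard genotype callers, while per-sample qPCR copy-number assays are
accurate but too expensive at association-study scale.  `kircnv` is for
statistical geneticists who have qPCR copy-number data on a modest training
cohort and raw Illumina intensities on a large one, and want locus-wide
copy-number association tests with calling uncertainty propagated honestly.

## What it does

1. **qPCR preprocessing** — per-well ΔCt = Ct(STAT6) − Ct(gene), replicate
   medians, QC (reference non-amplification, automated plate-outlier rule),
   the hard-zero rule (gene missing in ≥3 of 4 wells ⇒ zero copies), and
   cross-plate normalization: per plate and gene, 1-D k-medoids locates the
   one- and two-copy clusters and the affine map
   `x ↦ 1 + (x − m₁)/(m₂ − m₁)` sends their medians to 1 and 2
   (negatives clamped to 0).
2. **Joint calling** — an 8-component bivariate Gaussian mixture on the
   normalized (ΔCt₃DS1, ΔCt₃DL1) plane, fitted by EM from deterministic
   expected-centre initialization, with hard-zero samples masked to
   compatible components.  Every sample gets posterior probabilities over
   the eight groups; `draw_imputations()` turns them into m plausible
   hard-call datasets.
3. **SNP imputation** — R = X + Y and θ = (2/π)·atan2(Y, X) per SNP;
   screening by `copy ~ R + θ` regressions; k-nearest-neighbour
   classification on standardized (R, θ) with deterministic tie-breaking,
   leave-one-out model selection over SNP subsets and k, and
   training-size curves.
4. **Association** — per-group and overall logistic-regression tests pooled
   across imputations by Rubin's rules (D1-style overall Wald test), crude
   odds ratios with Woolf CIs for table verification, HLA-Bw4 /
   HLA-Bw4-80I carrier-subset tests, and the case-only χ² interaction test.
5. **Synthetic data** — generators for well tables, SNP signals and
   phenotypes with plate batch effects, amplification dropout and
   per-group (R, θ) cluster structure, so the whole pipeline runs and is
   tested without any external data.

## Worked example

```r
library(kircnv)

cfg  <- kir_sim_config(n_cases = 400, n_controls = 400, seed = 2025)
sim  <- simulate_cohort(cfg)
qpcr <- simulate_qpcr(sim$truth, cfg)
snp  <- simulate_snp_signals(sim$truth, cfg)

res <- run_kir_pipeline(wells = qpcr$wells, snp_signals = snp,
                        phenotype = sim$phenotype, m = 10, seed = 2025)
print(res$mixture)
#> KIR3DS1/KIR3DL1 copy-number mixture (8 bivariate Gaussian components)
#>   836 samples, 3 EM iterations (converged), loglik 2916.700
#>   MAP posterior > 0.99 for 100.0% of samples; 0 no-call sample(s)
#>
#> 0-2 1-1 2-0 2-1 1-2 0-1 1-0 3-0
#> 473 252  30  36  27  14   4   0

print(res$association$marginal_3dl1)
#> Copy-number association (3DL1 grouping, reference 2, m = 10)
#>  group n_case n_control   or   lo   hi       p
#>      2    234       248 1.00   NA   NA      NA
#>      0     22        12 1.94 0.94 4.02 0.07319
#>      1    144       140 1.09 0.81 1.46 0.56440
#> Overall p = 0.1906
```

The mixture summary reports how many samples were assigned with MAP
posterior above 0.99 (here all of them: the synthetic plates are
study-condition-like, ~8σ between adjacent integer groups after
normalization).  The association table gives MAP-call counts per marginal
KIR3DL1 copy number, Rubin-pooled odds ratios versus the two-copy
reference with 95% Wald intervals, and the pooled overall Wald p — here a
null cohort, so nothing is significant.

A thin CLI over the same functions is installed with the package
(`system.file("cli", "kircnv", package = "kircnv")`) with subcommands
`simulate`, `run-all` and `verify-tables`.

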