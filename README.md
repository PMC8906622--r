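# omivec

Vector analysis of longitudinal multi-omics colitis studies on a
discriminant plane.

## The problem

Dextran-sulfate-sodium (DSS) colitis develops very differently in
Th1-biased C57BL/6 and Th2-biased BALB/c mice: C57BL/6 deteriorates
monotonically over a 15-day course while BALB/c peaks around day 7 and
then recovers. Studies of this design collect colon transcriptomics,
serum and cecal (microbiota-derived) metabolite concentrations, 16S OTU
counts and clinical observations across a strain × day × treatment grid
with very few replicates per cell. `omivec` gives analysts of such
studies a common geometric language for all of those layers, plus a
calibrated synthetic-study generator so every stage of the analysis is
testable without access to the original animals.

## The method

Samples of a feature table (genes, metabolites, or OTU-derived
abundances) are ordinated by multi-class Fisher LDA onto the two leading
discriminant axes — the directions **w** maximizing the Rayleigh
quotient of the scatter pencil,

    max_w  (wᵀ S_B w) / (wᵀ S_W(λ) w),

where S_B is the between-condition scatter and S_W(λ) a within-condition
covariance shrunk toward a scaled identity, S_W(λ) = (1−λ) S_W +
λ·(tr S_W / p)·I, with Ledoit–Wolf intensity λ by default. Shrinkage is
what makes the projection well-posed at n = 3 replicates against
hundreds or thousands of features. On the resulting plane the package
computes:

- **Dissimilarity Coefficient** `r = √((x₂−x₁)² + (y₂−y₁)²)` — the
  Euclidean distance between condition centroids, quantifying how far a
  disease stage has displaced the molecular profile;
- **centroid trajectories** — the polyline a treatment arm traces over
  days, with per-segment lengths;
- **Disease Severity Index** `D = Σ ρₓ ρᵧ r_xy` — summed over all cross
  pairs (x from one condition, y from the other), where ρ is a sample's
  distance from the plane's center and r_xy the distance between the two
  samples.

Around this core sit Welch-test + 1.5-fold-change shortlisting with
Benjamini–Hochberg control, an OTU minimum-count/prevalence filter with
total-sum scaling and phylum/genus aggregation, the Evenness Index
`E = −Σ pᵢ ln pᵢ` (Shannon entropy of a composition) with
treated/control ratios, pro/anti-inflammatory ratio and Venn-overlap
analytics, the 0–12 clinical disease-activity score, and condition-level
Spearman correlation of inflammation markers with phylum abundances and
metabolic-category scores.

## Worked example

```r
library(omivec)
study <- default_study(seed = 1)          # full 2x3x2x3 synthetic study
tr <- study$tables$transcript
keep <- tr$metadata$strain == "C57BL/6"
c57 <- feature_table(tr$values[keep, ], "transcript", tr$metadata[keep, ])

fit <- discriminant_plane(c57)            # strain-wise LDA ordination
fit
#> <discriminant_plane> 18 samples, 120 features, 6 groups
#>   shrinkage = 0.6005; discriminant ratio LD1 = 0.561, LD2 = 0.154

d0  <- condition_id("C57BL/6",  0, "treated")
d7  <- condition_id("C57BL/6",  7, "treated")
d15 <- condition_id("C57BL/6", 15, "treated")
trajectory(fit, c(d0, d7, d15))
#> <plane_trajectory> C57BL/6|0|treated -> C57BL/6|7|treated -> C57BL/6|15|treated
#>   segment lengths: 12.01, 14.32  (total 26.33)
dissimilarity_ratio(fit, c(d0, d15), c(d0, d7))
#> [1] 1.674431
```

The trajectory moves farther at every step and the distance ratio
r(0,15)/r(0,7) > 1: the simulated C57BL/6 molecular profile keeps
diverging from baseline as the disease progresses, exactly the pattern
the geometry is designed to expose. On the microbiome side:

```r
phy <- aggregate_taxa(total_sum_scale(filter_otus(study$tables$otu)),
                      study$taxonomy, "phylum")
evenness_ratio_report(phy)$ratios
#>   strain day     ratio
#>   ...
#>  C57BL/6   0 1.0343938
#>  C57BL/6   7 0.9740465
#>  C57BL/6  15 0.8350802
```

The treated/control evenness ratio in C57BL/6 falls from ~1.03 at day 0
to ~0.84 at day 15 — the Proteobacteria bloom concentrates the phylum
composition as severity grows — while in BALB/c it dips at day 7
(0.83) and recovers above 1 by day 15.

The whole analysis (simulate → shortlist → project → vector statistics →
microbiome profiles → annotation analytics → correlations) runs as one
restartable, manifest-checked pipeline:

```r
run_pipeline(run_config("out", seed = 1))
```

or from a shell via the thin wrapper `inst/cli/omivec.R`.

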