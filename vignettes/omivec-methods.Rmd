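---
title: "Methods: discriminant-plane vector analysis of multi-omics colitis data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discriminant-plane vector analysis of multi-omics colitis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omivec)
```

## Scope and data model

`omivec` analyses processed feature tables from a two-strain
(C57BL/6, BALB/c) × three-day (0, 7, 15) × two-arm (control, DSS-treated)
colitis design with few biological replicates per cell. Four layers share
one container, the `feature_table`: a samples × features matrix of
finite non-negative values plus per-sample (strain, day, arm) metadata.
All statistics are computed at the level of a *condition* — one
strain × day × arm cell, encoded as the key `"strain|day|arm"`. Values
must be explicit: a missing concentration is a 0, never a blank, which
keeps every invariant machine-checkable. Raw reads, spectra and BIOM
files are out of scope; upstream quantification is assumed done.

## The discriminant ordination

The core model is a multi-class Fisher LDA used as an *ordination*, not
a classifier. With group means $m_k$, between-class scatter
$S_B = \sum_k n_k (m_k - \bar m)(m_k - \bar m)^\top$ and within-class
covariance $W$, the two leading axes solve

$$\max_w \; \frac{w^\top S_B w}{w^\top W_\lambda w}, \qquad
W_\lambda = (1-\lambda)\,W + \lambda\,\frac{\mathrm{tr}\,W}{p}\,I .$$

**Why shrinkage.** With 3 replicates per condition and $p$ in the
hundreds or thousands, $W$ is singular and plain LDA is undefined. The
ridge target $\frac{\mathrm{tr} W}{p} I$ preserves the trace; the
intensity $\lambda$ defaults to the Ledoit–Wolf estimate computed on
within-class-centered rows, and can be fixed in $[0,1]$. $\lambda = 0$
reproduces classical LDA when $W$ is well-conditioned (verified in the
test suite against an independent reference implementation).

**Conventions.** Features are centered and unit-variance scaled by
default (`scale = FALSE` to disable), since metabolite concentrations
span orders of magnitude. Axes are normalized to unit within-class
variance, $w^\top W_\lambda w = 1$, and the sign of each axis is fixed
by requiring its largest-magnitude loading to be positive, so
coordinates — and every statistic derived from them — are reproducible
across platforms. The solver whitens $W_\lambda$ symmetrically and
eigendecomposes the whitened between-scatter; the test suite checks it
against a dense generalized eigendecomposition through an independent
`solve()`-based route to 1e-8.

**Degenerate inputs.** Fewer than 3 groups cannot define a plane and
are rejected; so are groups with a single sample, identical-sample
inputs (zero between-class scatter), and $\lambda = 0$ with singular
within-scatter (the error advises shrinkage). Fits are strain-wise by
default in the pipeline, mirroring the design where each strain's
six conditions form one ordination; a joint fit is just a different
grouping vector.

**A note on regularized geometry.** Exact duplication of a feature
column is *not* a no-op under ridge shrinkage — the duplicated feature
legitimately carries double weight in the shrunken metric. The suite
therefore checks bounded stability (axis-wise correlation > 0.999)
rather than exact invariance.

## Vector statistics on the plane

- `dissimilarity_coefficient(p1, p2)`: Euclidean distance, typically
  between condition centroids. Centroids (not medoids) are used,
  consistent with LDA's mean geometry.
- `trajectory(e, conditions)`: the centroid polyline across ordered
  conditions; segment lengths are consecutive dissimilarity
  coefficients.
- `disease_severity_index(e, A, B, center)`:
  $D = \sum_{x \in A}\sum_{y \in B} \rho_x \rho_y r_{xy}$ over **all**
  cross-condition sample pairs. The summation set was a genuinely open
  design point; the full cross product was chosen because it makes $D$
  symmetric in its two conditions and reduces to the obvious closed form
  on singleton conditions ($\rho_x \rho_y r_{xy}$). The *center* from
  which $\rho$ is measured is likewise open; the default is the grand
  mean of all embedded samples (which is the origin of the ordination),
  configurable to any condition centroid or fixed point. $D$ is
  rotation-invariant about the center and scales as $s^3$ under uniform
  scaling — both property-tested.

No significance testing is attached to $r$ or $D$; they are reported
descriptively, and a bootstrap would be a natural extension.

## Shortlisting

`differential_test()` runs a per-feature Welch two-sample $t$ test on
natural-log values with Benjamini–Hochberg adjustment per contrast, and
selects features with adjusted $p \le \alpha$ (default 0.05) **and**
geometric-mean fold change beyond the cutoff in either direction
(default 1.5, i.e. $\ge 1.5$ or $\le 1/1.5$). Choices worth stating:

- zeros are replaced by half the smallest positive value in the table
  before logging — the standard pseudo-value device keeping
  fold-change semantics;
- the fold change is computed from geometric means (differences of log
  means), matching the scale on which the test operates;
- selection is monotone in both knobs (tightening either never adds a
  feature), and under a pure null the selected fraction respects the BH
  level — both verified by simulation in the suite.

No moderated-variance (empirical-Bayes) testing and no count-model
differential abundance: with the package's log-normal data model the
Welch test is the defensible default, and both test and cutoff are
configurable.

## Microbiome profiles and evenness

OTUs are filtered by the conventional rule "count ≥ `min_count` in at
least ⌈`prevalence` × n⌉ samples" (defaults 2 and 20%; the ceiling
resolves the fractional-sample ambiguity in the usual direction), then
total-sum scaled to per-sample proportions and aggregated to genus or
phylum by summation. The Evenness Index is Shannon entropy in nats,
$E = -\sum_i p_i \ln p_i$, applied to a composition; it is bounded by
$\ln k$, permutation-invariant, unchanged by zero-proportion categories
and strictly decreased by merging categories — all property-tested. An
optional Pielou normalization ($E/\ln k$) is available behind a flag
and clearly not part of the plain index.

Per-condition evenness is computed on the **condition-mean composition**
(replicates pooled by averaging proportions), matching one $E$ per
condition as plotted in this literature; a per-sample mode
(`per_sample = TRUE`) averages per-replicate entropies instead.
Treated/control ratios are formed per (strain, day).

## Annotation analytics

Pro/anti-inflammatory ratios count shortlist members by label; a ratio
with zero anti-labelled features is serialized as `"undefined"`, never
as infinity. Overlap counts are exact set arithmetic. The clinical
score follows the standard DSS disease-activity convention — weight
loss bands <1/1–5/5–10/10–15/>15% mapping to grades 0–4, stool and
bleeding grades passed through, total 0–12; the bands are an argument,
not a constant, because published rubric tables vary. Correlations
between inflammation markers, phylum abundances and metabolic-category
scores are computed at condition level (12 conditions) with Spearman by
default — at that $n$, rank correlation is the honest choice — with BH
adjustment across all cells and explicit `NA`-with-reason entries for
constant vectors. Category scores are per-category means of
condition-mean log fold changes against the same strain's day-0
control.

## The synthetic study generator

The generator exists so that every downstream stage has data with known
ground truth; its defaults are the study conditions, fixed in
`inst/extdata/default_calibration.yaml` and not in code.

- **Design**: 2 strains × days {0, 7, 15} × 2 arms × 3 replicates
  (the literature reports 6 animals per group but 3 omics replicates;
  3 is the default and `n_per_group` is configurable).
- **OTU counts**: Dirichlet-multinomial per condition (concentration
  200, depth 10,000 in the default bundle) over a six-genus panel —
  Bacteroides and Alistipes (Bacteroidetes), Lachnospiraceae
  (Firmicutes), Helicobacter (Proteobacteria), Akkermansia
  (Verrucomicrobia), plus an unclassified remainder. Real 16S
  replicates are overdispersed, hence Dirichlet-multinomial; plain
  multinomial is recovered at infinite concentration. The calibrated
  kinetics place the Proteobacteria peak at 32% of total abundance in
  treated C57BL/6 on day 15 and 29% in treated BALB/c on day 7, and
  make Akkermansia appear only in the BALB/c day-15 recovery.
  A compact six-genus panel cannot simultaneously push *both* dominant
  phyla down and keep phylum entropy falling while a third phylum rises
  to 32% — entropy arithmetic forbids it — so the calibration lets
  Firmicutes carry the collapse and keeps Bacteroidetes roughly stable
  at peak severity; this preserves the composition peaks and the
  falling treated/control evenness ratio in C57BL/6, which are the
  behaviors the analyses consume.
- **Expression/metabolite layers**: log-normal, value =
  exp(baseline log-mean + condition shift by label + noise), with
  log-sd 0.5 (≈50% CV) and label-specific shifts: pro-inflammatory
  shifts rise monotonically over days in treated C57BL/6 and peak at
  day 7 in treated BALB/c; serum (host) metabolites are displaced most
  at C57BL/6 day 15 and cecal (microbial) metabolites at BALB/c day 7.
  Additive log-scale shifts make the planted effects exactly the
  fold changes the shortlisting rule targets.
- **Clinical records**: per-condition rubric grades with ±1 integer
  jitter clamped to 0–4 and Gaussian weight noise.
- **Seeding**: one master seed is split per layer/condition through a
  deterministic string hash (`derive_seed`), so regenerating one layer
  never perturbs another; everything is bit-reproducible under a fixed
  seed.

What the generator does *not* emulate: read-level artifacts (chimeras,
primer bias, variable depth), compositional correlations between taxa
beyond the Dirichlet's, batch effects, cage effects or any
animal-level correlation across layers (each sample is treated as
independent), and heavy-tailed metabolite noise. Passing tests
therefore demonstrate correctness of the *methods* under the stated
statistical model, not robustness to every artifact of real data.

## Numerical and testing choices

Tolerances: exact closed forms are asserted at 1e-9–1e-12; the LDA
oracle agreement at 1e-8; compositions must sum to 1 within 1e-9.
Monte-Carlo checks compare means within 3 standard errors. The
planted-shift shortlisting fixture uses log-sd 0.3 (≈30% CV, typical of
quantitative NMR), the noise level at which a Welch test at the
BH-corrected threshold retains ≥80% power against a 3-fold shift at
n = 5 per group. Simulation-based suites use 20–200 replicates at the
default table sizes (36 samples; 120 transcripts; 40 metabolites per
fluid; 6 OTUs at depth 10,000), sizes chosen so the entire suite runs
in well under a minute while keeping Monte-Carlo error small relative
to the effects asserted. The composition-recovery analysis
(`scripts/acceptance.R`) uses 50 replicate simulations at depth 50,000.

The pipeline writes plain TSV only, with numbers at 15 significant
digits (round-trip safe), and a JSON manifest of config echo, package
version, seed and per-file MD5 checksums. The manifest deliberately
contains no timestamps or absolute paths, so identical configs and
seeds yield byte-identical manifests; stage timing goes to the console
log. Stages whose outputs exist are skipped, making the pipeline
restartable after deleting any stage's files.

## Known limitations

- LDA axes are estimated, not inferential: no confidence regions on
  centroids, trajectories, $r$ or $D$.
- The Disease Severity Index grows with replicate count (it is a sum,
  not a mean); compare it only between condition pairs with equal
  sample counts, as in the balanced designs it serves.
- Evenness on condition-mean compositions hides replicate variance;
  use `per_sample = TRUE` when that matters.
- The correlation analytics treat conditions as exchangeable units and
  ignore the day ordering; they describe association, not dynamics.
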