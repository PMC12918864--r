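---
title: "Methods: models, parameters and design choices in mechscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mechscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechscreen)
```

mechscreen analyzes pooled CRISPR-knockout screens whose selection step is
*mechanical*: cells flow through a channel of diagonal ridges, stiff cells
are deflected ridge by ridge toward the "stiff" outlets, and the sgRNA
distribution of each outlet is compared against the inlet to find knockouts
that change cell stiffness. This vignette describes the statistical models,
the tunable parameters, and the design decisions taken where the problem
admitted more than one defensible answer. No empirical claims are made here
beyond what the package's tests and `scripts/acceptance.R` themselves
compute.

## The synthetic screen generator

All pipeline inputs can be simulated with known ground truth, which is what
makes the chain testable end to end.

**Guide library.** `make_guide_library()` draws unique random 20-nt ACGT
protospacers for `n_genes × guides_per_gene` guides. The genome-scale
libraries this emulates carry roughly 3–6 guides per gene depending on the
design; we leave `guides_per_gene` as a parameter (4 in all shipped runs, a
value both common designs bracket).

**Inlet abundances.** Drawn log-normal (`abundance_sdlog`, default 0.5) and
normalized to a simplex. A log-normal inlet is the standard picture of an
unevenly represented pooled library and gives the Gini-index QC something
real to measure (a perfectly uniform library would pin G = 0 everywhere).

**Sorting effects.** Each outlet carries a per-gene *weight multiplier*
(≥ 0, 1 = neutral): the outlet's expected guide profile is the inlet profile
times the multipliers, renormalized. Multiplicative weights keep outlet
profiles on the simplex, which additive shifts would not. A consequence
worth knowing: renormalization caps the achievable fold change at
`1/(inlet share of affected genes)`, so a demo planting 5 of 200 genes can
never reach 100-fold — the shipped demo therefore plants one dominant
knockout (weight 600) plus four moderate ones (weight 8).

**Sequencing noise.** Counts are negative binomial with mean
`depth × abundance` and overdispersion `dispersion` (default 0.05;
`Var = μ + αμ²`), degrading to Poisson at `dispersion = 0`. Note that
summing `g` independent NB guides gives a gene-level dispersion of roughly
`α/g`; the dispersion estimator sees the gene level.

**Reads.** `write_screen_fastq()` emits
`anchor + protospacer + random filler` with a constant quality string
(quality is not consumed downstream) — so quantification must reproduce the
generating matrix *exactly*, and the tests assert that identity at the
million-read scale. Sequencing errors, quality decay and chimeric reads are
deliberately not modeled: passing the round trip shows the counting logic is
correct, not that it is robust to a real instrument's error profile.

## Quantification and QC

Extraction is anchored: the 20 bases after the first exact occurrence of the
19-nt vector anchor (`TTGTGGAAAGGACGAAACA`); a positional fallback (first 20
bases) is available. Matching is exact hash lookup — pooled-screen pipelines
commonly count exact matches, and a mismatch-tolerant mode would change the
single source of truth the round-trip test relies on. Reads without anchor
or too short are "unextracted", extracted non-library sequences "unmapped";
`mapped + unmapped + unextracted = total` is asserted per sample. The Gini
index is computed on raw per-sample counts including zeros; an all-zero
sample is flagged, not an error.

## The enrichment model

Each outlet is tested against the inlet in its own two-condition fit:

* **Size factors**: median-of-ratios against the geometric-mean reference
  over genes positive in all samples, rescaled to geometric mean 1.
* **Dispersion**: method-of-moments per gene on normalized counts, variance
  pooled within condition; a parametric trend `α(μ) = a₁/μ + a₀` fitted by
  least squares on the *unfloored* estimates of all expressed genes (fitting
  only above-floor genes would bias the trend up). The dispersion used for
  testing is the trend value (floored at `α_min = 1e-8`).
* **Wald test**: per gene, IRLS for `log μ = log s + β₀ + β₁·[outlet]` with
  weights `μ/(1+αμ)`, tolerance 1e-8 on β, max 100 iterations, coefficients
  clamped at ±50; `SE` from the observed information, two-sided normal p,
  BH within outlet, hits at padj < 0.001.

**Why trend-only dispersion?** With 4+4 replicates the gene-wise estimate
has a standard deviation around 0.58·α (df = 6); taking
`max(gene estimate, trend)` — a tempting conservative rule — inflates the
working dispersion by ~0.4 sd on average and costs real calibration: on a
2000-gene null simulation it yields P(p < 0.05) ≈ 0.014 where the trend-only
choice gives ≈ 0.049. Since the synthetic generator shares one dispersion
level across genes (and real screens are close to that within the trend),
the parametric fit is both better calibrated and closer to the
"variance is stabilized with a parametric fit" description of the original
analysis. The conservative rule remains available
(`estimate_dispersions(..., method = "max")`). No empirical-Bayes shrinkage,
outlier refitting or independent filtering is attempted — hit lists are not
expected to match a full DESeq2 run numerically.

Genes all-zero in both conditions are excluded and reported; non-converged
fits (e.g. a condition with all-zero counts, whose MLE is infinite) are
flagged with p = 1 rather than dropped. Guide-level fold changes use
normalized means with pseudocount 0.5 on both sides
(`FC = (out + ½)/(in + ½)`), and a gene's summary is the *max* over its
guides — a gene passes the >100-fold filter if any guide does.

## AFM force curves

The forward model places Hertzian contact on a uniform piezo grid (default
1024 points over 4 µm): below the contact point `z₀` the force is baseline
(`slope·z + noise`); above it the indentation solves
`F = (4/3) E_r √R δ^{3/2}` self-consistently with cantilever deflection,
`δ = (z − z₀) − F/k`. The solver is a safeguarded Newton iteration on the
monotone convex residual, tolerance 1e-6 nm. Defaults mirror a typical
cell-indentation setup: bead radius R = 3660 nm (7.32 µm particle), spring
constant k = 30 pN/nm, 10 nN trigger force.

Fitting is two-stage. Stage 1 intersects a least-squares baseline line
(first 40% of points) with a contact-region line (last 20%); near-parallel
lines fall back to the first point exceeding baseline + 3 noise-sd and are
flagged. Stage 2 tests every candidate contact sample within ±25 samples:
baseline-subtracted force against `(4/3)√R δ^{3/2}` is a *linear* least
squares in E_r (identical optimum to a nonlinear fit, no initialization
issue), fit range contact → trigger, and the candidate with minimal RSS
wins. Because the stage-1 estimate can land far outside the window on
strongly curved contact regions, the window re-centers on the argmin and
repeats while the optimum sits at a window edge; a persistent edge optimum
is flagged `boundary-window`. Candidate contact points are grid samples, so
recovery is exact only when the true z₀ is representable on the grid —
recovery suites use grids containing z₀ and otherwise expect agreement to
one sample spacing. Retract segments, adhesion, viscoelasticity and tip
calibration are out of scope; E = E_r(1−ν²) conversion is offered with
ν = 0.5 by default.

## Ridge tracks

A cell "interacts" with ridge *i* while its along-flow distance to the
inclined centerline, `x − [x₀ᵢ + (y − y_ref)·tanθ]`, stays within ±w/2 —
the device literature does not define an interaction window, so we take the
ridge width plus about one cell diameter (default w = 40 µm, configurable).
Per ridge, deflection is y(last window frame) − y(first window frame)
(start-to-end, not peak-to-trough) over the *longest* contiguous frame run,
and interaction time is the run length divided by fps. Cumulative statistics
sum the first 5 ridges, missing windows contributing zero. Positive y points
toward the stiff outlets. Tracks with fewer than 2 frames are excluded, and
fragments are analyzed as-is — no re-linking or gap filling.

The generator builds trajectories directly in the along-flow coordinate, so
its windows coincide with the analysis rule; the per-ridge deflection ramps
over the middle of the dwell (plateaus at the edges) so the sampled
start-to-end difference equals the generated truth exactly at any frame
phase. Two caveats that bound what passing tests show: with inclined ridges
the window coordinate contains y, so y-noise can flip frame membership near
window edges (interaction time is exactly noise-invariant only at θ = 0);
and the constant-speed, instant-deflection kinematics are a caricature of
the real hydrodynamics — the tests validate the *measurement*, not the
device physics.

## Statistics

Welch's t (with Welch–Satterthwaite df), the Brown–Forsythe variance test
(ANOVA F on |x − group median|; even-sized groups use the mean of the
central pair as median), BH step-up adjustment, Kaplan–Meier and the
two-group log-rank test with hypergeometric variance under simultaneous
risk-set accounting are all delegated to base R / survival behind a thin
surface that adds the degenerate-case contracts: two constant equal samples
give t = 0, p = 1 (differing means p = 0) with a flag; all-zero deviations
give W = 0, p = 1; no events give χ² = 0, p = 1. The KM median uses the
first time S(t) ≤ 0.5, matching common survival plotters (undefined if the
curve never crosses). The Gini index is computed from the sorted-order
closed form and cross-checked in tests against the O(n²) pairwise form.

## Prioritization

Terciles are rank-based: cut at the 1/3 and 2/3 empirical quantiles, group
sizes differing by at most one, ties resolved by stable input order toward
the lower tercile; all-equal expression is an error, and any monotone
transform of expression leaves labels unchanged. Patient trichotomization
compares bottom vs top expression terciles (the middle third is discarded)
with the log-rank test per endpoint; the reported median difference is
median(low) − median(high) in months. The candidate filter is a pure
conjunction — commutative, monotone (relaxing a filter can only grow the
set), with genes missing from a lookup table failing that filter explicitly
and the missing source recorded.

## Problem sizes and runtime choices

Shipped simulations are sized for interactive use on one core: the demo
screen is 200 genes × 4 guides at 100 reads/guide; calibration suites use
2000 genes (null) and 1000 genes with 50 planted 8-fold effects (recovery)
at 300 reads/guide with 4+4 replicates; the AFM arm fits 150 curves per
group and trajectory suites use up to 280 tracks per group with a 6-ridge
geometry. These scales keep each acceptance check in seconds-to-a-minute
while leaving Monte-Carlo error well inside the asserted bands.

## Known limitations

* Exact-match counting only; no mismatch rescue or UMI handling.
* Dispersion moderation is a parametric trend, not empirical Bayes; single
  replicate designs fall back to the floor dispersion with a warning.
* The survival module consumes user-supplied cohort tables; it does not
  reproduce any external database's cohort, probe selection or censoring.
* The track simulator validates metrics, not hydrodynamics; outlet
  predictions depend entirely on the configured outlet boundaries.
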