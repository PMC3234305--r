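---
title: "Clustering and counting MS/MS spectra without a search engine: the qfish model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and counting MS/MS spectra without a search engine: the qfish model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qfish)
```

## The problem

In label-free shotgun proteomics a peptide's abundance can be estimated by
counting the MS/MS spectra attributed to it. The usual route — identify each
spectrum with a database or spectral-library search, then count per peptide —
discards every spectrum the engine cannot assign, which in ion-trap data is
most of them. But identification is not actually required for *counting*:
replicate spectra of one peptide share a precursor m/z, a fragment peak
pattern, and a narrow elution window. `qfish` clusters spectra directly on
those observables and counts cluster members per replicate, so unidentified
and novel peptides are quantified alongside known ones. Optional
identifications (of member spectra or of the cluster's reference spectrum)
can be attached afterwards purely for reporting.

## Spectrum representation

Each admitted spectrum (non-empty peak list, at least one positive intensity,
positive precursor m/z) is:

1. **scale-standardized** — intensities divided by their maximum, removing
   total-ion-current differences between acquisitions;
2. **binned** on a fixed half-open grid (`grid_config()`, default
   `[200, 2000)` Da at 0.1 Da), duplicate m/z and within-bin peaks summed
   before standardization;
3. **smoothed** with a moving window of `window_k` bins and stride one bin,
   `m[i] = Σ_{j=0}^{K-1} w_j y[i+j]`, giving a profile of length
   `bins − K + 1`.

The window exists to absorb small m/z calibration differences: two spectra of
the same peptide whose peaks sit one 0.1 Da bin apart have near-zero binwise
correlation but highly correlated smoothed profiles (this shift-robustness is
asserted in the test suite). The default `K = 30` spans 3 Da — comfortably
wider than typical ion-trap fragment mass error, narrower than the spacing of
unrelated fragment series. The profile length is always *derived* from the
grid, never hard-coded.

Two kernels are provided. Uniform weights are `1/K`. The Gaussian kernel
evaluates the standard normal density at the standardized within-window
bin-center m/z offsets and renormalizes to sum 1; because the bin centers in
any window are the same arithmetic sequence, this is one fixed symmetric bell
for all window positions. Weights summing to 1 keep profiles of `[0, 1]`
vectors inside `[0, 1]`. Similarity between spectra is the Pearson
correlation of their profiles (`correlation_index()`), which inherits
invariance to positive affine rescaling; a zero-variance profile (a
near-empty spectrum) yields `r = 0` with a warning rather than an error, so
such spectra never merge but the pipeline stays total.

## Two-stage clustering

**Stage 1 — precursor grouping.** Spectra of one peptide share their
precursor within instrument error, so clusters must satisfy a *pairwise*
bound: any two members' precursor m/z differ by at most the tolerance
(default 1 Da, i.e. a ±1 Da window, applied to the reported m/z in Da).
Complete-linkage agglomeration cut at the tolerance enforces exactly this
diameter bound; plain connected components would chain far beyond it. On a
one-dimensional axis the minimum-distance pair under complete linkage is
always adjacent in sorted order, so grouping is an O(n²) adjacent-interval
merge. When merge distances tie, the pair containing the lowest input index
merges first, making the partition deterministic. Precursor charge is ignored
by default (the charge is frequently unknown in the data this models);
`split_by_charge = TRUE` pre-partitions by known charge.

**Stage 2 — profile clustering.** Within each precursor group, single-linkage
clustering on `d = 1 − r` cut at `1 − ρ` (default `ρ = 0.6`). The resulting
partition equals the connected components of the graph with edges where
`r ≥ ρ`; the test suite verifies that equivalence against an independent
graph-traversal oracle on hundreds of random instances, and the
package-internal route goes through `stats::hclust`. All replicates of all
groups are clustered jointly, then counted per replicate, so a cluster can
(and should) mix members from both sample groups.

Each cluster's **reference spectrum** is the bin-wise mean of its members'
standardized binned spectra, and its **Q score** is the mean correlation
between the reference's profile and each member's profile — 1.0 for
singletons and identical members, decreasing with within-cluster noise.
Counting conserves spectra exactly: column sums of the cluster × replicate
count matrix equal the number of admitted spectra per replicate.

## Retention-time validation: the false clustering rate

A correctly assembled cluster elutes in one chromatographic window, so the
percent coefficient of variation (sample SD over mean, `cluster_cv()`) of its
members' retention times is small. CV rather than SD is used because elution
times span hours while peak widths scale roughly with elution time. The
*false clustering rate* asks how often clusters as tight as the observed ones
arise by chance: retention times of all spectra in size-≥2 clusters are
pooled, permuted, and dealt back into the same size template `P` times
(default 100), and

FCR(Δ) = mean over permutations of `#{CV_p ≤ Δ} / #{CV ≤ Δ}`.

Singletons are excluded from numerator and denominator (their CV is
undefined). The statistic can exceed 1 — permuted clusters occasionally come
out tighter than observed — and is reported unclamped with a warning rather
than silently truncated. When no observed cluster passes Δ the FCR is
undefined and reported `NA`. `scan_delta()` profiles FCR over a Δ grid;
`scan_rho()` re-clusters at each candidate correlation cutoff and evaluates
FCR at the fixed Δ — the published workflow's table of FCR against ρ is
under-specified about the exact procedure, and this re-clustering reading is
the interpretation implemented here. `choose_threshold()` picks the grid
value whose FCR is closest to the 0.05 target from below. A cluster "passes"
the validation when its CV is at most the chosen Δ; the global FCR certifies
the threshold rather than being a per-cluster error estimate.

An exhaustive mode (`compute_fcr(..., exhaustive = TRUE)`) enumerates all
permutations for small instances; it is the oracle against which the sampled
estimator is tested, and sampling error shrinks as `1/√P`.

## The beta-binomial differential test

Counts `x_j` out of replicate totals `n_j` (column sums over *all* clusters,
computed before any filtering) are modelled as binomial with a
beta-distributed proportion, giving the beta-binomial marginal
`p(x | α, β, n) = C(n, x) B(α + x, n + β − x) / B(α, β)` in the mean /
overdispersion parameterization `π = α/(α+β) = h(Xb)`, `φ = 1/(α+β+1)`, with
`E x = nπ` and `Var x = nπ(1−π)[1 + (n−1)φ]`. The link `h` is logit by
default (complementary log-log available). One `φ` is shared across both
groups within a cluster. Maximization is by `nlminb` on `(b, logit φ)` with a
deterministic two-point multi-start (moment estimates, and the pooled
proportion with `φ = 0.01`); fits driven to the `φ` boundary are reported as
binomial fits and flagged, as are all-zero/saturated clusters. The marginal
pmf is computed through log-beta functions, with the binomial limit
substituted below `φ = 10⁻¹²`; the test suite checks it against numerical
quadrature of the defining integral and exact normalization.

The group effect is tested per cluster by the likelihood ratio statistic
`stat = max(0, 2(ℓ_alt − ℓ_null))`. **Reference distribution:** with three
replicates per group, referring `stat` to χ²₁ is badly anticonservative —
measured type-I error ≈ 0.14 at nominal 0.05 — because `φ` is a nuisance
parameter estimated from six observations; the Gaussian analogue
(`stat = N log(1 + t²/(N−2))`) predicts exactly this inflation, the same way
a z-test misbehaves where a t-test is required. The default reference
therefore inverts that transform, `t² = (N−2)(e^{stat/N} − 1)`, and refers
`t` to a t distribution with `N − 2` degrees of freedom (`N` = number of
replicates). This restores type-I error to its nominal level in simulation
while leaving the statistic itself untouched; the asymptotic χ² reference
remains available (`ref = "chisq"`), and with fewer than three replicates in
total it is the fallback. Only clusters observed in *both* groups (and, in
the full pipeline, passing the CV filter at the certified Δ) are tested;
group-exclusive clusters are reported descriptively. P-values are adjusted
with Benjamini–Hochberg (`stats::p.adjust` behind `bh_adjust()`), with
non-converged fits excluded from the number of tests.

## What the synthetic generator does and does not emulate

`sim_config()` defaults describe a two-group, three-replicate study at desk
scale: 30 peptide templates with 20–40 fragment peaks each, precursors spaced
≥ 2 Da apart (collision on request for stress tests), pairwise template
profile correlation rejection-sampled below 0.3, elution times uniform over a
1800–7200 s gradient. Acquisition counts per template, replicate are Poisson
(mean 4); each acquisition applies multiplicative lognormal intensity noise
(log-sd 0.3), independent peak dropout (0.1), Gaussian fragment m/z jitter
(0.02 Da), precursor error (0.2 Da) and retention-time jitter (20 s —
within-peptide CV well below 1% of elution time, as in real chromatography).
A 10% fraction of templates carries a group effect at abundance odds ratio 4
(rates scaled by √OR up in the first group, down in the second).
`emit_counts()` samples the count model directly (defaults `π = 0.01`,
`φ = 0.05`, totals 5000 per replicate — counts in the tens out of thousands,
as in real runs) for testing the differential module without spectra.

Real data differ in ways the generator does not model: chimeric spectra,
isotope structure and charge-dependent fragmentation, correlated (not
independent) peak dropout, retention-time drift between runs, and precursor-
dependent m/z error. Passing tests therefore demonstrate correctness of the
algorithms under the model's own assumptions, not performance on any
particular instrument's data.

## Numerical and design choices

* Binning is half-open `[lo, hi)`; out-of-range peaks are dropped and
  counted; duplicate m/z entries merge by summing (preserving total ion
  current).
* The m/z grid default is 200–2000 Da. One published description of this
  workflow gives the profile length for a 20–2000 Da grid while its prose
  states 200–2000 Da; the prose range matches ion-trap scan ranges and is
  used here, with the profile length always derived.
* Optimizer tolerances: `nlminb` relative tolerance 1e-10, 500 iterations;
  `φ` estimated on the logit scale, boundary declared below 1e-6.
* Ties in stage-1 merging break to the lowest input index; stage-2 partitions
  are cut-height partitions and therefore tie-invariant.
* Degenerate inputs: all-zero spectra are rejected at ingest with a count;
  zero-variance profiles correlate as 0 with a warning; singleton clusters
  score Q = 1 and are FCR-ineligible; an empty denominator yields `NA` FCR.
* All randomness (permutations, simulations) flows from explicit seeds;
  results are byte-identical on re-run with the same configuration.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run on narrowed m/z grids
(200–320 or 200–500 Da at 0.1 Da, keeping the 3 Da window) with 8–12
templates and a few hundred spectra per run; the calibration study uses 1000
all-null clusters at the 3+3 design, power curves 400 clusters per odds
ratio, and overdispersion recovery 500 clusters at `π = 0.01`, `φ = 0.05`,
totals 5000. These sizes were chosen as the smallest at which the Monte-Carlo
error of each check is comfortably below the effect being asserted. Power
simulations use `φ = 0.01`: at `φ = 0.05` the between-replicate proportion
noise (SD ≈ 0.022 around π = 0.01) swamps even a four-fold effect at three
replicates per group, so every rejection rate sits at the α floor and
ordering by effect size would be noise — a regime worth knowing about when
planning real studies.

## Known limitations

* Two groups only; the model extends to more, but the interface does not.
* No empirical-Bayes sharing of `φ` across clusters; each cluster stands
  alone, which costs power at few replicates.
* No retention-time alignment across runs (by design — the CV/FCR machinery
  is the alternative), and no peak picking, deisotoping or charge
  deconvolution: input must be centroided peak lists.
* Clusters from different grid configurations are not comparable.
* The FCR certifies thresholds globally; it is not a per-cluster q-value.
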