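---
title: "Methods: chemometric authentication of milk from DESI-MS fingerprints"
author: "desimilk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemometric authentication of milk from DESI-MS fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Desorption electrospray ionisation mass spectrometry (DESI-MS) records a
lipid-dominated fingerprint of a diluted milk sample in seconds. Because the
lipid complement differs between cow, goat, camel, oat and soya milk —
glycerophospholipids (PA species), sphingolipids (ceramides,
inositol-phosphoceramides) and acyl-CoAs dominating the dairy milks,
triacylglycerols the plant and camel milks — a chemometric model over binned
positive-mode spectra can call the species of a milk sample and detect
cow-milk admixture in products sold as something else. `desimilk`
implements that workflow end to end: mass binning and filtering, PCA-LDA
classification with bootstrap validation, binary OPLS-DA with S-plot
biomarker selection, formula-level marker annotation, and mixture-series
limit-of-detection analysis, together with a synthetic spectrum generator
that stands in for instrument data.

# Preprocessing

**Binning.** Centroided peak lists are accumulated onto a fixed grid of
half-open 0.2 Da bins over m/z 100–2000 (9500 bins), each labelled by its
center. Centers sit at odd multiples of 0.1, so the bin labelled 537.3
covers [537.2, 537.4). This is the unique 0.2 Da convention under which the
bundled marker table's measured masses fall into their printed bins (27 of
28 do; the row labelled 1232.7 carries a representative mass of 1230.6704
and is shipped as printed, surfaced by `verifyMarkerTable()` rather than
silently corrected). A grid of 0.2 Da steps over 100-2000 is sometimes
described as having 9501 components, which counts both endpoints as bin
boundaries' labels; (2000 − 100)/0.2 gives 9500 half-open bins and that is
what the grid implements.

**Intensity limit.** The spectral intensity limit of 1.00e6 counts is
interpreted as a per-scan total-ion-count threshold applied before scan
averaging (`filterScans()`): it is the reading under which the limit can
reject failed acquisitions. Samples whose scans all fail are reported
together as errors, never silently dropped.

**Scan combination.** Replicate scans are binned first and the binned
vectors averaged arithmetically (`averageScans()`). Bin-then-average is
insensitive to centroid jitter between scans; with a 0.2 Da bin and ~10 ppm
jitter the two orders are nearly identical, but the choice is fixed for
reproducibility.

**Normalisation and scaling.** TIC (row-sum) normalisation is ON by default
for the classification pipeline — it removes the per-scan ionisation-yield
factor — and OFF for the S-plot reproduction, whose tabulated statistics
were computed on unnormalised exports; both are explicit flags. Scaling
(`scaleMatrix()`) offers mean-centering, Pareto scaling (divide centered
columns by the square root of the standard deviation — the customary
compromise that tempers high-intensity lipid peaks without blowing up
noise bins) and unit variance. The standard deviation is the population
(divide-by-N) form; either convention is defensible, one must be declared
for bit-reproducibility. Zero-variance columns are centered only. The
recorded means and scales invert the transform exactly
(`unscaleMatrix()`).

# PCA-LDA classification

`fitPCA()` extracts components from the SVD of the centered matrix; the
sign of each component is fixed by making its largest-magnitude loading
positive. `fitLDA()` projects onto the leading components (by default the
smallest number reaching 95% cumulative R2X, capped at min(samples − 1,
60) — the instrument software's internal rule is undocumented, so the
package declares its own and exposes it) and computes Fisher discriminant
axes with a ridge-regularised pooled within-class covariance.

**Q2 for PCA.** Predictive ability is estimated by row-wise k-fold
cross-validation (deterministic interleaved folds, 7 by default) with
*element-wise-corrected* reconstruction: each coordinate of a held-out row
is predicted from the row's other coordinates through the training
loadings (closed-form Sherman–Morrison downdate). The naive alternative —
projecting the whole held-out row onto the loadings — is a contraction and
cannot increase the residual, so it would report Q2 > 0 even on pure
noise; the corrected form goes negative there, which is the behaviour a
model-dimensionality diagnostic needs.

**Classification and outliers.** Spectra are assigned to the nearest class
centroid by Mahalanobis distance in discriminant space; a spectrum farther
than `outlierSigma` (default 5) standard deviations from every centroid is
flagged as an outlier and reported separately, never dropped silently.
Correct classification rates are always reported both excluding and
including outliers, since which denominator the original instrument
software used is unknowable. Models are fitted on per-sample averaged rows
(one spectrum per sample) but classify individual spectra; because
averaging 6–9 scans shrinks the within-class covariance roughly
seven-fold, `bootstrapCCR()` recalibrates the pooled covariance on
spectrum-level training rows (`calibrateCovariance()`) so that the
5-sigma radius is expressed in spectrum-level units. Without this
recalibration most held-out spectra would be flagged as outliers.

**Bootstrap CCR.** `bootstrapCCR()` repeats stratified 80/20 splits at the
*sample* level — all spectra of a sample stay on one side — and counts the
CCR at the *spectrum* level over held-out spectra, 25 repeats by default,
seeded.

# OPLS-DA and the S-plot

`fitOPLS()` is a binary (strictly two-class, matching its use for
cow-vs-rest and cow-vs-goat contrasts) OPLS-DA: `nOrth` orthogonal
components are removed (weights from the loading's component orthogonal to
w, deflation by the orthogonal score-loading product), then a single
predictive component is fitted; with `nOrth = 0` the model coincides with
textbook single-component PLS1, which is the oracle its tests compare
against. The default `nOrth` is 1 — the component count is never stated in
the originating workflow, and one orthogonal component is the customary
starting point. Q2 is stratified 7-fold cross-validation of the predicted
class value; the permutation test refits the model under label permutation
(identity permutations excluded) and declares the model valid when every
permuted Q2 falls below the original — the classical permutation-plot
criterion.

The S-plot reports, per bin, `p1 = cov(t, x)` (influence, model scale) and
`pcorr = cor(t, x)` (reliability), both with the sample (N−1) convention;
zero-variance bins get zeros. Marker selection applies |pcorr| ≥ 0.5 and
|p1| ≥ 0.05 *inclusively*, so a tabulated value sitting exactly on a
threshold (the camel marker's p1 = 0.050) is selected and the bundled
28-row table reproduces its own selection. Under the cow = −1 encoding,
negative-sign markers are cow-associated. Coefficients are mapped back to
bin space through the orthogonal deflations, so coefficient-path and
score-path predictions agree exactly.

# Lipid annotation

Elemental formulas (C, H, N, O, P, S; optional integer counts; Hill-order
serialisation) are parsed and given monoisotopic masses from fixed
constants (C 12, H 1.00782503, N 14.00307401, O 15.99491462, P 30.97376200,
S 31.97207117 Da). Adducts are positive-mode [M+H]+ only, with the
electron-corrected proton mass 1.00727646 Da: the bundled table's accurate
masses match M + proton to four decimals, not M + H-atom. The 28-row
marker table ships as a checksummed TSV; `verifyMarkerTable()` recomputes
every [M+H]+ (all 28 agree within ±0.001 Da, the worst deviation being
0.05 mDa) and every bin label. `matchPeak()` matches observed m/z by ppm;
`matchFragments()` matches MS/MS daughter ions at Da-scale (bin-resolution)
tolerance, since fragment masses are typically quoted at 0.1 m/z.

# Adulteration analysis

`defaultDesigns()` encodes the reference mixing series (v/v cow milk into
each base milk): goat 0/5/10/20/50/100%, camel 0/0.5/1/2/5/10/20/50/100%,
oat 0/0.5/5/10/20/50/100%, soya 0/0.1/1/2/5/10/20/50/100%.

**Level models.** `fitLevelLDA()` treats the levels of one series as
unordered classes (ordinal structure is assessed afterwards by the
Spearman correlation of the LD1 centroids with the cow fraction). Two
choices matter. First, it works on log intensities: mixing is
multiplicative at trace levels, so adjacent levels (0.5% vs 1%) are
equidistant on the log scale but crushed together linearly. Second, the
100% endpoint is excluded by default: it is pure cow milk — a different
species, not an adulteration level — and only there do the base milk's own
marker ions vanish, which would rotate LD1 off the mixing trajectory.
With these choices the level CCR reaches the 90–100% range on the default
synthetic series and the LD1 centroids rise monotonically with the cow
fraction.

**Limit of detection.** The underlying workflow states detection limits
but not the rule that produced them, so the rule here is the package's
own, exposed in configuration. For each nonzero level L, a detection axis
is built from the training split as a matched filter on log intensities:
the mean difference between the pooled samples at level ≥ L and the pure
samples, restricted to bins that (i) pass a 3-SE screen against the pooled
within-level spectrum variance, (ii) carry at least 5% of the maximal
contrast, and (iii) *increase* with adulteration. Held-out spectra of
level L are called adulterated when their score exceeds a one-sided cut
calibrated on the pure training spectra (mean + 2 sd, floored at the
largest pure training score — a distribution-free guard, since sparse
background hits skew the pure score distribution). The LOD is the
smallest level whose held-out detection rate reaches 0.8; level-0 spectra
beyond the cut give the false-positive rate. The design rationale: trace
adulteration manifests as the *presence* of cow marker ions in otherwise
near-empty bins, which log intensities express; pooled-class Fisher
constructions fail here because the adulteration gradient itself inflates
the "adulterated" class's within-variance, and PCA-compressed axes bury
the trace markers under high-variance base-milk bins — both failure modes
were measured, not conjectured, during development. Restricting to
increasing bins matters because base-milk bins carry farm-specific
variation that an unseen farm would otherwise turn into false positives.

On default synthetic studies this yields LODs of 0.1% for soya and 0.5%
for camel and oat — the smallest levels of their designs. The goat series
is the honest exception: goat milk already carries the cow markers at
three quarters of their cow level with ~10% farm-to-farm variation, so
trace cow addition to goat is undetectable under this generator and the
goat LOD comes out at 50% or "not detected"; distinguishing the two
dairy species is instead the job of the dedicated binary cow-vs-goat
model.

# The synthetic study generator

No public DESI milk dataset exists, so `simulateStudy()` generates one
with the statistical structure the analysis assumes. The study design
follows the reference conditions: 103 cow, 27 goat, 36 camel, 34 oat and
73 soya samples (30 cow farms, 2 goat farms, 2 camel distributors, 4 oat
factories, 5 soya suppliers), 6–9 replicate scans per sample, plus the
four mixture series above.

Per-species expected profiles are built from the bundled marker table:
the cow profile carries the 23 cow markers at their *representative*
(measured) masses — so ppm-scale annotation is exercised with realistic
offsets — with base intensity proportional to tabulated |p1|; goat keeps
the cow markers shrunk by the goat-cow similarity factor plus a few small
private peaks, making it the hardest class; camel, oat and soya carry
their tabulated glycerolipid markers, shared across that trio at a reduced
cross-level (their lipidomes are all TG-rich; the table attributes each
marker to the species where it is most abundant), plus private peaks. All
species share a common 40-peak lipid backbone. Peak positions of backbone
and private peaks are deterministic (a fixed internal seed, restored
afterwards), identical in every study.

The noise laws are the package's own: per-scan peak intensities are
lognormal around the expected profile (sigma 0.30, ~30% CV — the scale of
ambient-MS replicate variability), m/z jitter is Gaussian at 10 ppm
(consistent with the deviations between measured and theoretical masses in
the marker table, up to ~30 ppm), background peaks are Poisson (mean 150
per scan) at uniform m/z with exponential intensities (mean 800 counts),
each scan carries a lognormal TIC factor (sigma 0.25), and each
farm/supplier draws a per-lipid lognormal offset (sigma 0.10) applied to
its marker peaks — per-lipid rather than a single scalar, because one
scalar on all markers would mimic exactly the cow-goat contrast.
Mixtures are peak-wise linear: the expected α-mixture intensity is
(1−α)·base + α·cow on the union of peak positions. All constants live in
`inst/extdata/sim_defaults.yaml`, not in code, and were calibrated once so
that default runs land in the reference qualitative regime: camel, oat
and soya separate from cow perfectly, goat is strictly the hardest class
(a few percent of cow/goat spectra cross over), the OPLS-DA model
validates by permutation, and the soya LOD is sub-1%.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: isotopologue envelopes, chemical (dense) rather
than sparse background noise, correlated matrix effects between lipids,
in-source fragmentation, detector saturation, and drift over an
acquisition batch. The per-species spectrum totals of a real study are
also not reproduced exactly (replicate counts are uniform on 6–9; real
acquisitions lose scans unevenly).

# Problem sizes and numerical choices

The test suite and the acceptance script run a scaled-down study — 42 pure
samples (10 cow, 8 each of the rest) and 5 samples per mixture level —
chosen as the smallest size at which the regime above is stable across
seeds; the full-design generator (273 pure samples) is exercised for its
counts. Bootstrap CCRs use 5 repeats there (default 25). Degenerate
inputs are handled explicitly: zero-TIC rows are removed with a warning at
normalisation, never divided; constant columns are centered only;
zero-variance bins get zero S-plot statistics; all-outlier classifications
yield NaN for the excluding-outliers rate; ties in nearest-centroid
assignment resolve to the first class in sorted order. Mahalanobis
pooled covariances carry a relative ridge of 1e-8 times the mean diagonal.

# Known limitations

Multiclass OPLS-DA is deliberately out of scope (binary contrasts only,
as used for cow-vs-rest and cow-vs-goat); quantitative regression of the
adulteration fraction (PLS on α) is not attempted — the LOD rule is a
detector, not a calibration; mzML support is read-only, centroid-mode,
uncompressed arrays; and the t-tests sometimes mentioned alongside
S-plots are not implemented, since no test statistic or correction is
specified for them anywhere in the originating workflow.
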