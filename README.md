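# desimilk

Chemometric authentication of milk species from DESI-MS lipid fingerprints.

Ambient desorption electrospray ionisation mass spectrometry (DESI-MS)
fingerprints a water-diluted milk sample in seconds, without chromatography
or clean-up. Because the lipidome differs between cow, goat, camel, oat and
soya milk — glycerophospholipids (PA), ceramides and acyl-CoAs dominating
the dairy milks, triacylglycerols the plant and camel milks — a multivariate
model over binned positive-mode spectra can identify the species of a milk
sample and detect fraudulent or accidental cow-milk admixture in products
sold as something else. The package is aimed at food-authenticity and
ambient-MS researchers who need the full downstream workflow as tested,
scriptable R.

## What it implements

* **Preprocessing** — centroided peak lists binned onto 9500 half-open
  0.2 Da bins over m/z 100–2000 (bin centers at odd tenths, e.g. 537.3
  labels [537.2, 537.4)), a per-scan total-ion-count limit of 1e6 counts,
  bin-then-average scan combination, TIC normalisation, mean-centering and
  Pareto scaling (`binGrid()`, `buildFeatureMatrix()`, `ticNormalize()`,
  `scaleMatrix()`).
* **PCA-LDA classification** — PCA (SVD, deterministic sign convention)
  with element-wise cross-validated Q2; Fisher LDA in the PCA subspace;
  Mahalanobis assignment with a 5σ outlier radius; leave-20%-out bootstrap
  estimation of the correct classification rate (CCR), split at sample
  level, counted at spectrum level, reported with and without outliers
  (`fitPCA()`, `pcaQ2()`, `fitLDA()`, `classifySpectra()`,
  `bootstrapCCR()`).
* **Binary OPLS-DA** — orthogonal-component filtering (textbook PLS1 at
  `nOrth = 0`), R2Y and stratified k-fold Q2, Y-permutation validation,
  S-plot statistics `p1 = cov(t, x)` and `pcorr = cor(t, x)`, marker
  selection at |pcorr| ≥ 0.5 and |p1| ≥ 0.05, and regression coefficients
  mapped back to bin space (`fitOPLS()`, `oplsQ2()`, `permutationTest()`,
  `sPlot()`, `selectMarkers()`, `oplsCoefficients()`).
* **Lipid annotation** — elemental-formula parsing (Hill order),
  monoisotopic masses from fixed constants, [M+H]+ adducts with the
  electron-corrected proton mass 1.00727646 Da, ppm peak matching and
  Da-scale MS/MS fragment matching against a bundled, checksummed 28-row
  lipid marker table (23 cow markers, 5 from oat/soya/camel), every row
  mass-verified to ±0.001 Da (`parseFormula()`, `protonatedMass()`,
  `matchPeak()`, `matchFragments()`, `loadMarkerTable()`,
  `verifyMarkerTable()`).
* **Adulteration analysis** — the reference cow-into-other mixture designs
  (goat 0–100% in 6 levels, camel and soya in 9, oat in 7), per-level LDA
  on log intensities with an LD1 monotone-trend statistic, and a
  limit-of-detection estimator with a pure-calibrated one-sided decision
  rule (`defaultDesigns()`, `fitLevelLDA()`, `estimateLOD()`).
* **Synthetic studies** — a generator reproducing the reference study
  design (103/27/36/34/73 samples across the five species, 30 cow farms,
  6–9 replicate scans) with declared noise laws, so the entire pipeline is
  testable without instrument data (`simConfig()`, `simulateStudy()`).
* **Orchestration** — a configuration-driven pipeline writing CSV/JSON
  artifacts with a provenance manifest (`pipelineConfig()`,
  `runPipeline()`; a thin Rscript wrapper lives in `inst/scripts/`).

## Worked example

```r
library(desimilk)

## Annotation chemistry: theoretical [M+H]+ of PA(24:0) and a ppm match
protonatedMass("C27H53O8P")
#> [1] 537.3551
sum(verifyMarkerTable(tol = 0.001)$pass)
#> [1] 28
matchPeak(537.3516, tolPpm = 10)
#>   observed_mz lipid_name        lm_id milk_type accurate_mass error_ppm
#> 1    537.3516   PA(24:0) LMGP10010030       cow      537.3551 -6.513384

## A synthetic five-species study with mixture series
cfg <- simConfig(seed = 1,
                 samplesPerSpecies = c(cow = 10, goat = 8, camel = 8,
                                       oat = 8, soya = 8),
                 samplesPerLevel = 5)
study <- simulateStudy(cfg)
m <- ticNormalize(buildFeatureMatrix(study$samples, perSpectrum = TRUE))
m
#> FeatureMatrix: 1512 row(s) x 9500 bins [tic, unscaled]

## Species classification: leave-20%-out bootstrap, 5-sigma outliers
pureIds <- study$truth$sample_id[study$truth$series == "pure"]
bootstrapCCR(m[sampleMeta(m)$sample_id %in% pureIds], repeats = 5, seed = 1)
#> ClassificationResult: 399 held-out spectra; CCR 95.7% excluding / 95.7% including outliers

## OPLS-DA cow vs rest with S-plot marker selection
avg <- scaleMatrix(buildFeatureMatrix(
    study$samples[study$truth$series == "pure"]), "pareto")
y <- encodeY(sampleMeta(avg)$species)   # cow = -1, everything else = +1
fit <- fitOPLS(avg, y, nOrth = 1)
round(fit@r2y, 3)
#> [1] 0.894
round(oplsQ2(featureValues(avg), y, nOrth = 1, seed = 1), 3)
#> [1] 0.786
sel <- selectMarkers(sPlot(fit, avg))
c(selected = sum(sel$selected), cow_side = nrow(sel$negative))
#> selected cow_side
#>       48       43

## Limit of detection for cow milk spiked into soya milk
soyaIds <- study$truth$sample_id[study$truth$series == "mix_soya"]
estimateLOD(m[sampleMeta(m)$sample_id %in% soyaIds], repeats = 5, seed = 1)
#> LODResult for soya: LOD 0.1% (v/v) at detection rate >= 0.8; level CCR 98.1%
```

Reading the numbers: the recomputed protonated mass of C27H53O8P agrees
with the table's accurate mass to four decimals and the measured peak
matches it at −6.5 ppm; the five-species classifier holds a held-out CCR
near 96% with camel, oat and soya at 100% and goat the hardest class; the
cow-vs-rest OPLS-DA explains ~0.89 of the class variance with
cross-validated Q2 ~0.79; S-plot selection recovers all 28 planted marker
bins among 48 selected from 9500; and cow milk is detected in soya milk
down to the 0.1% (v/v) level of the design.

## Documentation

The methods vignette (`vignettes/desimilk-methods.Rmd`) documents the
model and its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, the
numerical conventions, and known limitations.
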