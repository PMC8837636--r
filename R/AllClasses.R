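#' @include desimilk-package.R
NULL

MILK_SPECIES <- c("cow", "goat", "camel", "oat", "soya", "mixture")
MARKER_SPECIES <- c("cow", "oat", "oat+soya", "soya", "camel")

#' Single-scan sparse mass spectrum
#'
#' One centroided DESI-MS scan stored as parallel vectors of m/z positions and
#' non-negative intensities, m/z strictly ascending.
#'
#' @slot mz numeric, strictly ascending m/z values.
#' @slot intensity numeric, matching non-negative intensities (counts).
#' @export
setClass("PeakList", representation(mz = "numeric", intensity = "numeric"))

setValidity("PeakList", function(object) {
    msg <- character()
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have equal length")
    if (anyNA(object@mz) || anyNA(object@intensity))
        msg <- c(msg, "mz and intensity must not contain NA")
    if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
        msg <- c(msg, "mz must be strictly ascending")
    if (length(object@intensity) && any(object@intensity < 0))
        msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
})

#' One milk sample: identity, metadata and its replicate scans
#'
#' @slot sampleId character scalar identifier.
#' @slot species one of cow, goat, camel, oat, soya or mixture.
#' @slot adulterationFraction volume fraction of cow milk in `[0, 1]`
#'   (0 for pure non-cow milk, 1 for pure cow milk).
#' @slot sourceId farm / supplier / production-batch identifier.
#' @slot scans list of [PeakList-class] replicate scans (at least one).
#' @export
setClass("SampleRecord", representation(
    sampleId = "character", species = "character",
    adulterationFraction = "numeric", sourceId = "character",
    scans = "list"))

setValidity("SampleRecord", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be a scalar")
    if (length(object@species) != 1L || !object@species %in% MILK_SPECIES)
        msg <- c(msg, sprintf("species must be one of %s",
                              paste(MILK_SPECIES, collapse = ", ")))
    f <- object@adulterationFraction
    if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
        msg <- c(msg, "adulterationFraction must be a scalar in [0, 1]")
    else {
        mixed <- f > 0 && f < 1
        if (mixed && object@species != "mixture")
            msg <- c(msg, "species must be 'mixture' when 0 < adulterationFraction < 1")
        if (!mixed && identical(object@species, "mixture"))
            msg <- c(msg, "species 'mixture' requires 0 < adulterationFraction < 1")
    }
    if (length(object@scans) < 1L) msg <- c(msg, "at least one scan is required")
    if (!all(vapply(object@scans, is, logical(1), "PeakList")))
        msg <- c(msg, "scans must all be PeakList objects")
    if (length(msg)) msg else TRUE
})

#' Fixed-width mass bin grid
#'
#' Half-open bins `[low + k*width, low + (k+1)*width)` labelled by their
#' centers. With the defaults (100-2000 m/z, 0.2 Da) the centers sit at odd
#' multiples of 0.1 (100.1, 100.3, ..., 1999.9), the unique 0.2 Da convention
#' under which the bundled marker table's representative masses land in their
#' printed bins.
#'
#' @slot low lower m/z bound (inclusive).
#' @slot high upper m/z bound (exclusive).
#' @slot width bin width in Da.
#' @export
setClass("BinGrid", representation(low = "numeric", high = "numeric",
                                   width = "numeric"))

setValidity("BinGrid", function(object) {
    msg <- character()
    if (length(object@low) != 1L || length(object@high) != 1L ||
        length(object@width) != 1L)
        msg <- c(msg, "low, high and width must be scalars")
    else {
        if (object@width <= 0) msg <- c(msg, "width must be positive")
        if (object@high <= object@low) msg <- c(msg, "high must exceed low")
        n <- (object@high - object@low) / object@width
        if (abs(n - round(n)) > 1e-6)
            msg <- c(msg, "(high - low) must be an integer multiple of width")
    }
    if (length(msg)) msg else TRUE
})

#' Samples-by-bins feature matrix with processing state
#'
#' Rows are samples (or single spectra in per-spectrum mode), columns are the
#' bins of a [BinGrid-class]. The normalisation and scaling state is carried
#' with the data; after scaling, the recorded column means/scales reproduce
#' the transform (and its inverse).
#'
#' @slot values numeric matrix, samples x bins.
#' @slot grid the [BinGrid-class] the columns refer to.
#' @slot meta data.frame with one row per matrix row: sample_id, species,
#'   adulteration_fraction, source_id and (per-spectrum mode) scan.
#' @slot normalisation "raw" or "tic".
#' @slot scaling "unscaled", "centered", "pareto" or "unit_variance".
#' @slot columnMeans,columnScales recorded transform (length 0 when unscaled).
#' @export
setClass("FeatureMatrix", representation(
    values = "matrix", grid = "BinGrid", meta = "data.frame",
    normalisation = "character", scaling = "character",
    columnMeans = "numeric", columnScales = "numeric"))

setValidity("FeatureMatrix", function(object) {
    msg <- character()
    if (nrow(object@values) != nrow(object@meta))
        msg <- c(msg, "meta must have one row per matrix row")
    nb <- nBins(object@grid)
    if (ncol(object@values) != nb)
        msg <- c(msg, sprintf("matrix has %d columns but grid defines %d bins",
                              ncol(object@values), nb))
    if (!object@normalisation %in% c("raw", "tic"))
        msg <- c(msg, "normalisation must be 'raw' or 'tic'")
    if (!object@scaling %in% c("unscaled", "centered", "pareto", "unit_variance"))
        msg <- c(msg, "unknown scaling state")
    if (length(msg)) msg else TRUE
})

#' Principal component model
#'
#' @slot loadings bins x k orthonormal loading matrix.
#' @slot scores samples x k score matrix (centered data times loadings).
#' @slot explained per-component fraction of total variance (R2X).
#' @slot q2 per-component cumulative Q2 (empty until [pcaQ2()] is run).
#' @slot columnMeans centering vector.
#' @export
setClass("PCAModel", representation(
    loadings = "matrix", scores = "matrix", explained = "numeric",
    q2 = "numeric", columnMeans = "numeric"))

#' PCA-subspace Fisher discriminant model
#'
#' @slot pca the [PCAModel-class] defining the input subspace.
#' @slot directions PCA-score-space discriminant axes (nPcs x nAxes).
#' @slot classMeans class centroids in discriminant space (classes x nAxes).
#' @slot pooledCov pooled within-class covariance in discriminant space.
#' @slot classes class labels, in centroid row order.
#' @slot outlierSigma Mahalanobis radius (in sd units) beyond which a
#'   spectrum is flagged as an outlier; the instrument-software default is 5.
#' @export
setClass("LDAModel", representation(
    pca = "PCAModel", directions = "matrix", classMeans = "matrix",
    pooledCov = "matrix", classes = "character", outlierSigma = "numeric"))

#' Held-out classification summary
#'
#' @slot assignments data.frame with one row per classified spectrum:
#'   sample_id, scan, truth, predicted, distance (Mahalanobis, sd units),
#'   outlier flag and bootstrap repeat.
#' @slot ccrExcludingOutliers correct/total over non-outlier held-out spectra.
#' @slot ccrIncludingOutliers correct/total over all held-out spectra.
#' @export
setClass("ClassificationResult", representation(
    assignments = "data.frame", ccrExcludingOutliers = "numeric",
    ccrIncludingOutliers = "numeric"))

#' Fitted binary OPLS-DA model
#'
#' A single predictive component plus `nOrth` removed orthogonal components,
#' fitted on a centered (typically Pareto-scaled) matrix against a +/-1 class
#' encoding.
#'
#' @slot yEncoding named numeric mapping class label to -1 / +1.
#' @slot w unit-norm predictive weight vector.
#' @slot t predictive scores on the training data.
#' @slot p predictive loading vector.
#' @slot c scalar y-loading.
#' @slot wOrth,pOrth bins x nOrth orthogonal weights / loadings.
#' @slot tOrth samples x nOrth orthogonal scores.
#' @slot nOrth number of removed orthogonal components.
#' @slot r2y fraction of (centered) y variance explained on training data.
#' @slot q2y cross-validated predictive fraction (NA until [oplsQ2()]).
#' @slot yMean centering constant of y.
#' @export
setClass("OPLSModel", representation(
    yEncoding = "numeric", w = "numeric", t = "numeric", p = "numeric",
    c = "numeric", wOrth = "matrix", pOrth = "matrix", tOrth = "matrix",
    nOrth = "integer", r2y = "numeric", q2y = "numeric", yMean = "numeric"))

#' Per-bin S-plot statistics
#'
#' For every bin, the covariance p1 of the bin with the predictive score
#' (magnitude = influence on the model) and the Pearson correlation pcorr
#' (reliability), plus the selection flag under the thresholds used.
#'
#' @slot binCenters bin labels.
#' @slot p1 per-bin covariance with the predictive score t.
#' @slot pcorr per-bin correlation with t, in `[-1, 1]`.
#' @slot selected logical selection flag per bin.
#' @slot thresholds named numeric: pcorr_min, p1_min.
#' @export
setClass("SPlotResult", representation(
    binCenters = "numeric", p1 = "numeric", pcorr = "numeric",
    selected = "logical", thresholds = "numeric"))

#' Y-permutation validation report
#'
#' @slot nPerm number of label permutations.
#' @slot permCor absolute correlation of each permuted y with the original.
#' @slot permR2Y,permQ2 per-permutation model statistics.
#' @slot origR2Y,origQ2 statistics of the unpermuted model.
#' @slot valid TRUE iff every permuted Q2 is below the original Q2.
#' @export
setClass("PermutationReport", representation(
    nPerm = "integer", permCor = "numeric", permR2Y = "numeric",
    permQ2 = "numeric", origR2Y = "numeric", origQ2 = "numeric",
    valid = "logical"))

#' Cow-into-base-milk mixture design
#'
#' @slot baseSpecies the milk the cow milk is mixed into.
#' @slot levels ascending unique cow-milk volume fractions, starting at 0.
#' @slot samplesPerLevel samples simulated/collected per level.
#' @slot replicatesPerSample integer range (min, max) of replicate scans.
#' @export
setClass("MixtureDesign", representation(
    baseSpecies = "character", levels = "numeric",
    samplesPerLevel = "integer", replicatesPerSample = "integer"))

setValidity("MixtureDesign", function(object) {
    msg <- character()
    lv <- object@levels
    if (!length(lv) || lv[1] != 0) msg <- c(msg, "levels must start at 0")
    if (any(lv < 0 | lv > 1)) msg <- c(msg, "levels must lie in [0, 1]")
    if (is.unsorted(lv, strictly = TRUE)) msg <- c(msg, "levels must be strictly ascending")
    if (length(msg)) msg else TRUE
})

#' Limit-of-detection result for one base milk
#'
#' @slot baseSpecies base milk species.
#' @slot lod smallest cow-milk fraction with held-out detection rate at or
#'   above the criterion, or NA when no level reaches it ("not detected").
#' @slot perLevel data.frame: level, n_spectra, detection_rate.
#' @slot ccr cross-validated correct level-classification rate.
#' @slot criterionRate the detection-rate criterion used.
#' @export
setClass("LODResult", representation(
    baseSpecies = "character", lod = "numeric", perLevel = "data.frame",
    ccr = "numeric", criterionRate = "numeric"))

#' Synthetic five-species study configuration
#'
#' Defaults (read from the package's `sim_defaults.yaml`) reproduce the
#' reference study design: 103 cow / 27 goat / 36 camel / 34 oat / 73 soya
#' samples, 6-9 replicate scans each, 30 cow farms, plus the four
#' cow-into-other mixture series.
#'
#' @slot samplesPerSpecies named integer, pure samples per species.
#' @slot sourcesPerSpecies named integer, farms/suppliers per species.
#' @slot replicateRange integer (min, max) replicate scans per sample.
#' @slot intensitySigma lognormal sigma of per-scan peak intensity noise.
#' @slot mzJitterPpm Gaussian m/z jitter sd, ppm.
#' @slot backgroundPeaks Poisson mean count of background peaks per scan.
#' @slot backgroundMeanIntensity mean intensity of a background peak (counts).
#' @slot ticSigma lognormal sigma of the per-scan TIC factor.
#' @slot effectSize multiplier on marker peak intensities.
#' @slot goatSimilarity fraction of the cow marker intensity retained in the
#'   goat profile (1 = identical to cow), making goat the hardest class.
#' @slot sourceSigma lognormal sigma of the per-farm marker-intensity offset.
#' @slot markerScale base intensity scale of marker peaks (counts).
#' @slot sharedScale base intensity scale of the shared lipid backbone.
#' @slot glCrossLevel fraction of a glycerolipid marker's intensity present
#'   in the non-attributed members of the GL-rich group (camel/oat/soya).
#' @slot samplesPerLevel samples per adulteration level in mixture series.
#' @slot seed integer seed; mandatory for reproducibility.
#' @export
setClass("SimulationConfig", representation(
    samplesPerSpecies = "integer", sourcesPerSpecies = "integer",
    replicateRange = "integer", intensitySigma = "numeric",
    mzJitterPpm = "numeric", backgroundPeaks = "numeric",
    backgroundMeanIntensity = "numeric", ticSigma = "numeric",
    effectSize = "numeric", goatSimilarity = "numeric",
    sourceSigma = "numeric", markerScale = "numeric",
    sharedScale = "numeric", glCrossLevel = "numeric",
    samplesPerLevel = "integer", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (any(object@samplesPerSpecies < 1L))
        msg <- c(msg, "samplesPerSpecies must all be >= 1")
    if (length(object@replicateRange) != 2L ||
        object@replicateRange[1] > object@replicateRange[2] ||
        object@replicateRange[1] < 1L)
        msg <- c(msg, "replicateRange must be an increasing pair of counts >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a seed is mandatory")
    if (object@goatSimilarity < 0 || object@goatSimilarity > 1)
        msg <- c(msg, "goatSimilarity must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
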