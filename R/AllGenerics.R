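#' @include AllClasses.R
NULL

#' Accessors for desimilk objects
#'
#' Small accessor family used throughout the package: `mzValues()` /
#' `intensityValues()` read a scan, `scanCount()` the number of replicate
#' scans of a sample, `binCenters()` / `nBins()` interrogate a grid,
#' `featureValues()` returns the numeric matrix of a [FeatureMatrix-class],
#' `sampleMeta()` its per-row metadata, and `scores()` / `loadings()` /
#' `explainedVariance()` read a fitted [PCAModel-class].
#'
#' @param object the object to query.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mzValues", function(object) standardGeneric("mzValues"))
#' @rdname accessors
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))
#' @rdname accessors
#' @export
setGeneric("scanCount", function(object) standardGeneric("scanCount"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setMethod("mzValues", "PeakList", function(object) object@mz)
#' @rdname accessors
#' @export
setMethod("intensityValues", "PeakList", function(object) object@intensity)
#' @rdname accessors
#' @export
setMethod("scanCount", "SampleRecord", function(object) length(object@scans))
#' @rdname accessors
#' @export
setMethod("nBins", "BinGrid", function(object)
    as.integer(round((object@high - object@low) / object@width)))
#' @rdname accessors
#' @export
setMethod("binCenters", "BinGrid", function(object)
    object@low + (seq_len(nBins(object)) - 0.5) * object@width)
#' @rdname accessors
#' @export
setMethod("binCenters", "FeatureMatrix", function(object) binCenters(object@grid))
#' @rdname accessors
#' @export
setMethod("binCenters", "SPlotResult", function(object) object@binCenters)
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("sampleMeta", "FeatureMatrix", function(object) object@meta)
#' @rdname accessors
#' @export
setMethod("scores", "PCAModel", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("loadings", "PCAModel", function(object) object@loadings)
#' @rdname accessors
#' @export
setMethod("explainedVariance", "PCAModel", function(object) object@explained)

setMethod("show", "PeakList", function(object) {
    cat(sprintf("PeakList with %d peaks", length(object@mz)))
    if (length(object@mz))
        cat(sprintf(" (m/z %.4f-%.4f, TIC %.3g)",
                    min(object@mz), max(object@mz), sum(object@intensity)))
    cat("\n")
})

setMethod("show", "SampleRecord", function(object) {
    cat(sprintf("SampleRecord '%s': %s (cow fraction %.3g), source %s, %d scan(s)\n",
                object@sampleId, object@species, object@adulterationFraction,
                object@sourceId, length(object@scans)))
})

setMethod("show", "BinGrid", function(object) {
    cat(sprintf("BinGrid: %d bins of %.3g Da over m/z [%g, %g)\n",
                nBins(object), object@width, object@low, object@high))
})

setMethod("show", "FeatureMatrix", function(object) {
    cat(sprintf("FeatureMatrix: %d row(s) x %d bins [%s, %s]\n",
                nrow(object@values), ncol(object@values),
                object@normalisation, object@scaling))
})

setMethod("show", "PCAModel", function(object) {
    k <- ncol(object@loadings)
    cat(sprintf("PCAModel with %d component(s); cumulative R2X %.3f", k,
                sum(object@explained)))
    if (length(object@q2)) cat(sprintf("; Q2[%d] %.3f", k, object@q2[k]))
    cat("\n")
})

setMethod("show", "LDAModel", function(object) {
    cat(sprintf("LDAModel: %d class(es) [%s], %d PCA dims, %d discriminant axis(es), outlier radius %g sd\n",
                length(object@classes), paste(object@classes, collapse = ", "),
                nrow(object@directions), ncol(object@directions),
                object@outlierSigma))
})

setMethod("show", "ClassificationResult", function(object) {
    cat(sprintf("ClassificationResult: %d held-out spectra; CCR %.1f%% excluding / %.1f%% including outliers\n",
                nrow(object@assignments), 100 * object@ccrExcludingOutliers,
                100 * object@ccrIncludingOutliers))
})

setMethod("show", "OPLSModel", function(object) {
    cat(sprintf("OPLSModel: 1 predictive + %d orthogonal component(s); R2Y %.3f",
                object@nOrth, object@r2y))
    if (!is.na(object@q2y)) cat(sprintf(", Q2 %.3f", object@q2y))
    cat("\n")
})

setMethod("show", "SPlotResult", function(object) {
    cat(sprintf("SPlotResult over %d bins; %d selected at |pcorr| >= %g, |p1| >= %g\n",
                length(object@binCenters), sum(object@selected),
                object@thresholds[["pcorr_min"]], object@thresholds[["p1_min"]]))
})

setMethod("show", "PermutationReport", function(object) {
    cat(sprintf("PermutationReport: %d permutations; original R2Y %.3f, Q2 %.3f; model %s\n",
                object@nPerm, object@origR2Y, object@origQ2,
                if (object@valid) "VALID (all permuted Q2 lower)" else "NOT valid"))
})

setMethod("show", "MixtureDesign", function(object) {
    cat(sprintf("MixtureDesign: cow into %s at levels %s; %d sample(s)/level\n",
                object@baseSpecies,
                paste(format(100 * object@levels, trim = TRUE), collapse = "/"),
                object@samplesPerLevel))
})

setMethod("show", "LODResult", function(object) {
    lod <- if (is.na(object@lod)) "not detected"
           else sprintf("%g%% (v/v)", 100 * object@lod)
    cat(sprintf("LODResult for %s: LOD %s at detection rate >= %g; level CCR %.1f%%\n",
                object@baseSpecies, lod, object@criterionRate, 100 * object@ccr))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:\n")
    cat("  samples/species: ",
        paste(sprintf("%s=%d", names(object@samplesPerSpecies),
                      object@samplesPerSpecies), collapse = ", "), "\n", sep = "")
    cat(sprintf("  replicates %d-%d, intensity sigma %g, m/z jitter %g ppm, seed %d\n",
                object@replicateRange[1], object@replicateRange[2],
                object@intensitySigma, object@mzJitterPpm, object@seed))
})
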