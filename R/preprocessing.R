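#' @include spectra_io.R
NULL

#' Construct a mass bin grid
#'
#' Defaults follow the chemometric processing convention for DESI milk
#' fingerprints: m/z 100-2000 at 0.2 Da, i.e. 9500 half-open bins labelled by
#' centers at odd multiples of 0.1 (537.3 labels `[537.2, 537.4)`).
#'
#' @param low lower m/z bound (inclusive), default 100.
#' @param high upper m/z bound (exclusive), default 2000.
#' @param width bin width in Da, default 0.2.
#' @return a [BinGrid-class].
#' @export
#' @examples
#' nBins(binGrid())  # 9500
binGrid <- function(low = 100, high = 2000, width = 0.2) {
    new("BinGrid", low = low, high = high, width = width)
}

## Bin index of each m/z under the half-open convention; NA when outside
## [low, high). Guards against floating-point edge droop at exact bin
## boundaries (e.g. 537.4 must open bin [537.4, 537.6)).
binIndex <- function(mz, grid) {
    idx <- floor((mz - grid@low) / grid@width + 1e-9) + 1
    idx[mz < grid@low | mz >= grid@high] <- NA_integer_
    as.integer(idx)
}

#' Bin a scan onto a grid
#'
#' Every peak with `low <= mz < high` contributes its full intensity to the
#' unique bin containing it; intensities within a bin sum; peaks outside the
#' grid are discarded. Total intensity inside the grid is conserved exactly.
#'
#' @param scan a [PeakList-class].
#' @param grid a [BinGrid-class].
#' @return numeric vector of per-bin summed intensities, named by bin center.
#' @export
#' @examples
#' v <- binPeaks(peakList(537.3516, 1e4), binGrid())
#' names(which(v > 0))  # "537.3"
binPeaks <- function(scan, grid = binGrid()) {
    out <- numeric(nBins(grid))
    idx <- binIndex(mzValues(scan), grid)
    keep <- !is.na(idx)
    if (any(keep)) {
        sums <- rowsum(intensityValues(scan)[keep], idx[keep])
        out[as.integer(rownames(sums))] <- sums[, 1]
    }
    names(out) <- sprintf("%.1f", binCenters(grid))
    out
}

#' Drop low-TIC scans from a sample
#'
#' Scans whose total ion count falls below `intensityLimit` are removed
#' (order preserved). The limit is the per-scan spectral intensity threshold
#' applied before scan averaging, which rejects failed acquisitions; the
#' conventional value is 1e6 counts.
#'
#' @param sample a [SampleRecord-class].
#' @param intensityLimit minimum TIC for a scan to be kept (>= 0).
#' @return the sample with only surviving scans.
#' @export
filterScans <- function(sample, intensityLimit = 1e6) {
    stopifnot(intensityLimit >= 0)
    keep <- vapply(sample@scans, totalIonCount, 0) >= intensityLimit
    if (!any(keep))
        stop(sprintf("empty sample '%s': all %d scans fall below the intensity limit %g",
                     sample@sampleId, length(keep), intensityLimit))
    initialize(sample, scans = sample@scans[keep])
}

#' Build the analysis-ready feature matrix
#'
#' Filters each sample's scans by the TIC limit, bins every surviving scan,
#' and assembles either one averaged row per sample (the model-building
#' default) or one row per scan (`perSpectrum = TRUE`, used when correct
#' classification rates are counted over individual spectra).
#'
#' @param samples list of [SampleRecord-class].
#' @param grid a [BinGrid-class].
#' @param intensityLimit per-scan TIC limit (see [filterScans()]).
#' @param perSpectrum logical; one row per scan instead of per sample.
#' @return a [FeatureMatrix-class] in state (raw, unscaled).
#' @export
buildFeatureMatrix <- function(samples, grid = binGrid(),
                               intensityLimit = 1e6, perSpectrum = FALSE) {
    if (length(samples) < 2L) stop("at least 2 samples are required")
    errors <- character()
    kept <- list()
    for (s in samples) {
        f <- tryCatch(filterScans(s, intensityLimit), error = function(e)
            conditionMessage(e))
        if (is.character(f)) errors <- c(errors, f) else kept <- c(kept, f)
    }
    if (length(errors))
        stop("empty sample(s) after intensity filtering:\n  ",
             paste(errors, collapse = "\n  "))
    meta1 <- function(s, scan = NA_integer_)
        data.frame(sample_id = s@sampleId, species = s@species,
                   adulteration_fraction = s@adulterationFraction,
                   source_id = s@sourceId, scan = scan,
                   stringsAsFactors = FALSE)
    if (perSpectrum) {
        rows <- list(); meta <- list()
        for (s in kept) for (j in seq_along(s@scans)) {
            rows[[length(rows) + 1L]] <- binPeaks(s@scans[[j]], grid)
            meta[[length(meta) + 1L]] <- meta1(s, j)
        }
        values <- do.call(rbind, rows)
        meta <- do.call(rbind, meta)
        rownames(values) <- paste(meta$sample_id, meta$scan, sep = "#")
    } else {
        values <- t(vapply(kept, averageScans, numeric(nBins(grid)),
                           grid = grid))
        meta <- do.call(rbind, lapply(kept, meta1))
        rownames(values) <- meta$sample_id
    }
    new("FeatureMatrix", values = values, grid = grid, meta = meta,
        normalisation = "raw", scaling = "unscaled",
        columnMeans = numeric(), columnScales = numeric())
}

#' Normalise each row to unit total ion count
#'
#' Divides every row by its sum so each spectrum becomes a composition
#' summing to 1, removing between-scan TIC drift. Zero-sum rows are removed
#' with a warning, never divided.
#'
#' @param m a raw [FeatureMatrix-class].
#' @return the matrix in state (tic, unscaled).
#' @export
ticNormalize <- function(m) {
    if (m@normalisation != "raw" || m@scaling != "unscaled")
        stop("ticNormalize expects a raw, unscaled matrix")
    rs <- rowSums(m@values)
    drop <- rs == 0
    if (any(drop)) {
        warning(sprintf("removed %d zero-TIC row(s): %s", sum(drop),
                        paste(rownames(m@values)[drop], collapse = ", ")))
    }
    vals <- m@values[!drop, , drop = FALSE] / rs[!drop]
    initialize(m, values = vals, meta = m@meta[!drop, , drop = FALSE],
               normalisation = "tic")
}

## Population (divide-by-N) column standard deviations; the sd convention is
## fixed so scaled matrices are bit-reproducible.
popSd <- function(x) {
    mu <- colMeans(x)
    sqrt(pmax(colMeans(x^2) - mu^2, 0))
}

#' Column scaling for multivariate modelling
#'
#' `center` subtracts column means; `pareto` additionally divides by the
#' square root of the (population) column standard deviation, the customary
#' compromise for mass-spectral intensities; `unit_variance` divides by the
#' sd itself. Columns with zero sd are centered only. The recorded means and
#' scales make the transform invertible (see [unscaleMatrix()]).
#'
#' @param m an unscaled [FeatureMatrix-class] with >= 2 rows.
#' @param mode "center", "pareto" or "unit_variance".
#' @return the scaled matrix with `columnMeans`/`columnScales` recorded.
#' @export
scaleMatrix <- function(m, mode = c("pareto", "center", "unit_variance")) {
    mode <- match.arg(mode)
    if (m@scaling != "unscaled") stop("matrix is already scaled")
    if (nrow(m@values) < 2L) stop("scaling requires at least 2 rows")
    mu <- colMeans(m@values)
    s <- popSd(m@values)
    scales <- switch(mode, center = rep(1, length(s)),
                     pareto = sqrt(s), unit_variance = s)
    scales[scales == 0] <- 1
    vals <- sweep(sweep(m@values, 2, mu), 2, scales, "/")
    initialize(m, values = vals,
               scaling = if (mode == "center") "centered" else mode,
               columnMeans = mu, columnScales = scales)
}

#' Invert a recorded scaling transform
#'
#' @param m a scaled [FeatureMatrix-class].
#' @return the matrix restored to its unscaled values.
#' @export
unscaleMatrix <- function(m) {
    if (m@scaling == "unscaled") stop("matrix is not scaled")
    vals <- sweep(sweep(m@values, 2, m@columnScales, "*"), 2, m@columnMeans, "+")
    initialize(m, values = vals, scaling = "unscaled",
               columnMeans = numeric(), columnScales = numeric())
}

## Apply a fitted scaling to new rows (same grid, raw/tic-consistent values).
applyScaling <- function(m, newValues) {
    if (m@scaling == "unscaled") return(newValues)
    sweep(sweep(newValues, 2, m@columnMeans), 2, m@columnScales, "/")
}

#' Row subsetting of feature matrices
#'
#' `m[i]` (or `m[i, ]`) keeps the selected rows with their metadata;
#' columns are tied to the bin grid and cannot be subset.
#'
#' @param x a [FeatureMatrix-class].
#' @param i row index (logical, integer or rowname character).
#' @param j unused; column subsetting is not supported.
#' @param ... ignored.
#' @param drop ignored (always FALSE).
#' @return the subset [FeatureMatrix-class].
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
    if (!missing(j))
        stop("columns are tied to the bin grid and cannot be subset")
    if (is.character(i)) i <- match(i, rownames(x@values))
    initialize(x, values = x@values[i, , drop = FALSE],
               meta = x@meta[i, , drop = FALSE])
})

#' Write / read a feature matrix as delimited text
#'
#' The matrix is stored as a TSV (first column sample_id, remaining columns
#' bin centers to 1 dp) next to a JSON state file recording the grid and the
#' normalisation/scaling state, so a reread reproduces the object.
#'
#' @param m a [FeatureMatrix-class].
#' @param path output TSV path; the state file is `<path>.state.json`.
#' @return `writeFeatureMatrix`: invisibly, `path`;
#'   `readFeatureMatrix`: the restored [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(m, path) {
    df <- data.frame(sample_id = rownames(m@values), m@values,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    state <- list(low = m@grid@low, high = m@grid@high, width = m@grid@width,
                  normalisation = m@normalisation, scaling = m@scaling,
                  columnMeans = m@columnMeans, columnScales = m@columnScales,
                  meta = m@meta)
    jsonlite::write_json(state, paste0(path, ".state.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
    state <- jsonlite::read_json(paste0(path, ".state.json"),
                                 simplifyVector = TRUE)
    df <- read.delim(path, check.names = FALSE)
    vals <- as.matrix(df[, -1, drop = FALSE])
    rownames(vals) <- df$sample_id
    new("FeatureMatrix", values = vals,
        grid = binGrid(state$low, state$high, state$width),
        meta = as.data.frame(state$meta),
        normalisation = state$normalisation, scaling = state$scaling,
        columnMeans = as.numeric(state$columnMeans),
        columnScales = as.numeric(state$columnScales))
}
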