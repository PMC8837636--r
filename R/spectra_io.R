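#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PeakList
#'
#' @param mz ascending m/z values.
#' @param intensity matching non-negative intensities. Peaks are sorted by
#'   m/z; duplicate m/z values are rejected by the class validity check.
#' @return a [PeakList-class].
#' @export
#' @examples
#' peakList(c(537.35, 703.53), c(1e4, 2e4))
peakList <- function(mz = numeric(), intensity = numeric()) {
    ord <- order(mz)
    new("PeakList", mz = as.numeric(mz[ord]),
        intensity = as.numeric(intensity[ord]))
}

#' Construct a SampleRecord
#'
#' @param sampleId sample identifier.
#' @param species cow, goat, camel, oat, soya or mixture.
#' @param adulterationFraction cow-milk volume fraction in `[0, 1]`.
#' @param sourceId farm/supplier/batch identifier.
#' @param scans list of [PeakList-class] scans.
#' @return a [SampleRecord-class].
#' @export
sampleRecord <- function(sampleId, species, adulterationFraction = if
                         (identical(species, "cow")) 1 else 0,
                         sourceId = "unknown", scans) {
    new("SampleRecord", sampleId = as.character(sampleId),
        species = species, adulterationFraction = adulterationFraction,
        sourceId = as.character(sourceId), scans = scans)
}

#' Total ion count of a scan
#'
#' @param scan a [PeakList-class].
#' @return sum of all peak intensities.
#' @export
totalIonCount <- function(scan) sum(intensityValues(scan))

#' Read peak lists and sample metadata
#'
#' Reads the package's delimited dialect: a peaks file with columns
#' (sample_id, scan, mz, intensity) and a companion manifest with columns
#' (sample_id, species, adulteration_fraction, source_id). Records are
#' returned in deterministic (sample_id, scan index) order. With
#' `dialect = "mzml"` a single centroided mzML file is read through a
#' minimal MS1 reader and all scans are attached to the manifest's single
#' sample.
#'
#' @param peaksFile path to the peaks file (CSV) or the mzML file.
#' @param manifestFile path to the manifest CSV.
#' @param dialect "csv" or "mzml".
#' @return list of [SampleRecord-class] objects.
#' @export
readPeakLists <- function(peaksFile, manifestFile, dialect = c("csv", "mzml")) {
    dialect <- match.arg(dialect)
    manifest <- read.csv(manifestFile, stringsAsFactors = FALSE)
    need <- c("sample_id", "species", "adulteration_fraction", "source_id")
    miss <- setdiff(need, names(manifest))
    if (length(miss))
        stop("manifest is missing field(s): ", paste(miss, collapse = ", "))
    scansBySample <-
        if (dialect == "csv") readPeaksCsv(peaksFile)
        else {
            if (nrow(manifest) != 1L)
                stop("mzML input carries no sample ids; the manifest must describe exactly one sample")
            setNames(list(readMzmlScans(peaksFile)), manifest$sample_id[1])
        }
    manifest <- manifest[order(manifest$sample_id), , drop = FALSE]
    records <- lapply(seq_len(nrow(manifest)), function(i) {
        sid <- as.character(manifest$sample_id[i])
        scans <- scansBySample[[sid]]
        if (is.null(scans))
            stop(sprintf("sample '%s' appears in the manifest but has no scans", sid))
        sampleRecord(sid, manifest$species[i],
                     manifest$adulteration_fraction[i],
                     manifest$source_id[i], scans)
    })
    extra <- setdiff(names(scansBySample), as.character(manifest$sample_id))
    if (length(extra))
        stop("peaks file contains sample(s) absent from the manifest: ",
             paste(extra, collapse = ", "))
    records
}

readPeaksCsv <- function(path) {
    peaks <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "scan", "mz", "intensity")
    miss <- setdiff(need, names(peaks))
    if (length(miss))
        stop("peaks file is missing column(s): ", paste(miss, collapse = ", "))
    if (!is.numeric(peaks$mz) || !is.numeric(peaks$intensity))
        stop("non-numeric mz/intensity values in peaks file")
    bySample <- split(peaks, as.character(peaks$sample_id))
    lapply(bySample, function(df) {
        scans <- split(df, df$scan)
        scans <- scans[order(as.integer(names(scans)))]
        lapply(seq_along(scans), function(j) {
            s <- scans[[j]]
            if (is.unsorted(s$mz, strictly = TRUE))
                stop(sprintf("scan %s of sample '%s': m/z not strictly ascending",
                             names(scans)[j], s$sample_id[1]))
            peakList(s$mz, s$intensity)
        })
    })
}

## Minimal centroided-MS1 mzML reader: pulls base64-encoded 64-bit little-
## endian m/z and intensity arrays from each <spectrum> (no compression).
readMzmlScans <- function(path) {
    doc <- readChar(path, file.info(path)$size, useBytes = TRUE)
    if (!grepl("<mzML", doc, fixed = TRUE)) stop("not an mzML document")
    spectra <- regmatches(doc, gregexpr("<spectrum .*?</spectrum>", doc))[[1]]
    if (!length(spectra)) stop("mzML document contains no spectra")
    lapply(spectra, function(sp) {
        if (grepl("MS:1000128", sp, fixed = TRUE))
            stop("profile-mode spectra are not supported; centroid the data first")
        arrays <- regmatches(sp,
            gregexpr("<binaryDataArray.*?</binaryDataArray>", sp))[[1]]
        vals <- lapply(arrays, function(a) {
            if (grepl("MS:1000574", a, fixed = TRUE))
                stop("compressed binary arrays are not supported")
            b64 <- sub(".*<binary>(.*)</binary>.*", "\\1", a)
            raw <- jsonlite::base64_dec(b64)
            readBin(raw, "double", n = length(raw) / 8, size = 8,
                    endian = "little")
        })
        isMz <- vapply(arrays, grepl, logical(1), pattern = "MS:1000514",
                       fixed = TRUE)
        if (sum(isMz) != 1L || length(arrays) < 2L)
            stop("spectrum lacks an m/z / intensity array pair")
        peakList(vals[[which(isMz)]], vals[[which(!isMz)[1]]])
    })
}

#' Write peak lists (and manifest) in the CSV dialect
#'
#' Lossless for the CSV dialect: m/z written to 4 decimal places, intensity
#' as counts. Zero-intensity peaks are preserved; no filtering happens at the
#' I/O layer.
#'
#' @param records list of [SampleRecord-class].
#' @param peaksFile output path for the peaks CSV.
#' @param manifestFile output path for the manifest CSV.
#' @return invisibly, the two paths.
#' @export
writePeakLists <- function(records, peaksFile, manifestFile) {
    rows <- lapply(records, function(r) {
        do.call(rbind, lapply(seq_along(r@scans), function(j) {
            s <- r@scans[[j]]
            if (!length(s@mz)) return(NULL)
            ## the dialect stores m/z at 4 dp; peaks that collide at that
            ## precision are merged so a reread yields a valid scan
            mz4 <- round(s@mz, 4)
            int <- s@intensity
            if (anyDuplicated(mz4)) {
                int <- as.vector(rowsum(int, mz4))
                mz4 <- sort(unique(mz4))
            }
            data.frame(sample_id = r@sampleId, scan = j,
                       mz = sprintf("%.4f", mz4),
                       intensity = int, stringsAsFactors = FALSE)
        }))
    })
    peaks <- do.call(rbind, rows)
    if (is.null(peaks))
        peaks <- data.frame(sample_id = character(), scan = integer(),
                            mz = character(), intensity = numeric())
    write.csv(peaks, peaksFile, row.names = FALSE, quote = FALSE)
    manifest <- data.frame(
        sample_id = vapply(records, slot, "", "sampleId"),
        species = vapply(records, slot, "", "species"),
        adulteration_fraction = vapply(records, slot, 0, "adulterationFraction"),
        source_id = vapply(records, slot, "", "sourceId"),
        stringsAsFactors = FALSE)
    write.csv(manifest, manifestFile, row.names = FALSE, quote = FALSE)
    invisible(c(peaks = peaksFile, manifest = manifestFile))
}

#' Average a sample's scans on a bin grid
#'
#' Each scan is binned first, then the binned vectors are averaged
#' arithmetically (bin-then-average), which is insensitive to peak-centroid
#' jitter between replicate scans.
#'
#' @param sample a [SampleRecord-class] (scans already filtered upstream).
#' @param grid a [BinGrid-class].
#' @return numeric vector of length `nBins(grid)`.
#' @export
averageScans <- function(sample, grid = binGrid()) {
    if (!length(sample@scans))
        stop(sprintf("empty sample '%s': no scans to average", sample@sampleId))
    binned <- vapply(sample@scans, binPeaks, numeric(nBins(grid)), grid = grid)
    rowMeans(binned)
}
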