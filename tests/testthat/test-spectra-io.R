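test_that("PeakList and SampleRecord validity rules hold", {
    expect_error(new("PeakList", mz = c(2, 1), intensity = c(1, 1)),
                 "ascending")
    expect_error(new("PeakList", mz = 1, intensity = -1), "non-negative")
    expect_error(new("PeakList", mz = c(1, 2), intensity = 1), "equal length")
    pl <- peakList(c(300, 100), c(2, 1))  # constructor sorts
    expect_equal(mzValues(pl), c(100, 300))
    expect_equal(intensityValues(pl), c(1, 2))
    expect_error(sampleRecord("s1", "goat", 0.5, "f1", list(pl)), "mixture")
    expect_error(sampleRecord("s1", "mixture", 0, "f1", list(pl)), "mixture")
    ok <- sampleRecord("s1", "mixture", 0.2, "f1", list(pl))
    expect_equal(scanCount(ok), 1)
})

test_that("the CSV dialect round-trips records exactly", {
    scans1 <- list(peakList(c(150.1234, 537.3516), c(1000, 0)),
                   peakList(c(150.1234, 880.5), c(1500, 30)))
    scans2 <- list(peakList(200.5, 12))
    recs <- list(sampleRecord("a1", "cow", 1, "farm1", scans1),
                 sampleRecord("b2", "oat", 0, "sup2", scans2))
    pf <- tempfile(fileext = ".csv"); mf <- tempfile(fileext = ".csv")
    writePeakLists(recs, pf, mf)
    back <- readPeakLists(pf, mf)
    expect_equal(length(back), 2)
    expect_equal(back[[1]]@sampleId, "a1")
    expect_equal(back[[1]]@species, "cow")
    expect_equal(back[[1]]@sourceId, "farm1")
    expect_equal(scanCount(back[[1]]), 2)
    ## zero-intensity peak preserved, m/z at 4 dp
    expect_equal(intensityValues(back[[1]]@scans[[1]]), c(1000, 0))
    expect_equal(mzValues(back[[1]]@scans[[1]]), c(150.1234, 537.3516))
    expect_equal(back[[2]]@adulterationFraction, 0)
})

test_that("writing an empty record list yields a header-only peaks file", {
    pf <- tempfile(); mf <- tempfile()
    writePeakLists(list(), pf, mf)
    expect_equal(length(readLines(pf)), 1)
})

test_that("malformed inputs fail with context", {
    pf <- tempfile(); mf <- tempfile()
    writeLines(c("sample_id,scan,mz,intensity", "s1,1,200,5", "s1,1,150,5"),
               pf)
    writeLines(c("sample_id,species,adulteration_fraction,source_id",
                 "s1,cow,1,f"), mf)
    expect_error(readPeakLists(pf, mf), "ascending")
    writeLines(c("sample_id,species", "s1,cow"), mf)
    expect_error(readPeakLists(pf, mf), "missing field")
    writeLines(c("sample_id,species,adulteration_fraction,source_id",
                 "s2,cow,1,f"), mf)
    writeLines(c("sample_id,scan,mz,intensity", "s1,1,200,5"), pf)
    expect_error(readPeakLists(pf, mf))
})

test_that("scan averaging is bin-then-average and permutation invariant", {
    grid <- binGrid()
    s1 <- peakList(c(200.05, 500.11), c(10, 40))
    s2 <- peakList(c(200.09, 500.15), c(30, 120))  # same bins, 3x intensity
    rec <- sampleRecord("x", "cow", 1, "f", list(s1, s2))
    avg <- averageScans(rec, grid)
    expect_equal(unname(avg[avg > 0]), c(20, 80))
    rec2 <- sampleRecord("x", "cow", 1, "f", list(s2, s1))
    expect_equal(averageScans(rec2, grid), avg)
    one <- sampleRecord("y", "cow", 1, "f", list(s1))
    expect_equal(averageScans(one, grid), binPeaks(s1, grid))
})

## Minimal centroided mzML document with uncompressed 64-bit arrays.
writeTinyMzml <- function(path, scans) {
    enc <- function(x) jsonlite::base64_enc(writeBin(as.numeric(x), raw(),
                                                     size = 8,
                                                     endian = "little"))
    spec <- vapply(seq_along(scans), function(i) {
        s <- scans[[i]]
        paste0('<spectrum index="', i - 1, '" defaultArrayLength="',
               length(s$mz), '">',
               '<cvParam accession="MS:1000127" name="centroid spectrum"/>',
               '<binaryDataArrayList count="2">',
               '<binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/>',
               '<binary>', enc(s$mz), '</binary></binaryDataArray>',
               '<binaryDataArray><cvParam accession="MS:1000515" name="intensity array"/>',
               '<binary>', enc(s$intensity), '</binary></binaryDataArray>',
               '</binaryDataArrayList></spectrum>')
    }, "")
    writeLines(paste0('<?xml version="1.0"?><mzML><run><spectrumList>',
                      paste(spec, collapse = ""),
                      '</spectrumList></run></mzML>'), path)
}

test_that("centroided mzML scans are read and attached to the manifest", {
    mz <- tempfile(fileext = ".mzML"); mf <- tempfile()
    writeTinyMzml(mz, list(list(mz = c(150.5, 537.3516), intensity = c(5, 9)),
                           list(mz = 880.25, intensity = 3)))
    writeLines(c("sample_id,species,adulteration_fraction,source_id",
                 "m1,camel,0,online1"), mf)
    recs <- readPeakLists(mz, mf, dialect = "mzml")
    expect_equal(length(recs), 1)
    expect_equal(scanCount(recs[[1]]), 2)
    expect_equal(mzValues(recs[[1]]@scans[[1]]), c(150.5, 537.3516))
    expect_equal(intensityValues(recs[[1]]@scans[[2]]), 3)
    ## profile-mode data are refused
    doc <- readLines(mz)
    writeLines(sub("MS:1000127", "MS:1000128", doc), mz)
    expect_error(readPeakLists(mz, mf, dialect = "mzml"), "profile")
})
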