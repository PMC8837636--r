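grid <- binGrid()

test_that("the default grid has 9500 half-open bins centered at odd tenths", {
    expect_equal(nBins(grid), 9500)
    centers <- binCenters(grid)
    expect_equal(centers[1], 100.1)
    expect_equal(centers[9500], 1999.9)
    expect_true(all(abs(round((centers - 0.1) / 0.2) * 0.2 + 0.1 -
                        centers) < 1e-9))
    expect_error(binGrid(100, 2000, -0.2), "positive")
    expect_error(binGrid(2000, 100), "exceed")
    expect_error(binGrid(100, 2000.1, 0.2), "multiple")
})

test_that("peaks land in the bins their labels promise", {
    hit <- function(mz) names(which(binPeaks(peakList(mz, 1), grid) > 0))
    expect_equal(hit(537.3516), "537.3")
    expect_equal(hit(656.5998), "656.5")
    expect_equal(hit(537.4), "537.5")      # boundary opens the next bin
    expect_equal(hit(1202.6506), "1202.7")
    v <- binPeaks(peakList(c(537.31, 537.39), c(10, 5)), grid)
    expect_equal(unname(v[["537.3"]]), 15)
})

test_that("binning conserves in-range intensity exactly and drops the rest", {
    set.seed(3)
    for (i in 1:10) {
        mz <- sort(runif(200, 50, 2100))
        int <- rexp(200, 1 / 1000)
        v <- binPeaks(peakList(mz, int), grid)
        inRange <- mz >= 100 & mz < 2000
        expect_equal(sum(v), sum(int[inRange]))
    }
})

test_that("the TIC limit drops failing scans and errors on empty samples", {
    low <- peakList(c(200.1, 300.1), c(2e5, 3e5))    # TIC 5e5
    high <- peakList(c(200.1, 300.1), c(1e6, 1e6))   # TIC 2e6
    rec <- sampleRecord("s", "cow", 1, "f", list(low, high))
    expect_equal(scanCount(filterScans(rec, 0)), 2)
    kept <- filterScans(rec, 1e6)
    expect_equal(scanCount(kept), 1)
    expect_equal(totalIonCount(kept@scans[[1]]), 2e6)
    expect_error(filterScans(rec, 1e9), "empty sample 's'")
})

test_that("feature matrices carry the declared shape in both row modes", {
    p1 <- peakList(c(200.05, 700.11), c(1e6, 2e6))
    p2 <- peakList(c(200.05, 900.33), c(3e6, 1e6))
    recs <- list(sampleRecord("a", "cow", 1, "f", list(p1, p1)),
                 sampleRecord("b", "oat", 0, "g", list(p2)))
    m <- buildFeatureMatrix(recs, grid, intensityLimit = 0)
    expect_equal(dim(featureValues(m)), c(2L, 9500L))
    expect_equal(unname(featureValues(m)["a", "200.1"]), 1e6)
    ms <- buildFeatureMatrix(recs, grid, intensityLimit = 0,
                             perSpectrum = TRUE)
    expect_equal(nrow(featureValues(ms)), 3)
    expect_equal(sampleMeta(ms)$scan, c(1, 2, 1))
    bad <- c(recs, sampleRecord("c", "soya", 0, "h",
                                list(peakList(300.1, 10))))
    expect_error(buildFeatureMatrix(bad, grid, intensityLimit = 1e6),
                 "empty sample")
})

test_that("TIC normalisation yields compositions and removes zero rows", {
    vals <- rbind(c(2, 2, 0), c(0, 0, 0), c(4, 4, 0))
    g3 <- binGrid(100, 100.6, 0.2)
    m <- new("FeatureMatrix", values = vals, grid = g3,
             meta = data.frame(sample_id = c("a", "b", "c"),
                               species = "cow", adulteration_fraction = 1,
                               source_id = "f", scan = NA_integer_),
             normalisation = "raw", scaling = "unscaled",
             columnMeans = numeric(), columnScales = numeric())
    rownames(m@values) <- m@meta$sample_id
    expect_warning(mt <- ticNormalize(m), "zero-TIC")
    expect_equal(nrow(featureValues(mt)), 2)
    expect_equal(unname(featureValues(mt)[1, ]), c(0.5, 0.5, 0))
    expect_equal(unname(rowSums(featureValues(mt))), c(1, 1),
                 tolerance = 1e-9)
    ## scale invariance: doubling a sample's counts changes nothing
    m2 <- m; m2@values[1, ] <- 2 * m@values[1, ]
    expect_warning(mt2 <- ticNormalize(m2), "zero-TIC")
    expect_equal(featureValues(mt2)[1, ], featureValues(mt)[1, ])
})

test_that("scaling modes follow the population-sd convention and invert", {
    vals <- rbind(c(1, 0, 5), c(3, 4, 5))
    g3 <- binGrid(100, 100.6, 0.2)
    m <- new("FeatureMatrix", values = vals, grid = g3,
             meta = data.frame(sample_id = c("a", "b"), species = "cow",
                               adulteration_fraction = 1, source_id = "f",
                               scan = NA_integer_),
             normalisation = "raw", scaling = "unscaled",
             columnMeans = numeric(), columnScales = numeric())
    cen <- scaleMatrix(m, "center")
    expect_equal(unname(featureValues(cen)[, 1]), c(-1, 1))
    par <- scaleMatrix(m, "pareto")
    expect_equal(unname(featureValues(par)[, 2]), c(-2, 2) / sqrt(2))
    expect_equal(unname(featureValues(par)[, 3]), c(0, 0))  # constant column
    uv <- scaleMatrix(m, "unit_variance")
    expect_equal(unname(featureValues(uv)[, 2]), c(-1, 1))
    back <- unscaleMatrix(par)
    expect_equal(featureValues(back), featureValues(m), tolerance = 1e-9)
    expect_error(scaleMatrix(par, "center"), "already scaled")
})

test_that("feature matrices round-trip through the text serialisation", {
    s <- smallStudy()
    m <- desimilk:::subsetRows(s$perSpectrum, seq_len(5))
    path <- tempfile(fileext = ".tsv")
    writeFeatureMatrix(m, path)
    back <- readFeatureMatrix(path)
    expect_equal(featureValues(back), featureValues(m), tolerance = 1e-12)
    expect_equal(back@normalisation, "tic")
    expect_equal(nBins(back@grid), 9500)
    expect_equal(sampleMeta(back)$species, sampleMeta(m)$species)
})
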