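test_that("the reference mixture designs match the stated level series", {
    d <- defaultDesigns()
    expect_setequal(names(d), c("goat", "camel", "oat", "soya"))
    expect_equal(d$goat@levels, c(0, .05, .10, .20, .50, 1))
    expect_equal(length(d$goat@levels), 6)
    expect_equal(d$camel@levels, c(0, .005, .01, .02, .05, .10, .20, .50, 1))
    expect_equal(d$oat@levels, c(0, .005, .05, .10, .20, .50, 1))
    expect_equal(d$soya@levels[2], 0.001)
    expect_true(all(vapply(d, function(x) x@levels[1] == 0, TRUE)))
    expect_error(new("MixtureDesign", baseSpecies = "goat",
                     levels = c(0.1, 0.5), samplesPerLevel = 2L,
                     replicatesPerSample = c(6L, 9L)), "start at 0")
    expect_error(new("MixtureDesign", baseSpecies = "goat",
                     levels = c(0, 0.5, 0.2), samplesPerLevel = 2L,
                     replicatesPerSample = c(6L, 9L)), "ascending")
})

## A tiny two-level series with a clean planted contrast.
twoLevelMatrix <- function(sep = 6, seed = 5) {
    set.seed(seed)
    nS <- 8; nScan <- 3
    sid <- rep(sprintf("p%02d", 1:(2 * nS)), each = nScan)
    lev <- rep(c(0, 0.5), each = nS * nScan)
    X <- matrix(abs(rnorm(2 * nS * nScan * 8, mean = 4)), ncol = 8)
    X[lev > 0, 1:2] <- X[lev > 0, 1:2] + sep
    g <- binGrid(100, 101.6, 0.2)
    m <- new("FeatureMatrix", values = X, grid = g,
             meta = data.frame(sample_id = sid,
                               species = ifelse(lev == 0, "soya", "mixture"),
                               adulteration_fraction = lev, source_id = "f",
                               scan = rep(1:nScan, 2 * nS)),
             normalisation = "raw", scaling = "unscaled",
             columnMeans = numeric(), columnScales = numeric())
    rownames(m@values) <- paste(sid, rep(1:nScan, 2 * nS), sep = "#")
    m
}

test_that("widely separated levels classify perfectly and trend on LD1", {
    m <- twoLevelMatrix()
    fit <- fitLevelLDA(m, repeats = 3, seed = 1, nPcs = 3)
    expect_equal(fit$ccr@ccrExcludingOutliers, 1)
    expect_equal(nrow(fit$centroids), 2)
    expect_error(fitLevelLDA(desimilk:::subsetRows(
        m, m@meta$adulteration_fraction == 0)), ">= 2")
})

test_that("clean mixtures are detected down to the smallest level; pure noise is not", {
    m <- twoLevelMatrix(sep = 8)
    lod <- estimateLOD(m, repeats = 4, seed = 2)
    expect_equal(lod@lod, 0.5)
    expect_equal(lod@criterionRate, 0.8)
    expect_true(all(c(0, 0.5) %in% lod@perLevel$level))
    noise <- twoLevelMatrix(sep = 0)
    lodN <- estimateLOD(noise, repeats = 4, seed = 2)
    expect_true(is.na(lodN@lod))
    expect_error(estimateLOD(desimilk:::subsetRows(
        m, m@meta$adulteration_fraction > 0), seed = 1), "level 0")
})

test_that("expected mixture intensities are linear in the cow fraction", {
    cfg <- simConfig(seed = 55)
    profiles <- defaultProfiles(cfg)
    mixed <- desimilk:::mixProfiles(profiles$soya, profiles$cow, 0.3)
    for (mz in profiles$cow$mz[profiles$cow$marker][1:5]) {
        cowI <- profiles$cow$intensity[profiles$cow$mz == mz]
        baseI <- if (mz %in% profiles$soya$mz)
            profiles$soya$intensity[profiles$soya$mz == mz] else 0
        expect_equal(mixed$intensity[mixed$mz == mz],
                     0.7 * baseI + 0.3 * cowI, tolerance = 1e-12)
    }
    ## Monte-Carlo: simulated scan means track the mixture expectation
    cfgQ <- simConfig(seed = 56, mzJitterPpm = 0, backgroundPeaks = 0,
                      ticSigma = 0, replicateRange = c(6L, 6L))
    prof <- defaultProfiles(cfgQ)
    half <- desimilk:::mixProfiles(prof$camel, prof$cow, 0.5)
    mzTarget <- prof$cow$mz[prof$cow$marker][1]
    expI <- half$intensity[half$mz == mzTarget] *
        exp(cfgQ@intensitySigma^2 / 2)   # lognormal mean correction
    set.seed(99)
    draws <- replicate(200, {
        rec <- simulateSample(prof$camel, cfgQ, "s", "mixture",
                              alpha = 0.5, cowProfile = prof$cow)
        mean(vapply(rec@scans, function(sc)
            intensityValues(sc)[which.min(abs(mzValues(sc) - mzTarget))], 0))
    })
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - expI), 3 * se + 1e-9)
})

test_that("the detection limit tightens as marker effect size grows", {
    lods <- vapply(c(0.3, 3), function(es) {
        cfg <- simConfig(seed = 77, samplesPerSpecies = c(
            cow = 2, goat = 2, camel = 2, oat = 2, soya = 2),
            samplesPerLevel = 4, effectSize = es)
        st <- simulateStudy(cfg, designs = defaultDesigns(4L)["camel"])
        m <- ticNormalize(buildFeatureMatrix(st$samples, perSpectrum = TRUE))
        sub <- desimilk:::subsetRows(m, grepl("^mix_",
                                              sampleMeta(m)$sample_id))
        lod <- estimateLOD(sub, repeats = 3, seed = 1)
        if (is.na(lod@lod)) 1.5 else lod@lod
    }, 0)
    expect_lte(lods[2], lods[1])
})
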