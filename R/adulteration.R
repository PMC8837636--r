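#' @include pca_lda.R
NULL

#' Reference cow-into-other mixture designs
#'
#' The volume-fraction series used when spiking cow milk into each base
#' milk: goat 0/5/10/20/50/100%, camel 0/0.5/1/2/5/10/20/50/100%, oat
#' 0/0.5/5/10/20/50/100% and soya 0/0.1/1/2/5/10/20/50/100% (v/v).
#'
#' @param samplesPerLevel samples per adulteration level.
#' @param replicatesPerSample integer (min, max) replicate scans per sample.
#' @return named list of [MixtureDesign-class], one per base species.
#' @export
#' @examples
#' defaultDesigns()[["soya"]]@levels[2]  # 0.001
defaultDesigns <- function(samplesPerLevel = 6L,
                           replicatesPerSample = c(6L, 9L)) {
    lv <- list(
        goat = c(0, .05, .10, .20, .50, 1),
        camel = c(0, .005, .01, .02, .05, .10, .20, .50, 1),
        oat = c(0, .005, .05, .10, .20, .50, 1),
        soya = c(0, .001, .01, .02, .05, .10, .20, .50, 1))
    lapply(setNames(names(lv), names(lv)), function(sp)
        new("MixtureDesign", baseSpecies = sp, levels = lv[[sp]],
            samplesPerLevel = as.integer(samplesPerLevel),
            replicatesPerSample = as.integer(replicatesPerSample)))
}

#' Adulteration-level LDA for one base milk
#'
#' Treats the adulteration levels of one cow-into-base mixture series as
#' unordered classes, fits a PCA-subspace LDA, and summarises (i) the LD1
#' centroid per level, (ii) the Spearman correlation between centroid and
#' cow fraction (the monotone-trend statistic behind the "linear tendency"
#' reading of such models), and (iii) the leave-20%-out cross-validated
#' level classification rate.
#'
#' @param m per-spectrum [FeatureMatrix-class] for one base species'
#'   mixture series (levels in `meta$adulteration_fraction`).
#' @param repeats bootstrap repeats for the CCR.
#' @param seed RNG seed.
#' @param logFeatures work on log intensities (default TRUE): mixing levels
#'   are multiplicative, so adjacent trace levels (0.5% vs 1%) are
#'   equidistant on the log scale but crushed together on the linear
#'   scale.
#' @param includeEndpoint keep the 100% (pure cow) endpoint in the model
#'   (default FALSE): it is a different species rather than an
#'   adulteration level of the base milk, and its inclusion rotates LD1
#'   away from the mixing trajectory (the base milk's own marker ions
#'   vanish only there).
#' @param ... passed to [fitLDA()] / [bootstrapCCR()].
#' @return list: model ([LDAModel-class]), centroids (data.frame level,
#'   ld1), trendSpearman, ccr ([ClassificationResult-class]).
#' @export
fitLevelLDA <- function(m, repeats = 10, seed = 1, logFeatures = TRUE,
                        includeEndpoint = FALSE, ...) {
    if (!includeEndpoint && any(m@meta$adulteration_fraction < 1))
        m <- subsetRows(m, m@meta$adulteration_fraction < 1)
    if (logFeatures) {
        unit <- 0.1 * stats::median(m@values[m@values > 0])
        m <- initialize(m, values = log1p(m@values / unit))
    }
    lev <- levelLabel(m@meta$adulteration_fraction)
    counts <- table(lev)
    if (length(counts) < 2L) stop("need >= 2 adulteration levels")
    sid <- m@meta$sample_id
    avg <- rowsum(m@values, sid) / as.vector(table(sid)[sort(unique(sid))])
    sampleLev <- vapply(split(lev, sid), function(x) x[1], "")[rownames(avg)]
    model <- fitLDA(avg, sampleLev, ...)
    Z <- pcaProject(model@pca, m@values) %*% model@directions
    cent <- aggregate(Z[, 1] ~ lev, FUN = mean)
    names(cent) <- c("level", "ld1")
    cent$level <- as.numeric(cent$level)
    cent <- cent[order(cent$level), ]
    ## the trend is assessed over the adulteration range proper (alpha < 1):
    ## the 100% endpoint is pure cow milk, where the base milk's own marker
    ## ions vanish entirely and LD1 leaves the mixing trajectory
    mix <- cent$level < 1
    trend <- cor(cent$level[mix], cent$ld1[mix], method = "spearman")
    ccr <- bootstrapCCR(m, labels = lev, repeats = repeats, seed = seed, ...)
    list(model = model, centroids = cent, trendSpearman = abs(trend),
         ccr = ccr)
}

levelLabel <- function(fraction) sprintf("%.6g", fraction)

#' Estimate the limit of detection for cow-milk adulteration
#'
#' For each nonzero level L of the series, a binary pure-vs-adulterated LDA
#' is trained on the pure (level 0) samples against the samples at level L
#' and above, under repeated stratified sample-level splits. The LD1 axis of
#' that model is the detection direction; the decision cut sits at the pure
#' class's spectrum-level LD1 mean plus `zCut` spectrum-level standard
#' deviations towards the adulterated side (a one-sided criterion -- the
#' centroid midpoint would drift far beyond trace levels because pooling
#' higher levels inflates the adulterated class's spread). Held-out spectra
#' of level L beyond the cut count as detected. The limit of detection is
#' the smallest level whose held-out detection rate reaches
#' `criterionRate`; NA ("not detected") when none does. Held-out level-0
#' spectra beyond the cut give the false-positive rate, which `zCut = 2`
#' holds near 2%.
#'
#' @param m per-spectrum [FeatureMatrix-class] of one mixture series.
#' @param criterionRate detection-rate criterion (default 0.8).
#' @param zCut one-sided decision cut in pure-class sd units (default 2).
#' @param repeats number of stratified split repeats.
#' @param holdoutFraction fraction of samples held out per repeat.
#' @param seed RNG seed.
#' @param nPcs PCA dimensionality forwarded to the level-classification
#'   CCR model (the detection axis itself works in full bin space).
#' @return an [LODResult-class]; `perLevel` includes level 0, whose
#'   "detection rate" is the false-positive rate.
#' @details The discriminant direction is a matched filter in full bin
#'   space on log intensities, `d_i = mu_adulterated_i - mu_pure_i` over
#'   screened bins. Four choices matter: (i) log features -- trace
#'   adulteration shows up as the PRESENCE of cow marker ions in otherwise
#'   near-empty bins, which the lognormal intensity scale expresses and a
#'   linear-intensity statistic buries under background-intensity
#'   variance (the log transform also roughly equalises per-bin
#'   variances, so no per-bin variance weights are needed or wanted);
#'   (ii) bins are screened against the pooled within-LEVEL variance,
#'   because with thousands of near-empty bins an unscreened axis fits the
#'   training split's background pattern; (iii) only bins that INCREASE
#'   with adulteration enter the axis -- added cow milk manifests as
#'   presence markers, while base-milk bins carry farm-specific variation
#'   that an unseen farm would turn into false positives; (iv) the
#'   decision cut never sits below the largest pure training score, a
#'   distribution-free guard against the skew of sparse background hits.
#'   A PCA-compressed full-covariance axis (the species classifier's
#'   construction) is deliberately not used here: it buries the
#'   trace-level cow markers under the high-variance base-milk bins.
#' @export
estimateLOD <- function(m, criterionRate = 0.8, zCut = 2, repeats = 10,
                        holdoutFraction = 0.2, seed = 1, nPcs = NULL) {
    frac <- m@meta$adulteration_fraction
    levels <- sort(unique(frac))
    if (levels[1] != 0) stop("level 0 (pure base milk) must be present")
    nz <- levels[levels > 0]
    if (!length(nz)) stop("no nonzero adulteration levels")
    sid <- m@meta$sample_id
    sampleFrac <- vapply(split(frac, sid), function(x) x[1], 0)
    set.seed(seed)
    det <- matrix(0, nrow = length(levels), ncol = 2,
                  dimnames = list(levelLabel(levels),
                                  c("adulterated", "total")))
    for (r in seq_len(repeats)) {
        ## stratified sample-level holdout within every level
        testSamples <- unlist(lapply(levels, function(lv) {
            ids <- names(sampleFrac)[sampleFrac == lv]
            sample(ids, max(1L, round(holdoutFraction * length(ids))))
        }))
        trainIds <- setdiff(names(sampleFrac), testSamples)
        trainMask <- sid %in% trainIds
        avg <- rowsum(m@values[trainMask, , drop = FALSE], sid[trainMask])
        avg <- avg / as.vector(table(sid[trainMask])[rownames(avg)])
        avgFrac <- sampleFrac[rownames(avg)]
        specFrac <- frac[trainMask]
        ## log-intensity features: the unit is a tenth of the median
        ## positive bin value, putting trace marker ions and background
        ## hits on a comparable, compressed scale
        unit <- 0.1 * stats::median(m@values[m@values > 0])
        logf <- function(M) log1p(M / unit)
        Ltr <- logf(m@values[trainMask, , drop = FALSE])
        ## pooled spectrum-level within-LEVEL variance per bin: the noise
        ## metric for detecting single spectra is scan plus farm variation
        s2 <- numeric(ncol(Ltr)); dfw <- 0
        for (lv in levels) {
            rows <- Ltr[specFrac == lv, , drop = FALSE]
            if (nrow(rows) < 2L) next
            s2 <- s2 + colSums(sweep(rows, 2, colMeans(rows))^2)
            dfw <- dfw + nrow(rows) - 1L
        }
        s2 <- s2 / max(dfw, 1L)
        eps <- 1e-3 * mean(s2[s2 > 0]) + 1e-30
        rowsP <- Ltr[specFrac == 0, , drop = FALSE]
        for (lv in nz) {
            use <- avgFrac == 0 | avgFrac >= lv
            lab <- ifelse(avgFrac[use] == 0, "pure", "adulterated")
            if (length(unique(lab)) < 2L || any(table(lab) < 2L)) next
            muP0 <- colMeans(rowsP)
            muA <- colMeans(Ltr[specFrac >= lv, , drop = FALSE])
            delta <- muA - muP0
            nP <- nrow(rowsP); nA <- sum(specFrac >= lv)
            se <- sqrt((s2 + eps) * (1 / nP + 1 / nA))
            keep <- delta >= 3 * se & delta >= 0.05 * max(delta)
            if (!any(keep)) next
            ## matched filter on the log scale: the log transform already
            ## equalises per-bin variances, and per-bin 1/s^2 weights would
            ## hand unbounded weight to bins with no background hit in the
            ## training pure spectra
            d <- ifelse(keep, delta, 0)
            ld1 <- function(rows) drop(logf(rows) %*% d)
            ## calibrate the one-sided cut on spectrum-level training rows
            zPure <- drop(rowsP %*% d)
            ## the cut never sits below the largest pure training score:
            ## a distribution-free guard (the pure score distribution is
            ## skewed by sparse background hits, so mean + z*sd alone
            ## underestimates its upper tail)
            cut <- max(mean(zPure) + zCut * sd(zPure), max(zPure))
            evalMask <- !trainMask & (frac == lv | frac == 0)
            if (!any(evalMask)) next
            zEval <- ld1(m@values[evalMask, , drop = FALSE])
            detected <- zEval > cut
            fr <- frac[evalMask]
            ## level-0 spectra count toward the false-positive rate once,
            ## against the model of the smallest level
            scored <- if (lv == min(nz)) c(0, lv) else lv
            for (s in scored) {
                pick <- fr == s
                det[levelLabel(s), "adulterated"] <-
                    det[levelLabel(s), "adulterated"] + sum(detected[pick])
                det[levelLabel(s), "total"] <-
                    det[levelLabel(s), "total"] + sum(pick)
            }
        }
    }
    rate <- ifelse(det[, "total"] > 0, det[, "adulterated"] / det[, "total"],
                   NA_real_)
    perLevel <- data.frame(level = levels, n_spectra = det[, "total"],
                           detection_rate = rate, row.names = NULL)
    hit <- nz[which(rate[match(levelLabel(nz), levelLabel(levels))] >=
                    criterionRate)]
    ## level CCR on the log-intensity scale, where mixing levels are
    ## equidistant (see fitLevelLDA)
    mLog <- initialize(m, values = log1p(m@values /
        (0.1 * stats::median(m@values[m@values > 0]))))
    ccr <- bootstrapCCR(mLog, labels = levelLabel(frac), repeats = repeats,
                        holdoutFraction = holdoutFraction, seed = seed,
                        nPcs = nPcs)
    new("LODResult", baseSpecies = if (any(m@meta$species != "mixture" &
                                           frac == 0))
            m@meta$species[frac == 0][1] else "unknown",
        lod = if (length(hit)) min(hit) else NA_real_,
        perLevel = perLevel, ccr = ccr@ccrExcludingOutliers,
        criterionRate = criterionRate)
}
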