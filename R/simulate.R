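#' @include adulteration.R markers.R
NULL

#' Build a synthetic-study configuration
#'
#' Defaults come from the package's `sim_defaults.yaml`; any argument
#' overrides its default. The seed is mandatory: every random draw in
#' [simulateStudy()] flows from it.
#'
#' @param seed integer RNG seed (required).
#' @param samplesPerSpecies named vector (cow, goat, camel, oat, soya).
#' @param sourcesPerSpecies named vector of farm/supplier counts.
#' @param replicateRange integer (min, max) scans per sample.
#' @param intensitySigma,mzJitterPpm,backgroundPeaks,backgroundMeanIntensity,ticSigma,effectSize,goatSimilarity,sourceSigma,markerScale,sharedScale,glCrossLevel
#'   noise-law constants; see [SimulationConfig-class].
#' @param samplesPerLevel samples per adulteration level.
#' @return a validated [SimulationConfig-class].
#' @export
#' @examples
#' simConfig(seed = 1, samplesPerSpecies = c(cow = 8, goat = 6, camel = 6,
#'                                           oat = 6, soya = 6))
simConfig <- function(seed, samplesPerSpecies = NULL,
                      sourcesPerSpecies = NULL, replicateRange = NULL,
                      intensitySigma = NULL, mzJitterPpm = NULL,
                      backgroundPeaks = NULL,
                      backgroundMeanIntensity = NULL, ticSigma = NULL,
                      effectSize = NULL, goatSimilarity = NULL,
                      sourceSigma = NULL, markerScale = NULL,
                      sharedScale = NULL, glCrossLevel = NULL,
                      samplesPerLevel = NULL) {
    if (missing(seed)) stop("a seed is mandatory")
    d <- yaml::read_yaml(system.file("extdata", "sim_defaults.yaml",
                                     package = "desimilk", mustWork = TRUE))
    pick <- function(x, dflt) if (is.null(x)) dflt else x
    sps <- pick(samplesPerSpecies, unlist(d$samples_per_species))
    src <- pick(sourcesPerSpecies, unlist(d$sources_per_species))
    src <- pmin(src[names(sps)], sps)
    new("SimulationConfig",
        samplesPerSpecies = setNames(as.integer(sps), names(sps)),
        sourcesPerSpecies = setNames(as.integer(src), names(sps)),
        replicateRange = as.integer(pick(replicateRange,
                                         unlist(d$replicate_range))),
        intensitySigma = pick(intensitySigma, d$intensity_sigma),
        mzJitterPpm = pick(mzJitterPpm, d$mz_jitter_ppm),
        backgroundPeaks = pick(backgroundPeaks, d$background_peaks),
        backgroundMeanIntensity = pick(backgroundMeanIntensity,
                                       d$background_mean_intensity),
        ticSigma = pick(ticSigma, d$tic_sigma),
        effectSize = pick(effectSize, d$effect_size),
        goatSimilarity = pick(goatSimilarity, d$goat_similarity),
        sourceSigma = pick(sourceSigma, d$source_sigma),
        markerScale = pick(markerScale, d$marker_scale),
        sharedScale = pick(sharedScale, d$shared_scale),
        glCrossLevel = pick(glCrossLevel, d$gl_cross_level),
        samplesPerLevel = as.integer(pick(samplesPerLevel,
                                          d$samples_per_level)),
        seed = as.integer(seed))
}

## Deterministic pseudo-random peak positions/intensities for the profile
## definitions: a fixed internal seed, with the caller's RNG state restored.
withProfileSeed <- function(expr) {
    if (exists(".Random.seed", globalenv())) {
        old <- get(".Random.seed", globalenv())
        on.exit(assign(".Random.seed", old, globalenv()))
    } else on.exit(rm(".Random.seed", envir = globalenv()))
    set.seed(1563L)  # profile definition seed, independent of study seed
    expr
}

#' Expected species lipid profiles
#'
#' Builds the per-species expected peak profiles the simulator samples
#' around. The cow profile carries the 23 cow marker m/z values of the
#' bundled table at their representative (measured) masses, with base
#' intensity proportional to the tabulated |p1| influence. The goat profile
#' keeps the cow markers shrunk by the goat-cow similarity factor plus a few
#' small goat-private peaks, making goat the hardest species to separate
#' from cow. Camel, oat and soya carry their own tabulated markers plus
#' species-private peaks. All species share a common lipid backbone. Peak
#' positions of the backbone and the private peaks are deterministic (fixed
#' internal seed) and identical for every study.
#'
#' @param config a [SimulationConfig-class].
#' @param table marker table, defaults to [loadMarkerTable()].
#' @return named list of data.frames (mz, intensity, marker flag), one per
#'   species cow/goat/camel/oat/soya.
#' @export
defaultProfiles <- function(config, table = loadMarkerTable()) {
    withProfileSeed({
        nShared <- 40L
        sharedMz <- sort(runif(nShared, 120, 1100))
        sharedInt <- config@sharedScale * exp(rnorm(nShared, 0, 0.6))
        shared <- data.frame(mz = sharedMz, intensity = sharedInt,
                             marker = FALSE)
        priv <- lapply(c(goat = 6L, camel = 12L, oat = 12L, soya = 12L),
                       function(n) data.frame(
                           mz = sort(runif(n, 150, 1500)),
                           intensity = 0.5 * config@markerScale *
                               exp(rnorm(n, 0, 0.4)),
                           marker = FALSE))
    })
    markerInt <- function(rows)
        config@effectSize * config@markerScale * abs(rows$p1) / 0.08
    markerPeaks <- function(type) {
        rows <- table[grepl(type, table$milk_type, fixed = TRUE), ]
        data.frame(mz = rows$representative_mass,
                   intensity = markerInt(rows), marker = TRUE)
    }
    cowMarkers <- markerPeaks("cow")
    goatMarkers <- cowMarkers
    goatMarkers$intensity <- goatMarkers$intensity * config@goatSimilarity
    ## The glycerolipid (TG/PC) markers are a property of the GL-rich group
    ## (camel, oat, soya): each is most abundant in its attributed species
    ## and present at a reduced level in the other two. Goat milk, like cow,
    ## is GP/SP-dominated and carries none of them.
    glGroup <- c("camel", "oat", "soya")
    glMarkers <- function(sp) {
        rows <- table[table$milk_type != "cow", ]
        own <- grepl(sp, rows$milk_type, fixed = TRUE)
        data.frame(mz = rows$representative_mass,
                   intensity = markerInt(rows) *
                       ifelse(own, 1, config@glCrossLevel),
                   marker = TRUE)
    }
    mk <- function(...) {
        df <- do.call(rbind, list(...))
        df <- df[order(df$mz), ]
        stopifnot(all(df$mz >= 100 & df$mz < 2000))
        rownames(df) <- NULL
        df
    }
    out <- list(cow = mk(shared, cowMarkers),
                goat = mk(shared, goatMarkers, priv$goat))
    for (sp in glGroup)
        out[[sp]] <- mk(shared, glMarkers(sp), priv[[sp]])
    out
}

## Expected profile of an alpha cow-into-base mixture: peak-wise
## (1 - alpha) * base + alpha * cow on the union of m/z positions.
mixProfiles <- function(base, cow, alpha) {
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    if (alpha == 0) return(base)
    if (alpha == 1) return(cow)
    mz <- sort(union(base$mz, cow$mz))
    bi <- base$intensity[match(mz, base$mz)]; bi[is.na(bi)] <- 0
    ci <- cow$intensity[match(mz, cow$mz)]; ci[is.na(ci)] <- 0
    mrk <- (mz %in% base$mz[base$marker]) | (mz %in% cow$mz[cow$marker])
    data.frame(mz = mz, intensity = (1 - alpha) * bi + alpha * ci,
               marker = mrk)
}

#' Simulate one milk sample
#'
#' Draws a [SampleRecord-class] around an expected profile (optionally an
#' alpha-mixture of a base and the cow profile). Each replicate scan draws
#' peak intensities from `lognormal(log expected, sigma)`, jitters each m/z
#' by `Normal(0, ppm * mz / 1e6)`, adds a Poisson number of background peaks
#' at uniform m/z with exponential intensities, and scales the whole scan by
#' a lognormal TIC factor. Marker peaks are additionally multiplied by a
#' per-source (farm) offset. The replicate count is uniform over the
#' configured range. Draws come from the current RNG state; seed at the
#' study level.
#'
#' @param profile expected profile data.frame (mz, intensity, marker).
#' @param config a [SimulationConfig-class].
#' @param sampleId,species,sourceId metadata for the record.
#' @param alpha cow-milk volume fraction; when > 0, `cowProfile` must be
#'   supplied and the expected profile is the alpha-mixture.
#' @param cowProfile the cow profile used for mixing.
#' @param sourceEffect multiplicative per-source marker offset: either a
#'   scalar or a vector named by marker m/z ("%.4f" format), so each lipid
#'   carries its own farm-to-farm level.
#' @return a [SampleRecord-class].
#' @export
simulateSample <- function(profile, config, sampleId, species,
                           sourceId = "src1", alpha = 0, cowProfile = NULL,
                           sourceEffect = 1) {
    if (alpha > 0) {
        if (is.null(cowProfile)) stop("cowProfile is required when alpha > 0")
        profile <- mixProfiles(profile, cowProfile, alpha)
    }
    eff <- rep(1, nrow(profile))
    if (length(sourceEffect) == 1L && is.null(names(sourceEffect))) {
        eff[profile$marker] <- sourceEffect
    } else {
        key <- sprintf("%.4f", profile$mz)
        hit <- profile$marker & key %in% names(sourceEffect)
        eff[hit] <- sourceEffect[key[hit]]
    }
    expected <- profile$intensity * eff
    nRep <- sample(seq(config@replicateRange[1], config@replicateRange[2]),
                   1)
    scans <- lapply(seq_len(nRep), function(i) {
        int <- rlnorm(length(expected), log(expected),
                      config@intensitySigma)
        mz <- profile$mz + rnorm(length(expected)) * config@mzJitterPpm *
            profile$mz / 1e6
        nBg <- rpois(1, config@backgroundPeaks)
        if (nBg > 0) {
            mz <- c(mz, runif(nBg, 100, 2000))
            int <- c(int, rexp(nBg, 1 / config@backgroundMeanIntensity))
        }
        tic <- rlnorm(1, 0, config@ticSigma)
        ord <- order(mz)
        ## collapse (vanishingly rare) duplicate m/z after jitter
        mz <- mz[ord]; int <- int[ord] * tic
        dup <- duplicated(mz)
        if (any(dup)) {
            int <- as.vector(rowsum(int, mz))
            mz <- sort(unique(mz))
        }
        peakList(mz, int)
    })
    sampleRecord(sampleId, species, alpha, sourceId, scans)
}

#' Simulate a full five-species study with adulteration series
#'
#' Generates the pure-sample study (per-species sample counts, farm/supplier
#' structure and 6-9 replicate scans from the configuration) plus the four
#' cow-into-other mixture series of [defaultDesigns()], fully reproducible
#' from the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @param designs mixture designs; defaults to
#'   `defaultDesigns(config@samplesPerLevel, config@replicateRange)`. Pass
#'   an empty list to skip the adulteration series.
#' @return list with `samples` (list of [SampleRecord-class]) and `truth`
#'   (data.frame: sample_id, species, alpha, source_id, base_species,
#'   series, n_scans).
#' @export
simulateStudy <- function(config,
                          designs = defaultDesigns(config@samplesPerLevel,
                                                   config@replicateRange)) {
    set.seed(config@seed)
    profiles <- defaultProfiles(config)
    markerMz <- sort(unique(unlist(lapply(profiles, function(p)
        p$mz[p$marker]))))
    samples <- list()
    truth <- list()
    sourceEffects <- list()
    sourceOf <- function(species, k) {
        nSrc <- config@sourcesPerSpecies[[species]]
        sprintf("%s_src%02d", species, 1L + (k - 1L) %% nSrc)
    }
    ## per-farm, per-lipid marker levels: each marker m/z gets its own
    ## lognormal offset for each source
    effectOf <- function(src) {
        if (is.null(sourceEffects[[src]]))
            sourceEffects[[src]] <<- setNames(
                rlnorm(length(markerMz), 0, config@sourceSigma),
                sprintf("%.4f", markerMz))
        sourceEffects[[src]]
    }
    add <- function(rec, baseSpecies, series) {
        samples[[length(samples) + 1L]] <<- rec
        truth[[length(truth) + 1L]] <<- data.frame(
            sample_id = rec@sampleId, species = rec@species,
            alpha = rec@adulterationFraction, source_id = rec@sourceId,
            base_species = baseSpecies, series = series,
            n_scans = length(rec@scans), stringsAsFactors = FALSE)
    }
    for (sp in names(config@samplesPerSpecies)) {
        for (k in seq_len(config@samplesPerSpecies[[sp]])) {
            src <- sourceOf(sp, k)
            rec <- simulateSample(profiles[[sp]], config,
                                  sprintf("%s_%03d", sp, k), sp,
                                  src, alpha = if (sp == "cow") 1 else 0,
                                  cowProfile = profiles$cow,
                                  sourceEffect = effectOf(src))
            add(rec, sp, "pure")
        }
    }
    for (d in designs) {
        base <- d@baseSpecies
        for (lv in d@levels) for (k in seq_len(d@samplesPerLevel)) {
            species <- if (lv == 0) base else if (lv == 1) "cow" else
                "mixture"
            src <- sourceOf(base, k)
            rec <- simulateSample(profiles[[base]], config,
                                  sprintf("mix_%s_%.6g_%02d", base, lv, k),
                                  species, src, alpha = lv,
                                  cowProfile = profiles$cow,
                                  sourceEffect = effectOf(src))
            add(rec, base, paste0("mix_", base))
        }
    }
    list(samples = samples, truth = do.call(rbind, truth))
}
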