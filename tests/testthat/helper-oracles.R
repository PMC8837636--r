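## Independent single-component PLS1 (textbook NIPALS, closed form for one
## component). Kept free of any package internals so it can act as an
## oracle for fitOPLS(n_orth = 0).
pls1Oracle <- function(X, y) {
    yc <- y - mean(y)
    w <- drop(crossprod(X, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(X %*% w)
    p <- drop(crossprod(X, t)) / sum(t^2)
    c <- sum(t * yc) / sum(t^2)
    list(w = w, t = t, p = p, c = c, yMean = mean(y))
}

## Dense eigendecomposition oracle for PCA: eigenvectors/eigenvalues of the
## sample covariance of the centered data.
pcaEigenOracle <- function(X) {
    Xc <- sweep(X, 2, colMeans(X))
    eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
}

## Two well-separated Gaussian classes on a handful of variables.
gaussianClasses <- function(n = 10, p = 6, shift = 8, seed = 1,
                            classes = c("a", "b")) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n * p), n, p),
               matrix(rnorm(n * p, mean = shift), n, p))
    list(X = X, labels = rep(classes, each = n))
}

## Small synthetic milk study shared by the slower tests; built once per
## test run and cached.
.fixtures <- new.env(parent = emptyenv())

smallStudy <- function() {
    if (!is.null(.fixtures$study)) return(.fixtures$study)
    cfg <- simConfig(seed = 101,
                     samplesPerSpecies = c(cow = 10, goat = 8, camel = 8,
                                           oat = 8, soya = 8),
                     samplesPerLevel = 5)
    st <- simulateStudy(cfg)
    perSpec <- ticNormalize(buildFeatureMatrix(st$samples,
                                               perSpectrum = TRUE))
    pure <- sampleMeta(perSpec)$species != "mixture" &
        !grepl("^mix_", sampleMeta(perSpec)$sample_id)
    .fixtures$study <- list(config = cfg, study = st, perSpectrum = perSpec,
                            pureMask = pure)
    .fixtures$study
}

## Per-sample averaged, Pareto-scaled matrix of the pure samples (the
## OPLS-DA working representation).
pureScaled <- function() {
    if (!is.null(.fixtures$pureScaled)) return(.fixtures$pureScaled)
    s <- smallStudy()
    ma <- buildFeatureMatrix(
        s$study$samples[s$study$truth$series == "pure"])
    .fixtures$pureScaled <- scaleMatrix(ma, "pareto")
    .fixtures$pureScaled
}

markerBinCenters <- function() {
    tab <- loadMarkerTable()
    grid <- binGrid()
    centers <- binCenters(grid)
    idx <- floor((tab$representative_mass - 100) / 0.2 + 1e-9) + 1
    sort(unique(centers[idx]))
}
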