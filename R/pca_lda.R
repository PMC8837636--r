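#' @include preprocessing.R
NULL

asValues <- function(m) if (is(m, "FeatureMatrix")) m@values else as.matrix(m)

#' Fit a principal component model
#'
#' Components are extracted from the singular value decomposition of the
#' column-centered data, so they maximise captured variance. The sign of each
#' component is fixed so its largest-magnitude loading element is positive,
#' making runs reproducible.
#'
#' @param m a [FeatureMatrix-class] (centered or scaled is fine; centering is
#'   always applied internally and recorded) or a plain matrix.
#' @param k number of components, `k <= min(samples - 1, bins)`.
#' @return a [PCAModel-class].
#' @export
fitPCA <- function(m, k) {
    X <- asValues(m)
    kmax <- min(nrow(X) - 1L, ncol(X))
    if (k > kmax)
        stop(sprintf("k = %d exceeds min(samples - 1, bins) = %d", k, kmax))
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = k, nv = k)
    flip <- vapply(seq_len(k), function(j) {
        i <- which.max(abs(sv$v[, j]))
        if (sv$v[i, j] < 0) -1 else 1
    }, 0)
    V <- sweep(sv$v, 2, flip, "*")
    U <- sweep(sv$u, 2, flip, "*")
    scores <- U %*% diag(sv$d[seq_len(k)], k)
    rownames(scores) <- rownames(X)
    total <- sum(sv$d^2)
    explained <- if (total > 0) sv$d[seq_len(k)]^2 / total else rep(0, k)
    new("PCAModel", loadings = V, scores = scores, explained = explained,
        q2 = numeric(), columnMeans = mu)
}

## Project new rows into an existing PCA space.
pcaProject <- function(model, X, k = ncol(model@loadings)) {
    sweep(as.matrix(X), 2, model@columnMeans) %*%
        model@loadings[, seq_len(k), drop = FALSE]
}

#' Cross-validated predictive ability (Q2) of a PCA model
#'
#' Row-wise k-fold cross-validation with element-wise-corrected
#' reconstruction: each fold's rows are held out, a PCA is fitted on the
#' remainder, and every element of a held-out row is predicted from the
#' row's OTHER elements through the training loadings (the j-th coordinate
#' is excluded from its own score estimate). The naive alternative --
#' projecting the full held-out row onto the loadings -- is a contraction
#' and can never raise the residual, so it would report Q2 > 0 even for
#' pure noise. `Q2(a) = 1 - PRESS(a)/SS` with SS the train-centered total
#' sum of squares of the held-out rows. Fold assignment is deterministic
#' (interleaved by row order).
#'
#' @param m matrix or [FeatureMatrix-class].
#' @param k number of components to evaluate.
#' @param folds number of folds (>= 2, <= rows).
#' @return numeric vector, cumulative Q2 per component count 1..k.
#' @export
pcaQ2 <- function(m, k, folds = 7) {
    X <- asValues(m)
    n <- nrow(X)
    if (folds < 2L) stop("folds must be >= 2")
    if (folds > n) stop("more folds than samples")
    fold <- rep_len(seq_len(folds), n)
    press <- numeric(k)
    ss <- 0
    for (f in seq_len(folds)) {
        test <- which(fold == f)
        Xtr <- X[-test, , drop = FALSE]
        ktr <- min(k, nrow(Xtr) - 1L, ncol(Xtr))
        fit <- fitPCA(Xtr, ktr)
        Xc <- sweep(X[test, , drop = FALSE], 2, fit@columnMeans)
        ss <- ss + sum(Xc^2)
        for (a in seq_len(k)) {
            aa <- min(a, ktr)
            V <- fit@loadings[, seq_len(aa), drop = FALSE]
            recon <- ewReconstruct(Xc, V)
            press[a] <- press[a] + sum((Xc - recon)^2)
        }
    }
    1 - press / ss
}

## Element-wise-corrected reconstruction of (already centered) rows from an
## orthonormal loading matrix V (p x a): coordinate j is predicted from the
## score estimated WITHOUT coordinate j. With r_j the j-th row of V and
## t = V' x, the leave-j-out score is (I - r_j r_j')^{-1} (t - r_j x_j),
## inverted in closed form via Sherman-Morrison.
ewReconstruct <- function(Xc, V) {
    Tfull <- Xc %*% V                      # n x a scores from full rows
    h <- rowSums(V^2)                      # leverage r_j' r_j per coordinate
    ## r_j' (t - r_j x_j) / (1 - r_j' r_j), vectorised over rows and columns
    s <- Tfull %*% t(V) - sweep(Xc, 2, h, "*")
    sweep(s, 2, pmax(1 - h, 1e-12), "/")
}

## Symmetric inverse square root of a positive-definite matrix.
invSqrtm <- function(S) {
    e <- eigen(S, symmetric = TRUE)
    vals <- pmax(e$values, max(e$values) * 1e-12)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
}

#' Fit a PCA-subspace Fisher discriminant model
#'
#' The data are first projected onto `nPcs` principal components (by default
#' the smallest number reaching 95% cumulative explained variance, capped at
#' `min(samples - 1, 60)`), then Fisher discriminant axes maximise the
#' between-class to within-class variance ratio. The pooled within-class
#' covariance is ridge-regularised (`eps * trace/dim` on the diagonal) when
#' near-singular.
#'
#' @param m matrix or [FeatureMatrix-class] of training rows.
#' @param labels class label per row; defaults to the species column of a
#'   [FeatureMatrix-class]'s metadata.
#' @param nPcs number of PCA components, or NULL for the automatic rule.
#' @param outlierSigma Mahalanobis radius (sd units) for outlier flagging.
#' @param r2xTarget cumulative explained-variance target of the automatic
#'   `nPcs` rule.
#' @param maxPcs cap of the automatic rule.
#' @return an [LDAModel-class].
#' @export
fitLDA <- function(m, labels = NULL, nPcs = NULL, outlierSigma = 5,
                   r2xTarget = 0.95, maxPcs = 60) {
    X <- asValues(m)
    if (is.null(labels)) {
        if (!is(m, "FeatureMatrix"))
            stop("labels are required for plain-matrix input")
        labels <- m@meta$species
    }
    labels <- as.character(labels)
    counts <- table(labels)
    if (length(counts) < 2L) stop("at least 2 classes are required")
    if (any(counts < 2L))
        stop("every class needs >= 2 samples; too few in: ",
             paste(names(counts)[counts < 2L], collapse = ", "))
    kmax <- min(nrow(X) - 1L, ncol(X), maxPcs)
    if (is.null(nPcs)) {
        fit <- fitPCA(X, kmax)
        cum <- cumsum(fit@explained)
        nPcs <- which(cum >= r2xTarget)[1]
        if (is.na(nPcs)) nPcs <- kmax
    } else {
        if (nPcs > kmax) stop("nPcs exceeds min(samples - 1, bins)")
        fit <- fitPCA(X, nPcs)
    }
    S <- fit@scores[, seq_len(nPcs), drop = FALSE]
    classes <- sort(names(counts))
    mu <- t(vapply(classes, function(cl)
        colMeans(S[labels == cl, , drop = FALSE]), numeric(nPcs)))
    grand <- colMeans(S)
    Sw <- matrix(0, nPcs, nPcs)
    for (cl in classes) {
        D <- sweep(S[labels == cl, , drop = FALSE], 2, mu[cl, ])
        Sw <- Sw + crossprod(D)
    }
    Sw <- Sw / (nrow(S) - length(classes))
    Sw <- Sw + diag(1e-8 * sum(diag(Sw)) / nPcs, nPcs)
    Sb <- matrix(0, nPcs, nPcs)
    for (cl in classes) {
        d <- mu[cl, ] - grand
        Sb <- Sb + counts[[cl]] * tcrossprod(d)
    }
    Sb <- Sb / nrow(S)
    W <- invSqrtm(Sw)
    M <- W %*% Sb %*% W
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    nAxes <- min(length(classes) - 1L, nPcs)
    D <- W %*% e$vectors[, seq_len(nAxes), drop = FALSE]
    for (j in seq_len(nAxes)) {
        i <- which.max(abs(D[, j]))
        if (D[i, j] < 0) D[, j] <- -D[, j]
    }
    Z <- S %*% D
    muZ <- mu %*% D
    SwZ <- matrix(0, nAxes, nAxes)
    for (cl in classes) {
        dz <- sweep(Z[labels == cl, , drop = FALSE], 2, muZ[cl, ])
        SwZ <- SwZ + crossprod(dz)
    }
    SwZ <- SwZ / (nrow(Z) - length(classes))
    SwZ <- SwZ + diag(1e-10 * (sum(diag(SwZ)) / nAxes + 1), nAxes)
    pcaSmall <- initialize(fit,
        loadings = fit@loadings[, seq_len(nPcs), drop = FALSE],
        scores = S, explained = fit@explained[seq_len(nPcs)])
    new("LDAModel", pca = pcaSmall, directions = D, classMeans = muZ,
        pooledCov = SwZ, classes = classes, outlierSigma = outlierSigma)
}

#' Recalibrate an LDA model's pooled covariance on spectrum-level rows
#'
#' A model fitted on per-sample averaged rows underestimates the spread of
#' individual spectra (averaging over 6-9 scans shrinks the noise), which
#' inflates Mahalanobis distances when single spectra are classified. This
#' re-estimates the pooled within-class covariance in discriminant space
#' from spectrum-level rows, leaving the discriminant axes untouched, so the
#' outlier radius is expressed in spectrum-level standard deviations.
#'
#' @param model an [LDAModel-class].
#' @param m spectrum-level rows (matrix or [FeatureMatrix-class]).
#' @param labels class per row.
#' @return the model with `pooledCov` replaced.
#' @export
calibrateCovariance <- function(model, m, labels) {
    X <- asValues(m)
    labels <- as.character(labels)
    Z <- pcaProject(model@pca, X) %*% model@directions
    nAxes <- ncol(Z)
    used <- intersect(model@classes, unique(labels))
    SwZ <- matrix(0, nAxes, nAxes)
    for (cl in used) {
        dz <- sweep(Z[labels == cl, , drop = FALSE], 2,
                    colMeans(Z[labels == cl, , drop = FALSE]))
        SwZ <- SwZ + crossprod(dz)
    }
    SwZ <- SwZ / (sum(labels %in% used) - length(used))
    SwZ <- SwZ + diag(1e-10 * (sum(diag(SwZ)) / nAxes + 1), nAxes)
    initialize(model, pooledCov = SwZ)
}

#' Classify spectra with a fitted LDA model
#'
#' Each row is projected through the model's PCA subspace into discriminant
#' space and assigned to the nearest class by Mahalanobis distance under the
#' pooled within-class covariance. A spectrum whose distance to the nearest
#' class mean (in sd units) exceeds the model's outlier radius is flagged as
#' an outlier.
#'
#' @param model an [LDAModel-class].
#' @param newdata matrix (rows on the training grid, same normalisation) or
#'   [FeatureMatrix-class].
#' @return data.frame: predicted, distance, outlier.
#' @export
classifySpectra <- function(model, newdata) {
    X <- asValues(newdata)
    if (ncol(X) != nrow(model@pca@loadings))
        stop("grid mismatch: new data has a different number of bins")
    Z <- pcaProject(model@pca, X) %*% model@directions
    Sinv <- solve(model@pooledCov)
    d2 <- vapply(seq_along(model@classes), function(i) {
        D <- sweep(Z, 2, model@classMeans[i, ])
        rowSums((D %*% Sinv) * D)
    }, numeric(nrow(Z)))
    d2 <- matrix(d2, nrow = nrow(Z))
    best <- max.col(-d2, ties.method = "first")
    dist <- sqrt(d2[cbind(seq_len(nrow(Z)), best)])
    data.frame(predicted = model@classes[best], distance = dist,
               outlier = dist > model@outlierSigma,
               stringsAsFactors = FALSE)
}

#' Leave-20%-out bootstrap correct classification rate
#'
#' Repeated stratified random splits at the SAMPLE level (all spectra of a
#' sample stay together): in each repeat, 80% of the samples per class build
#' the model -- fitted on per-sample averaged rows -- and every held-out
#' spectrum is classified. The correct classification rate is counted at the
#' SPECTRUM level over all repeats, reported both excluding flagged outliers
#' from the denominator and including them.
#'
#' @param m per-spectrum [FeatureMatrix-class] (see
#'   [buildFeatureMatrix()] with `perSpectrum = TRUE`).
#' @param labels class per row; defaults to the species metadata column.
#' @param holdoutFraction fraction of samples held out per repeat.
#' @param repeats number of bootstrap repeats.
#' @param seed RNG seed for the splits.
#' @param ... passed to [fitLDA()] (nPcs, outlierSigma, ...).
#' @return a [ClassificationResult-class].
#' @export
bootstrapCCR <- function(m, labels = NULL, holdoutFraction = 0.2,
                         repeats = 25, seed = 1, ...) {
    stopifnot(is(m, "FeatureMatrix"), repeats >= 1)
    if (is.null(labels)) labels <- m@meta$species
    labels <- as.character(labels)
    sid <- m@meta$sample_id
    sampleClass <- vapply(split(labels, sid), function(x) x[1], "")
    counts <- table(sampleClass)
    nTest <- pmax(1L, round(holdoutFraction * as.integer(counts)))
    if (any(as.integer(counts) - nTest < 2L))
        stop("class too small to stratify: ",
             paste(names(counts)[as.integer(counts) - nTest < 2L],
                   collapse = ", "))
    set.seed(seed)
    out <- vector("list", repeats)
    for (r in seq_len(repeats)) {
        testSamples <- unlist(lapply(seq_along(counts), function(i) {
            ids <- names(sampleClass)[sampleClass == names(counts)[i]]
            sample(ids, nTest[i])
        }))
        trainMask <- !(sid %in% testSamples)
        stopifnot(!any(sid[trainMask] %in% sid[!trainMask]))
        trainRows <- m@values[trainMask, , drop = FALSE]
        trainAvg <- rowsum(trainRows, sid[trainMask]) /
            as.vector(table(sid[trainMask])[sort(unique(sid[trainMask]))])
        model <- fitLDA(trainAvg, sampleClass[rownames(trainAvg)], ...)
        model <- calibrateCovariance(model, trainRows, labels[trainMask])
        testMask <- !trainMask
        pred <- classifySpectra(model, m@values[testMask, , drop = FALSE])
        out[[r]] <- data.frame(
            sample_id = sid[testMask], scan = m@meta$scan[testMask],
            truth = labels[testMask], pred, repeat_ = r,
            stringsAsFactors = FALSE)
    }
    asg <- do.call(rbind, out)
    correct <- asg$truth == asg$predicted
    inl <- !asg$outlier
    new("ClassificationResult", assignments = asg,
        ccrExcludingOutliers = if (any(inl)) mean(correct[inl]) else NaN,
        ccrIncludingOutliers = mean(correct))
}
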