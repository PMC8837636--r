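test_that("PCA agrees with a dense eigendecomposition oracle", {
    set.seed(11)
    for (dims in list(c(6, 4), c(12, 9), c(20, 20))) {
        X <- matrix(rnorm(prod(dims)), dims[1], dims[2])
        k <- min(dims) - 1
        fit <- fitPCA(X, k)
        eo <- pcaEigenOracle(X)
        total <- sum(eo$values)
        expect_equal(explainedVariance(fit), eo$values[1:k] / total,
                     tolerance = 1e-8)
        for (j in 1:k) {
            v <- eo$vectors[, j]
            expect_equal(abs(sum(loadings(fit)[, j] * v)), 1,
                         tolerance = 1e-8)
        }
        ## projection identity and the deterministic sign convention
        Xc <- sweep(X, 2, colMeans(X))
        expect_equal(scores(fit), Xc %*% loadings(fit), tolerance = 1e-10,
                     ignore_attr = TRUE)
        for (j in 1:k)
            expect_gt(loadings(fit)[which.max(abs(loadings(fit)[, j])), j], 0)
    }
})

test_that("rank-1 data are fully explained by one component", {
    u <- 1:8; v <- rnorm(5, 2)
    X <- outer(u, v)
    fit <- fitPCA(X, 1)
    expect_equal(explainedVariance(fit)[1], 1, tolerance = 1e-9)
    expect_error(fitPCA(X, 8), "exceeds")
})

test_that("Q2 reflects predictable structure and penalises noise", {
    u <- seq(-2, 2, length.out = 12); v <- rnorm(6, 3)
    X <- outer(u, v)
    expect_gte(pcaQ2(X, 1, folds = 4)[1], 0.99)
    set.seed(5)
    q2noise <- replicate(20, {
        pcaQ2(matrix(rnorm(10 * 8), 10, 8), 1, folds = 5)[1]
    })
    expect_lte(median(q2noise), 0)
    ## Q2 never beats cumulative R2X on the same data
    set.seed(6)
    for (i in 1:5) {
        X <- matrix(rnorm(12 * 7), 12, 7) + outer(rnorm(12), rnorm(7, 1))
        k <- 3
        expect_true(all(pcaQ2(X, k, folds = 4) <=
                        cumsum(explainedVariance(fitPCA(X, k))) + 1e-8))
    }
    expect_error(pcaQ2(X, 2, folds = 50), "folds")
})

test_that("LDA separates Gaussian clouds and guards its preconditions", {
    g <- gaussianClasses(n = 12, shift = 8, seed = 2)
    model <- fitLDA(g$X, g$labels, nPcs = 3)
    pred <- classifySpectra(model, g$X)
    expect_equal(mean(pred$predicted == g$labels), 1)
    expect_error(fitLDA(g$X, rep("a", nrow(g$X))), "2 classes")
    expect_error(fitLDA(g$X, c("b", rep("a", nrow(g$X) - 1))), ">= 2 samples")
})

test_that("permuted labels drop training accuracy to chance", {
    set.seed(9)
    X <- matrix(rnorm(60 * 10), 60, 10)
    labels <- rep(letters[1:5], each = 12)
    accs <- replicate(10, {
        perm <- sample(labels)
        model <- fitLDA(X, perm, nPcs = 5)
        mean(classifySpectra(model, X)$predicted == perm)
    })
    ## training accuracy on permuted labels overfits somewhat above the
    ## 20% chance level but stays far from separation
    expect_lt(median(accs), 0.6)
    expect_gt(median(accs), 0.1)
})

test_that("classification distances match brute-force Mahalanobis", {
    g <- gaussianClasses(n = 10, shift = 5, seed = 4)
    model <- fitLDA(g$X, g$labels, nPcs = 4)
    pred <- classifySpectra(model, g$X)
    Z <- desimilk:::pcaProject(model@pca, g$X) %*% model@directions
    manual <- vapply(seq_len(nrow(Z)), function(i) {
        sqrt(min(vapply(seq_along(model@classes), function(c1)
            stats::mahalanobis(Z[i, ], model@classMeans[c1, ],
                               model@pooledCov), 0)))
    }, 0)
    expect_equal(pred$distance, manual, tolerance = 1e-8)
    expect_true(all(pred$outlier == (pred$distance > model@outlierSigma)))
})

test_that("class centroids classify to themselves; far points are outliers", {
    g <- gaussianClasses(n = 10, shift = 6, seed = 8)
    model <- fitLDA(g$X, g$labels, nPcs = 3)
    centroidA <- colMeans(g$X[g$labels == "a", ])
    ## reconstruct the row whose discriminant image is the class centroid
    predA <- classifySpectra(model, matrix(centroidA, 1))
    expect_equal(predA$predicted, "a")
    expect_false(predA$outlier)
    far <- matrix(centroidA + 100, 1)
    expect_true(classifySpectra(model, far)$outlier)
    expect_error(classifySpectra(model, matrix(0, 1, 3)), "grid mismatch")
})

test_that("bootstrap CCR is deterministic under a seed and perfect on separated classes", {
    set.seed(21)
    n <- 24
    X <- rbind(matrix(rnorm(n * 6), n, 6),
               matrix(rnorm(n * 6, mean = 10), n, 6))
    sid <- rep(sprintf("s%02d", 1:16), each = 3)
    g3 <- binGrid(100, 101.2, 0.2)
    m <- new("FeatureMatrix", values = X, grid = g3,
             meta = data.frame(sample_id = sid,
                               species = rep(c("cow", "oat"), each = n),
                               adulteration_fraction = rep(c(1, 0), each = n),
                               source_id = "f", scan = rep(1:3, 16)),
             normalisation = "raw", scaling = "unscaled",
             columnMeans = numeric(), columnScales = numeric())
    rownames(m@values) <- paste(sid, rep(1:3, 16))
    r1 <- bootstrapCCR(m, repeats = 3, seed = 42, nPcs = 2)
    r2 <- bootstrapCCR(m, repeats = 3, seed = 42, nPcs = 2)
    expect_identical(r1@assignments, r2@assignments)
    expect_equal(r1@ccrExcludingOutliers, 1)
    ## spectra of one sample never straddle the split
    byRep <- split(r1@assignments$sample_id, r1@assignments$repeat_)
    expect_true(all(vapply(byRep, function(ids)
        length(unique(ids)) <= 4, TRUE)))
    ## shuffled labels land near chance for two balanced classes
    set.seed(1)
    shuffledSampleClass <- sample(rep(c("cow", "oat"), 8))
    shuffled <- shuffledSampleClass[match(sid, sprintf("s%02d", 1:16))]
    rs <- bootstrapCCR(m, labels = shuffled, repeats = 5, seed = 1, nPcs = 2)
    expect_lt(rs@ccrIncludingOutliers, 0.9)
})
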