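test_that("the class encoding maps cow to -1 and guards degeneracies", {
    y <- encodeY(c("cow", "goat", "oat"))
    expect_equal(as.numeric(y), c(-1, 1, 1))
    expect_error(encodeY(c("cow", "cow")), "both groups")
    expect_error(encodeY(c("cow", "dog"), negativeClasses = "cow",
                         positiveClasses = "goat"), "neither group")
    y2 <- encodeY(c("water", "methanol"), negativeClasses = "methanol",
                  positiveClasses = "water")
    expect_equal(as.numeric(y2), c(1, -1))
})

test_that("a perfectly predictive column dominates the model", {
    set.seed(13)
    X <- matrix(rnorm(20 * 6, sd = 0.01), 20, 6)
    y <- rep(c(-1, 1), each = 10)
    X[, 3] <- y * 2
    X <- sweep(X, 2, colMeans(X))
    fit <- fitOPLS(X, y, nOrth = 0)
    expect_gte(fit@r2y, 0.999)
    b <- oplsCoefficients(fit)
    expect_gt(abs(b[3]), 10 * max(abs(b[-3])))
})

test_that("with no orthogonal components the model is exactly PLS1", {
    set.seed(17)
    for (i in 1:5) {
        X <- sweep(matrix(rnorm(10 * 6), 10, 6), 2, colMeans(
            matrix(0, 1, 6)))
        X <- sweep(X, 2, colMeans(X))
        y <- rep(c(-1, 1), each = 5)
        fit <- fitOPLS(X, y, nOrth = 0)
        oracle <- pls1Oracle(X, y)
        expect_equal(fit@w, oracle$w, tolerance = 1e-8)
        expect_equal(fit@t, oracle$t, tolerance = 1e-8)
        expect_equal(fit@p, oracle$p, tolerance = 1e-8)
        expect_equal(fit@c, oracle$c, tolerance = 1e-8)
        expect_equal(predictOPLS(fit, X),
                     oracle$t * oracle$c + oracle$yMean, tolerance = 1e-8)
    }
})

test_that("orthogonal components are orthogonal to w and uncorrelated with y", {
    set.seed(19)
    for (i in 1:5) {
        X <- matrix(rnorm(16 * 12), 16, 12) +
            outer(rnorm(16, sd = 3), rnorm(12))  # planted orthogonal structure
        X <- sweep(X, 2, colMeans(X))
        y <- rep(c(-1, 1), 8)
        fit <- fitOPLS(X, y, nOrth = 2)
        for (j in seq_len(fit@nOrth)) {
            expect_lt(abs(sum(fit@w * fit@wOrth[, j])), 1e-8)
            expect_lt(abs(cor(fit@tOrth[, j], y)), 1e-6)
        }
    }
})

test_that("coefficient-path predictions equal the score path exactly", {
    set.seed(23)
    X <- sweep(matrix(rnorm(14 * 9), 14, 9), 2, 0)
    X <- sweep(X, 2, colMeans(X))
    y <- rep(c(-1, 1), 7)
    for (nOrth in 0:2) {
        fit <- fitOPLS(X, y, nOrth)
        b <- oplsCoefficients(fit)
        expect_equal(drop(X %*% b) + fit@yMean, predictOPLS(fit, X),
                     tolerance = 1e-8)
    }
})

test_that("relabelling flips S-plot signs but not R2Y or Q2", {
    set.seed(29)
    X <- rbind(matrix(rnorm(8 * 10), 8, 10),
               matrix(rnorm(8 * 10, mean = 1.5), 8, 10))
    X <- sweep(X, 2, colMeans(X))
    y <- rep(c(-1, 1), each = 8)
    f1 <- fitOPLS(X, y, 1); f2 <- fitOPLS(X, -y, 1)
    expect_equal(f1@r2y, f2@r2y, tolerance = 1e-9)
    expect_equal(oplsQ2(X, y, 1, folds = 4, seed = 3),
                 oplsQ2(X, -y, 1, folds = 4, seed = 3), tolerance = 1e-9)
    s1 <- sPlot(f1, X); s2 <- sPlot(f2, X)
    expect_equal(s1@p1, -s2@p1, tolerance = 1e-9)
    expect_equal(s1@pcorr, -s2@pcorr, tolerance = 1e-9)
})

test_that("S-plot statistics behave at the extremes", {
    set.seed(31)
    X <- matrix(rnorm(12 * 5), 12, 5)
    X <- sweep(X, 2, colMeans(X))
    y <- rep(c(-1, 1), 6)
    fit <- fitOPLS(X, y, 0)
    X2 <- cbind(X, fit@t, 0)
    s <- sPlot(fit, X2)
    expect_equal(s@pcorr[6], 1, tolerance = 1e-9)
    expect_equal(s@p1[7], 0)
    expect_equal(s@pcorr[7], 0)
    expect_true(all(abs(s@pcorr) <= 1 + 1e-12))
})

test_that("Q2 rewards real separation, punishes permuted labels, and is seeded", {
    g <- gaussianClasses(n = 8, p = 12, shift = 3, seed = 37)
    X <- sweep(g$X, 2, colMeans(g$X))
    y <- encodeY(g$labels, negativeClasses = "a")
    expect_gt(oplsQ2(X, y, 1, folds = 4, seed = 1), 0.5)
    expect_equal(oplsQ2(X, y, 1, folds = 4, seed = 9),
                 oplsQ2(X, y, 1, folds = 4, seed = 9))
    set.seed(41)
    q2perm <- replicate(20, oplsQ2(X, sample(y), 1, folds = 4,
                                   seed = sample.int(1e6, 1)))
    expect_lte(median(q2perm), 0)
})

test_that("the permutation test validates real structure and reports honestly", {
    g <- gaussianClasses(n = 8, p = 10, shift = 4, seed = 43)
    X <- sweep(g$X, 2, colMeans(g$X))
    y <- encodeY(g$labels, negativeClasses = "a")
    rep <- permutationTest(X, y, nOrth = 0, nPerm = 30, folds = 4, seed = 5)
    expect_true(rep@valid)
    expect_equal(rep@nPerm, 30L)
    expect_true(all(rep@permQ2 < rep@origQ2))
    ## the identity permutation is excluded, so no permuted y matches
    expect_true(all(rep@permCor < 1))
    expect_error(permutationTest(X, y, nPerm = 5), "at least 10")
})
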