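#' @include pca_lda.R
NULL

#' Encode class labels as a +/-1 response
#'
#' The conventional encoding for the cow-vs-rest comparison maps cow to -1
#' and every other milk to +1, so cow-associated S-plot statistics come out
#' negative. Any caller-specified binary mapping is accepted.
#'
#' @param labels character vector of class labels.
#' @param negativeClasses labels mapped to -1 (default "cow").
#' @param positiveClasses labels mapped to +1; defaults to all remaining
#'   labels.
#' @return numeric vector of -1/+1 with the mapping in
#'   `attr(, "encoding")`; errors if a label falls in neither group or if
#'   only one group is present.
#' @export
#' @examples
#' encodeY(c("cow", "goat", "oat"))
encodeY <- function(labels, negativeClasses = "cow",
                    positiveClasses = NULL) {
    labels <- as.character(labels)
    if (is.null(positiveClasses))
        positiveClasses <- setdiff(unique(labels), negativeClasses)
    bad <- setdiff(unique(labels), c(negativeClasses, positiveClasses))
    if (length(bad))
        stop("label(s) in neither group: ", paste(bad, collapse = ", "))
    y <- ifelse(labels %in% negativeClasses, -1, 1)
    if (length(unique(y)) < 2L)
        stop("both groups must be present in the data")
    enc <- c(setNames(rep(-1, length(negativeClasses)), negativeClasses),
             setNames(rep(1, length(positiveClasses)), positiveClasses))
    structure(y, encoding = enc)
}

#' Fit a binary OPLS-DA model
#'
#' Iteratively removes `nOrth` components of X-variation orthogonal to the
#' response, then fits a single predictive component on the filtered matrix.
#' Per orthogonal round: `w = X'y` (normalised), `t = Xw`, `p = X't/(t't)`,
#' `w_o = p - (w'p)w` (normalised), `t_o = X w_o`, `p_o = X't_o/(t_o't_o)`,
#' and X is deflated by `t_o p_o'`. With `nOrth = 0` the model coincides with
#' single-component PLS1.
#'
#' @param X column-centered (typically Pareto-scaled) matrix or a scaled
#'   [FeatureMatrix-class].
#' @param y +/-1 response from [encodeY()] (centered internally).
#' @param nOrth number of orthogonal components to remove (>= 0).
#' @return an [OPLSModel-class].
#' @export
fitOPLS <- function(X, y, nOrth = 1) {
    Xm <- asValues(X)
    if (nOrth < 0) stop("nOrth must be >= 0")
    if (length(y) != nrow(Xm)) stop("y length must match the row count")
    if (var(y) == 0) stop("y has zero variance")
    nOrth <- as.integer(nOrth)
    yMean <- mean(y)
    yc <- y - yMean
    p <- ncol(Xm)
    wO <- matrix(0, p, nOrth); pO <- matrix(0, p, nOrth)
    tO <- matrix(0, nrow(Xm), nOrth)
    Xf <- Xm
    for (j in seq_len(nOrth)) {
        w <- crossprod(Xf, yc)[, 1]
        w <- w / sqrt(sum(w^2))
        t <- Xf %*% w
        pl <- crossprod(Xf, t)[, 1] / sum(t^2)
        wo <- pl - sum(w * pl) * w
        no <- sqrt(sum(wo^2))
        if (no < 1e-12) { nOrth <- j - 1L; break }
        wo <- wo / no
        to <- Xf %*% wo
        po <- crossprod(Xf, to)[, 1] / sum(to^2)
        Xf <- Xf - to %*% t(po)
        wO[, j] <- wo; pO[, j] <- po; tO[, j] <- to
    }
    wO <- wO[, seq_len(nOrth), drop = FALSE]
    pO <- pO[, seq_len(nOrth), drop = FALSE]
    tO <- tO[, seq_len(nOrth), drop = FALSE]
    w <- crossprod(Xf, yc)[, 1]
    w <- w / sqrt(sum(w^2))
    t <- (Xf %*% w)[, 1]
    pl <- crossprod(Xf, t)[, 1] / sum(t^2)
    cc <- sum(t * yc) / sum(t^2)
    r2y <- 1 - sum((yc - cc * t)^2) / sum(yc^2)
    enc <- attr(y, "encoding")
    if (is.null(enc)) enc <- c(negative = -1, positive = 1)
    new("OPLSModel", yEncoding = enc, w = w, t = t, p = pl, c = cc,
        wOrth = wO, pOrth = pO, tOrth = tO, nOrth = nOrth,
        r2y = r2y, q2y = NA_real_, yMean = yMean)
}

## Remove the fitted orthogonal components from (new) rows.
oplsFilter <- function(model, X) {
    Xf <- as.matrix(X)
    for (j in seq_len(model@nOrth)) {
        to <- Xf %*% model@wOrth[, j]
        Xf <- Xf - to %*% t(model@pOrth[, j])
    }
    Xf
}

#' Predict the response for new rows
#'
#' @param model an [OPLSModel-class].
#' @param X new rows on the training scaling.
#' @return numeric predictions of the +/-1 response.
#' @export
predictOPLS <- function(model, X) {
    Xf <- oplsFilter(model, X)
    drop(Xf %*% model@w) * model@c + model@yMean
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Stratified k-fold cross-validation of the predicted response:
#' `Q2 = 1 - PRESS/SS(y)` accumulated over held-out predictions from models
#' refitted without the held-out rows. Folds are stratified by class and
#' drawn from a seeded RNG.
#'
#' @inheritParams fitOPLS
#' @param folds number of folds (>= 2; at most the size of either class).
#' @param seed RNG seed for the fold assignment.
#' @return scalar Q2.
#' @export
oplsQ2 <- function(X, y, nOrth = 1, folds = 7, seed = 1) {
    Xm <- asValues(X)
    if (folds < 2L) stop("folds must be >= 2")
    if (folds > min(table(y)))
        stop("folds exceed the size of the smaller class")
    set.seed(seed)
    fold <- integer(length(y))
    for (cl in unique(y)) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    press <- 0
    for (f in seq_len(folds)) {
        test <- which(fold == f)
        fit <- fitOPLS(Xm[-test, , drop = FALSE], y[-test], nOrth)
        yhat <- predictOPLS(fit, Xm[test, , drop = FALSE])
        press <- press + sum((y[test] - yhat)^2)
    }
    1 - press / sum((y - mean(y))^2)
}

#' Y-permutation validation of an OPLS-DA model
#'
#' The response is randomly permuted `nPerm` times (identity permutations are
#' redrawn), the model and its Q2 recomputed each time, and the model is
#' declared valid when every permuted Q2 falls below the original Q2. The
#' per-permutation label correlation and R2Y are reported for the customary
#' permutation plot.
#'
#' @inheritParams oplsQ2
#' @param nPerm number of permutations (>= 10).
#' @return a [PermutationReport-class].
#' @export
permutationTest <- function(X, y, nOrth = 1, nPerm = 100, folds = 7,
                            seed = 1) {
    if (nPerm < 10) stop("use at least 10 permutations")
    Xm <- asValues(X)
    origFit <- fitOPLS(Xm, y, nOrth)
    origQ2 <- oplsQ2(Xm, y, nOrth, folds = folds, seed = seed)
    set.seed(seed)
    permCor <- permR2Y <- permQ2 <- numeric(nPerm)
    for (i in seq_len(nPerm)) {
        repeat {
            yp <- sample(y)
            if (!all(yp == y)) break
        }
        permCor[i] <- abs(cor(yp, y))
        fit <- fitOPLS(Xm, yp, nOrth)
        permR2Y[i] <- fit@r2y
        permQ2[i] <- oplsQ2(Xm, yp, nOrth, folds = min(folds, min(table(yp))),
                            seed = seed + i)
    }
    new("PermutationReport", nPerm = as.integer(nPerm), permCor = permCor,
        permR2Y = permR2Y, permQ2 = permQ2, origR2Y = origFit@r2y,
        origQ2 = origQ2, valid = all(permQ2 < origQ2))
}

#' S-plot statistics of a fitted OPLS-DA model
#'
#' For every bin i, `p1_i = cov(t, x_i)` (influence on the model, in model
#' scale) and `pcorr_i = p1_i / (sd(t) * sd(x_i))` (reliability), both with
#' the sample (N-1) convention. Zero-variance bins get p1 = pcorr = 0.
#'
#' @param model an [OPLSModel-class].
#' @param X the scaled matrix the model was fitted on.
#' @param pcorrMin,p1Min selection thresholds recorded into the result (see
#'   [selectMarkers()]).
#' @return an [SPlotResult-class].
#' @export
sPlot <- function(model, X, pcorrMin = 0.5, p1Min = 0.05) {
    Xm <- asValues(X)
    centers <- if (is(X, "FeatureMatrix")) binCenters(X) else
        seq_len(ncol(Xm))
    t <- model@t
    n <- length(t)
    tc <- t - mean(t)
    Xc <- sweep(Xm, 2, colMeans(Xm))
    p1 <- crossprod(Xc, tc)[, 1] / (n - 1)
    sdx <- sqrt(colSums(Xc^2) / (n - 1))
    sdt <- sqrt(sum(tc^2) / (n - 1))
    pcorr <- ifelse(sdx > 0, p1 / (sdt * sdx), 0)
    p1[sdx == 0] <- 0
    sel <- abs(pcorr) >= pcorrMin & abs(p1) >= p1Min
    new("SPlotResult", binCenters = centers, p1 = unname(p1),
        pcorr = unname(pcorr), selected = unname(sel),
        thresholds = c(pcorr_min = pcorrMin, p1_min = p1Min))
}

#' Threshold-based marker selection from S-plot statistics
#'
#' Selects bins with `|pcorr| >= pcorrMin` and `|p1| >= p1Min` and splits
#' them by sign: under the cow = -1 encoding the negative-sign list is
#' cow-associated, the positive-sign list belongs to the other group.
#' Thresholds are inclusive, so tabulated statistics sitting exactly on a
#' threshold (e.g. p1 = 0.05) are selected.
#'
#' @param s an [SPlotResult-class], or a data.frame with columns p1 and
#'   pcorr plus a bin label column (e.g. the bundled marker table).
#' @param pcorrMin,p1Min selection thresholds (>= 0).
#' @return list with elements `negative` and `positive` (data.frames of
#'   bin, p1, pcorr) and `selected` (logical over all bins).
#' @export
#' @examples
#' sel <- selectMarkers(loadMarkerTable())
#' nrow(sel$negative)  # 23 cow-associated markers
selectMarkers <- function(s, pcorrMin = 0.5, p1Min = 0.05) {
    stopifnot(pcorrMin >= 0, p1Min >= 0)
    if (is(s, "SPlotResult")) {
        df <- data.frame(bin = s@binCenters, p1 = s@p1, pcorr = s@pcorr)
    } else {
        binCol <- intersect(c("mass_bin", "bin"), names(s))[1]
        df <- data.frame(bin = s[[binCol]], p1 = s$p1, pcorr = s$pcorr)
    }
    sel <- abs(df$pcorr) >= pcorrMin & abs(df$p1) >= p1Min
    list(negative = df[sel & df$p1 < 0, , drop = FALSE],
         positive = df[sel & df$p1 > 0, , drop = FALSE],
         selected = sel)
}

#' Regression coefficients of an OPLS-DA model
#'
#' Coefficients b (in the original bin space) such that predictions via
#' `X b + yMean` reproduce the score-path predictions exactly: the filtered-
#' space coefficient `w c` is pulled back through the orthogonal deflations.
#'
#' @param model an [OPLSModel-class].
#' @return numeric coefficient vector, one entry per bin.
#' @export
oplsCoefficients <- function(model) {
    b <- model@w * model@c
    for (j in rev(seq_len(model@nOrth)))
        b <- b - model@wOrth[, j] * sum(model@pOrth[, j] * b)
    b
}
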