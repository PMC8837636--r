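#' @include oplsda.R
NULL

writeMat <- function(m, path) {
    write.table(m, path, sep = "\t", row.names = FALSE, col.names = FALSE)
    invisible(path)
}
readMat <- function(path, n, p) {
    m <- as.matrix(read.delim(path, header = FALSE))
    dimnames(m) <- NULL
    stopifnot(nrow(m) == n, ncol(m) == p)
    m
}

#' Save / load fitted models as text archives
#'
#' A fitted [LDAModel-class] or [OPLSModel-class] is stored as a directory
#' of delimited-text matrices plus a JSON manifest recording the scalar
#' slots and matrix shapes, so models survive sessions without any binary
#' serialisation.
#'
#' @param model an [LDAModel-class] or [OPLSModel-class].
#' @param dir archive directory (created; must not already contain a
#'   manifest of the other model kind).
#' @return `saveModel`: invisibly, `dir`; `loadModel`: the restored model.
#' @export
saveModel <- function(model, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    man <- list()
    if (is(model, "LDAModel")) {
        man$kind <- "LDAModel"
        man$classes <- model@classes
        man$outlierSigma <- model@outlierSigma
        man$explained <- model@pca@explained
        writeMat(model@pca@loadings, file.path(dir, "pca_loadings.tsv"))
        writeMat(model@pca@scores, file.path(dir, "pca_scores.tsv"))
        writeMat(matrix(model@pca@columnMeans, 1),
                 file.path(dir, "column_means.tsv"))
        writeMat(model@directions, file.path(dir, "directions.tsv"))
        writeMat(model@classMeans, file.path(dir, "class_means.tsv"))
        writeMat(model@pooledCov, file.path(dir, "pooled_cov.tsv"))
        man$shape <- dim(model@pca@loadings)
    } else if (is(model, "OPLSModel")) {
        man$kind <- "OPLSModel"
        man$yEncoding <- as.list(model@yEncoding)
        man$nOrth <- model@nOrth
        man$c <- model@c
        man$r2y <- model@r2y
        if (!is.na(model@q2y)) man$q2y <- model@q2y
        man$yMean <- model@yMean
        writeMat(matrix(model@w, 1), file.path(dir, "w.tsv"))
        writeMat(matrix(model@p, 1), file.path(dir, "p.tsv"))
        writeMat(matrix(model@t, ncol = 1), file.path(dir, "t.tsv"))
        writeMat(model@wOrth, file.path(dir, "w_orth.tsv"))
        writeMat(model@pOrth, file.path(dir, "p_orth.tsv"))
        writeMat(model@tOrth, file.path(dir, "t_orth.tsv"))
        man$shape <- c(length(model@w), length(model@t))
    } else stop("unsupported model class: ", class(model))
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    if (identical(man$kind, "LDAModel")) {
        p <- man$shape[1]; k <- man$shape[2]
        loadings <- readMat(file.path(dir, "pca_loadings.tsv"), p, k)
        scores <- as.matrix(read.delim(file.path(dir, "pca_scores.tsv"),
                                       header = FALSE))
        dimnames(scores) <- NULL
        pca <- new("PCAModel", loadings = loadings, scores = scores,
                   explained = as.numeric(man$explained), q2 = numeric(),
                   columnMeans = drop(readMat(
                       file.path(dir, "column_means.tsv"), 1, p)))
        directions <- as.matrix(read.delim(file.path(dir, "directions.tsv"),
                                           header = FALSE))
        dimnames(directions) <- NULL
        nAxes <- ncol(directions)
        new("LDAModel", pca = pca, directions = directions,
            classMeans = readMat(file.path(dir, "class_means.tsv"),
                                 length(man$classes), nAxes),
            pooledCov = readMat(file.path(dir, "pooled_cov.tsv"), nAxes,
                                nAxes),
            classes = man$classes, outlierSigma = man$outlierSigma)
    } else if (identical(man$kind, "OPLSModel")) {
        p <- man$shape[1]; n <- man$shape[2]
        nOrth <- as.integer(man$nOrth)
        readOrth <- function(f, nr) {
            if (nOrth == 0) return(matrix(0, nr, 0))
            readMat(file.path(dir, f), nr, nOrth)
        }
        new("OPLSModel", yEncoding = unlist(man$yEncoding),
            w = drop(readMat(file.path(dir, "w.tsv"), 1, p)),
            p = drop(readMat(file.path(dir, "p.tsv"), 1, p)),
            t = drop(readMat(file.path(dir, "t.tsv"), n, 1)),
            c = man$c, wOrth = readOrth("w_orth.tsv", p),
            pOrth = readOrth("p_orth.tsv", p),
            tOrth = readOrth("t_orth.tsv", n),
            nOrth = nOrth, r2y = man$r2y,
            q2y = if (is.null(man$q2y)) NA_real_ else as.numeric(man$q2y),
            yMean = man$yMean)
    } else stop("not a recognised model archive: ", dir)
}
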