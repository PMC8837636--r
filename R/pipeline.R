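#' @include simulate.R oplsda.R
NULL

#' Assemble a pipeline configuration
#'
#' Single configuration object driving [runPipeline()]. Every default equals
#' the standard processing value where one exists: grid 100-2000 m/z at
#' 0.2 Da, per-scan intensity limit 1e6 counts, 20% bootstrap holdout,
#' 5-sigma outlier radius and S-plot thresholds |pcorr| >= 0.5,
#' |p1| >= 0.05. The configuration round-trips through YAML
#' ([writePipelineConfig()] / [readPipelineConfig()]).
#'
#' @param seed integer seed; all pipeline randomness flows from it.
#' @param ... overrides of the defaults listed above (see the returned
#'   list's names).
#' @return a named list of class `"desimilk_config"`.
#' @export
pipelineConfig <- function(seed = 1, ...) {
    cfg <- list(
        seed = as.integer(seed),
        grid_low = 100, grid_high = 2000, grid_width = 0.2,
        intensity_limit = 1e6,
        tic_normalise = TRUE,
        scaling = "pareto",
        n_pcs = NA,              # NA = automatic 95% R2X rule
        outlier_sigma = 5,
        holdout_fraction = 0.2, bootstrap_repeats = 25,
        n_orth = 1, q2_folds = 7, n_perm = 100,
        pcorr_min = 0.5, p1_min = 0.05,
        lod_criterion_rate = 0.8, lod_repeats = 10,
        sim = list())
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    structure(cfg, class = c("desimilk_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a configuration from [pipelineConfig()].
#' @param path YAML file path.
#' @return `writePipelineConfig`: invisibly, `path`;
#'   `readPipelineConfig`: the configuration.
#' @export
writePipelineConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, c(list(seed = vals$seed),
                              vals[setdiff(names(vals), "seed")]))
}

#' Run the analysis pipeline
#'
#' Configuration-driven orchestration of the stages: `simulate` writes a
#' synthetic study in the CSV dialect; `preprocess` builds and stores the
#' per-spectrum feature matrix; `classify` runs the bootstrap PCA-LDA
#' species classification; `splot` fits the cow-vs-rest OPLS-DA and exports
#' the S-plot statistics and selected markers; `annotate` matches the
#' selected bins against the bundled marker table; `adulteration` estimates
#' per-base-species limits of detection; `all` runs everything in order.
#' Outputs go under `outDir` (inputs are never mutated) together with a
#' provenance manifest recording the configuration, seed and row/bin counts.
#'
#' @param config a `desimilk_config` from [pipelineConfig()].
#' @param command one of simulate, preprocess, classify, splot, annotate,
#'   adulteration, all.
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of artifact paths.
#' @export
runPipeline <- function(config, command = c("all", "simulate", "preprocess",
                                            "classify", "splot", "annotate",
                                            "adulteration"),
                        outDir = "desimilk_run") {
    command <- match.arg(command)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
        peaks = file.path(outDir, "peaks.csv"),
        manifest = file.path(outDir, "manifest.csv"),
        truth = file.path(outDir, "truth.csv"),
        matrix = file.path(outDir, "feature_matrix.tsv"),
        classification = file.path(outDir, "classification.csv"),
        splot = file.path(outDir, "splot.csv"),
        permutation = file.path(outDir, "permutation_report.csv"),
        markers = file.path(outDir, "selected_markers.csv"),
        annotation = file.path(outDir, "annotation.csv"),
        lod = file.path(outDir, "lod.csv"),
        manifestJson = file.path(outDir, "run_manifest.json"))
    grid <- binGrid(config$grid_low, config$grid_high, config$grid_width)
    prov <- list(seed = config$seed, config = unclass(config),
                 package_version = as.character(utils::packageVersion("desimilk")))
    stages <- if (command == "all")
        c("simulate", "preprocess", "classify", "splot", "annotate",
          "adulteration") else command
    for (stage in stages) switch(stage,
        simulate = {
            sim <- do.call(simConfig, c(list(seed = config$seed),
                                        config$sim))
            study <- simulateStudy(sim)
            writePeakLists(study$samples, paths$peaks, paths$manifest)
            write.csv(study$truth, paths$truth, row.names = FALSE)
        },
        preprocess = {
            if (!file.exists(paths$peaks))
                stop("preprocess: no peaks file; run 'simulate' first or place inputs in outDir")
            records <- readPeakLists(paths$peaks, paths$manifest)
            m <- buildFeatureMatrix(records, grid, config$intensity_limit,
                                    perSpectrum = TRUE)
            if (config$tic_normalise) m <- ticNormalize(m)
            writeFeatureMatrix(m, paths$matrix)
        },
        classify = {
            m <- requireMatrix(paths$matrix, "classify")
            pure <- m@meta$species != "mixture"
            msub <- subsetRows(m, pure)
            res <- bootstrapCCR(msub,
                                holdoutFraction = config$holdout_fraction,
                                repeats = config$bootstrap_repeats,
                                seed = config$seed,
                                outlierSigma = config$outlier_sigma,
                                nPcs = if (is.na(config$n_pcs)) NULL else
                                    config$n_pcs)
            write.csv(res@assignments, paths$classification,
                      row.names = FALSE)
            prov$ccr_excluding_outliers <- res@ccrExcludingOutliers
            prov$ccr_including_outliers <- res@ccrIncludingOutliers
        },
        splot = {
            m <- requireMatrix(paths$matrix, "splot")
            pure <- m@meta$species != "mixture"
            msub <- averageBySample(subsetRows(m, pure))
            msub <- scaleMatrix(msub, config$scaling)
            y <- encodeY(msub@meta$species)
            fit <- fitOPLS(msub, y, config$n_orth)
            sp <- sPlot(fit, msub, config$pcorr_min, config$p1_min)
            sel <- selectMarkers(sp, config$pcorr_min, config$p1_min)
            write.csv(data.frame(bin_center = sp@binCenters, p1 = sp@p1,
                                 pcorr = sp@pcorr, selected = sp@selected,
                                 sign_group = ifelse(sp@p1 < 0, "negative",
                                                     "positive")),
                      paths$splot, row.names = FALSE)
            markerRows <- do.call(rbind, Filter(nrow, list(
                if (nrow(sel$negative)) cbind(sel$negative,
                                              group = "negative"),
                if (nrow(sel$positive)) cbind(sel$positive,
                                              group = "positive"))))
            if (is.null(markerRows))
                markerRows <- data.frame(bin = numeric(), p1 = numeric(),
                                         pcorr = numeric(),
                                         group = character())
            write.csv(markerRows, paths$markers, row.names = FALSE)
            perm <- permutationTest(featureValues(msub), y,
                                    nOrth = config$n_orth,
                                    nPerm = config$n_perm,
                                    folds = config$q2_folds,
                                    seed = config$seed)
            write.csv(data.frame(label_correlation = perm@permCor,
                                 r2y = perm@permR2Y, q2 = perm@permQ2,
                                 original_r2y = perm@origR2Y,
                                 original_q2 = perm@origQ2,
                                 valid = perm@valid),
                      paths$permutation, row.names = FALSE)
            prov$r2y <- fit@r2y
            prov$permutation_valid <- perm@valid
        },
        annotate = {
            if (!file.exists(paths$markers))
                stop("annotate: no selected-markers file; run 'splot' first")
            sel <- read.csv(paths$markers)
            tab <- loadMarkerTable()
            ann <- do.call(rbind, lapply(sel$bin, function(b) {
                hits <- tab[abs(tab$mass_bin - b) < grid@width / 4, ,
                            drop = FALSE]
                if (!nrow(hits)) return(NULL)
                data.frame(bin = b, lipid_name = hits$lipid_name,
                           lm_id = hits$lm_id, milk_type = hits$milk_type)
            }))
            if (is.null(ann)) ann <- data.frame(bin = numeric(),
                                                lipid_name = character(),
                                                lm_id = character(),
                                                milk_type = character())
            write.csv(ann, paths$annotation, row.names = FALSE)
        },
        adulteration = {
            m <- requireMatrix(paths$matrix, "adulteration")
            if (!file.exists(paths$truth))
                stop("adulteration: no truth table; run 'simulate' first")
            truth <- read.csv(paths$truth)
            rows <- list()
            for (base in intersect(unique(truth$base_species),
                                   c("goat", "camel", "oat", "soya"))) {
                ids <- truth$sample_id[truth$series == paste0("mix_", base)]
                if (!length(ids)) next
                msub <- subsetRows(m, m@meta$sample_id %in% ids)
                lod <- estimateLOD(msub,
                                   criterionRate = config$lod_criterion_rate,
                                   repeats = config$lod_repeats,
                                   seed = config$seed)
                rows[[base]] <- cbind(base_species = base, lod@perLevel,
                                      ccr = lod@ccr,
                                      lod_flag = !is.na(lod@lod) &
                                          lod@perLevel$level == lod@lod)
            }
            write.csv(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                      paths$lod, row.names = FALSE)
        })
    prov$written <- Filter(file.exists, unlist(paths))
    jsonlite::write_json(prov, paths$manifestJson, auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}

requireMatrix <- function(path, stage) {
    if (!file.exists(path))
        stop(stage, ": no feature matrix; run 'preprocess' first")
    readFeatureMatrix(path)
}

## Row subset preserving metadata and state.
subsetRows <- function(m, i) {
    initialize(m, values = m@values[i, , drop = FALSE],
               meta = m@meta[i, , drop = FALSE])
}

## Collapse a per-spectrum matrix to per-sample averaged rows.
averageBySample <- function(m) {
    sid <- m@meta$sample_id
    avg <- rowsum(m@values, sid) / as.vector(table(sid)[sort(unique(sid))])
    meta <- m@meta[match(rownames(avg), sid), , drop = FALSE]
    meta$scan <- NA_integer_
    rownames(meta) <- NULL
    initialize(m, values = avg, meta = meta)
}
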