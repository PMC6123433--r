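## Orchestration: staged pipeline runs from a structured (YAML/list)
## config, with a JSON run manifest recording seeds, paths and the
## package version so every run is re-executable.

#' Read / write an RGB image
#'
#' Thin wrappers over the png/tiff packages returning/accepting the
#' package's `H x W x 3` numeric arrays in `[0, 255]`.
#'
#' @param path file ending in `.png`, `.tif` or `.tiff`.
#' @param rgb numeric array `H x W x 3` in `[0, 255]`.
#' @return `readRGBImage()` the array; `writeRGBImage()` `path`,
#'   invisibly.
#' @export
readRGBImage <- function(path) {
    ext <- tolower(tools::file_ext(path))
    img <- switch(ext,
        png = {
            if (!requireNamespace("png", quietly = TRUE))
                stop("reading PNG requires the png package", call. = FALSE)
            png::readPNG(path)
        },
        tif = , tiff = {
            if (!requireNamespace("tiff", quietly = TRUE))
                stop("reading TIFF requires the tiff package", call. = FALSE)
            tiff::readTIFF(path)
        },
        stop("unsupported image format: ", ext, call. = FALSE))
    if (length(dim(img)) == 2L)
        img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    img[, , 1:3, drop = FALSE] * 255
}

#' @rdname readRGBImage
#' @export
writeRGBImage <- function(rgb, path) {
    ext <- tolower(tools::file_ext(path))
    x <- pmin(pmax(rgb / 255, 0), 1)
    switch(ext,
        png = png::writePNG(x, path),
        tif = , tiff = tiff::writeTIFF(x, path),
        stop("unsupported image format: ", ext, call. = FALSE))
    invisible(path)
}

.cfgGet <- function(config, stage, key, required = TRUE) {
    v <- config[[stage]][[key]]
    if (is.null(v) && required)
        stop(sprintf("stage '%s' is missing required config field '%s'",
                     stage, key), call. = FALSE)
    v
}

#' Run a staged pipeline from a config
#'
#' Executes the requested stage chain (`simulate`, `segment`,
#' `encode`, `train`, `evaluate`) in order, failing fast with
#' stage-named errors when an upstream artifact is missing, and writes
#' a JSON run manifest (command, config hash, seeds, paths,
#' timestamps, package version) plus per-stage outputs into
#' `out_dir`.
#'
#' @param config a YAML file path or a named list with fields `seed`,
#'   `out_dir`, `stages` (character vector) and one optional sub-list
#'   per stage (`simulate`: `n_per_class` plus [generatorConfig()]
#'   overrides; `segment`: `input`, `resolution`; `train`:
#'   [trainConfig()] overrides and `train_fraction`; `evaluate`: none).
#' @return invisibly, a list with the run state (`snapshots`,
#'   `features`, `model`, `scores`, `manifestPath`).
#' @export
runPipeline <- function(config) {
    configPath <- NA_character_
    if (is.character(config) && length(config) == 1L) {
        configPath <- config
        config <- yaml::read_yaml(config)
    }
    stopifnot(is.list(config))
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outDir <- if (is.null(config$out_dir)) stop("config needs 'out_dir'",
                                                call. = FALSE)
              else config$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stages <- config$stages
    if (is.null(stages)) stop("config needs 'stages'", call. = FALSE)
    state <- list(snapshots = NULL, features = NULL, model = NULL,
                  split = NULL, scores = NULL)
    outputs <- character(0)
    for (stage in stages) {
        switch(stage,
        simulate = {
            nPer <- .cfgGet(config, "simulate", "n_per_class")
            gcArgs <- config$simulate
            gcArgs$n_per_class <- NULL
            gc <- do.call(generatorConfig, gcArgs)
            state$snapshots <- generateCohort(nPer, gc, seed = seed)
            dir.create(file.path(outDir, "snapshots"), showWarnings = FALSE)
            for (s in state$snapshots) {
                f <- file.path(outDir, "snapshots",
                               paste0(s@specimenId, ".xml"))
                writeSnapshotXML(s, f)
            }
            outputs <- c(outputs, file.path(outDir, "snapshots"))
        },
        segment = {
            input <- .cfgGet(config, "segment", "input")
            resolution <- .cfgGet(config, "segment", "resolution")
            rgb <- readRGBImage(input)
            snap <- segmentImage(rgb, nativeRes = resolution,
                                 specimenId = tools::file_path_sans_ext(
                                     basename(input)))
            state$snapshots <- c(state$snapshots, list(snap))
            f <- file.path(outDir, paste0(snap@specimenId, ".xml"))
            writeSnapshotXML(snap, f)
            outputs <- c(outputs, f)
        },
        encode = {
            if (is.null(state$snapshots))
                stop("stage 'encode': no snapshots; run 'simulate' or 'segment' first",
                     call. = FALSE)
            state$features <- lapply(state$snapshots, encodeSnapshot)
        },
        train = {
            if (is.null(state$features))
                stop("stage 'train': no feature images; run 'encode' first",
                     call. = FALSE)
            tcArgs <- config$train
            trainFraction <- tcArgs$train_fraction
            if (is.null(trainFraction)) trainFraction <- 0.6
            tcArgs$train_fraction <- NULL
            if (is.null(tcArgs$seed)) tcArgs$seed <- seed
            tc <- do.call(trainConfig, tcArgs)
            state$split <- splitCohort(state$features, trainFraction,
                                       seed = seed, stratify = TRUE)
            model <- buildNetwork(networkConfig(), seed = seed)
            state$model <- trainNetwork(model,
                                        state$features[state$split$train],
                                        config = tc)
            modelPath <- file.path(outDir, "model.rds")
            saveRDS(state$model, modelPath)
            outputs <- c(outputs, modelPath)
        },
        evaluate = {
            if (is.null(state$model))
                stop("stage 'evaluate': no model; run 'train' first",
                     call. = FALSE)
            testIdx <- if (!is.null(state$split)) state$split$test
                       else seq_along(state$features)
            scores <- scoreSpecimens(state$model, state$features[testIdx])
            scorePath <- file.path(outDir, "scores.csv")
            write.csv(scores, scorePath, row.names = FALSE)
            state$scores <- scores
            if (length(unique(scores$label[!is.na(scores$label)])) == 2L) {
                auc <- rocAuc(scores$score, scores$label)
                message(sprintf("evaluate: test AUC = %.3f (n = %d)",
                                auc, nrow(scores)))
            }
            outputs <- c(outputs, scorePath)
        },
        stop("unknown stage: ", stage, call. = FALSE))
    }
    manifest <- list(
        command = paste("runPipeline:", paste(stages, collapse = " -> ")),
        config_hash = if (!is.na(configPath))
            unname(tools::md5sum(configPath)) else NA,
        seed = seed,
        outputs = outputs,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        package_version = as.character(utils::packageVersion("nucleomorph")))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE)
    state$manifestPath <- manifestPath
    invisible(state)
}
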