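# Plain-text serialisation: session CSVs with a JSON manifest, tracks CSV,
# transforms JSON, configs YAML.

.contentHash <- function(txt) {
    # tiny stable polynomial content hash for manifests
    h <- 17
    for (b in utf8ToInt(txt))
        h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

#' Write / read one session cloud as CSV
#'
#' Columns: `neuron_id`, `week`, `x_um`, `y_um`, `z_um`, `tangle`,
#' `fiducial`. Bounds travel in the directory manifest (see
#' [writeSessionClouds()]) or are recomputed from the coordinate range.
#'
#' @param cloud a [SessionCloud-class].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writeSessionCloud <- function(cloud, path) {
    X <- coords(cloud)
    df <- data.frame(neuron_id = neuronIds(cloud), week = imagingWeek(cloud),
        x_um = X[, 1], y_um = X[, 2], z_um = X[, 3],
        tangle = as.integer(tangleFlags(cloud)),
        fiducial = as.integer(fiducialFlags(cloud)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeSessionCloud
#' @param bounds optional 3 x 2 bounds; default from the coordinate range.
#' @export
readSessionCloud <- function(path, bounds = NULL) {
    df <- utils::read.csv(path)
    SessionCloud(as.matrix(df[, c("x_um", "y_um", "z_um")]),
        neuronId = df$neuron_id, tangle = df$tangle > 0,
        fiducial = df$fiducial > 0, week = df$week[1], bounds = bounds)
}

#' Write a simulated experiment to a directory
#'
#' Writes `week_<w>.csv` per session, `truth.json` (fates, designated
#' neighbours, true transforms), `config.yaml`, and `manifest.json` (seed,
#' bounds, week files, config hash). Byte-identical for identical configs.
#'
#' @param sim output of [simulateLongitudinal()].
#' @param dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
writeSessionClouds <- function(sim, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (cl in sim$sessions) {
        f <- sprintf("week_%d.csv", imagingWeek(cl))
        writeSessionCloud(cl, file.path(dir, f))
        files <- c(files, f)
    }
    cfg <- sim$truth$config
    cfgClean <- cfg[!vapply(cfg, is.null, TRUE)]
    cfgClean$sessionTransforms <- NULL
    cfgTxt <- yaml::as.yaml(cfgClean)
    writeLines(cfgTxt, file.path(dir, "config.yaml"))
    truth <- sim$truth
    jsonlite::write_json(list(
        fates = truth$fates,
        neighbors = truth$neighbors,
        transforms = lapply(truth$transforms, .transformToList)),
        file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
    manifest <- list(seed = cfg$seed, nWeeks = cfg$nWeeks,
        bounds = cfg$bounds, files = files, configHash = .contentHash(cfgTxt))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Read a directory of weekly session CSVs
#'
#' @param dir directory written by [writeSessionClouds()] (or containing
#'   `week_<w>.csv` files; a `manifest.json`, when present, supplies the
#'   field bounds).
#' @return list of [SessionCloud-class] in week order.
#' @export
readSessionClouds <- function(dir) {
    mf <- file.path(dir, "manifest.json")
    bounds <- NULL
    if (file.exists(mf)) {
        man <- jsonlite::read_json(mf, simplifyVector = TRUE)
        bounds <- cbind(lo = c(0, 0, 0), hi = man$bounds)
    }
    files <- sort(list.files(dir, pattern = "^week_\\d+\\.csv$"))
    if (!length(files)) stop("no week_<w>.csv files in ", dir)
    wk <- as.integer(sub("^week_(\\d+)\\.csv$", "\\1", files))
    lapply(order(wk), function(i)
        readSessionCloud(file.path(dir, files[i]), bounds = bounds))
}

.transformToList <- function(tf) {
    list(scale = tf@scale, rotation = as.vector(t(tf@rotation)),
         translation = tf@translation)
}

#' Write / read a similarity transform as JSON
#'
#' Serialised as scale, 9 row-major rotation entries, and translation.
#'
#' @param transform a [SimilarityTransform-class].
#' @param path file path.
#' @return the path invisibly; `readTransform()` the transform.
#' @export
writeTransform <- function(transform, path) {
    jsonlite::write_json(.transformToList(transform), path,
        auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    SimilarityTransform(x$scale, matrix(x$rotation, 3, 3, byrow = TRUE),
        x$translation)
}

#' Write / read tracks as CSV
#'
#' Wide schema of [as.data.frame.NeuronTrackSet()].
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param path CSV path.
#' @return the path invisibly; `readTracks()` the track set.
#' @export
writeTracks <- function(tracks, path) {
    utils::write.csv(as.data.frame(tracks), path, row.names = FALSE,
        quote = FALSE)
    invisible(path)
}

#' @rdname writeTracks
#' @export
readTracks <- function(path) {
    df <- utils::read.csv(path)
    W <- sum(grepl("^x_w\\d+$", names(df)))
    n <- nrow(df)
    pos <- array(NA_real_, c(n, 3, W))
    for (w in seq_len(W)) {
        pos[, 1, w] <- df[[sprintf("x_w%d", w)]]
        pos[, 2, w] <- df[[sprintf("y_w%d", w)]]
        pos[, 3, w] <- df[[sprintf("z_w%d", w)]]
    }
    new("NeuronTrackSet", positions = pos, trackId = as.integer(df$track_id),
        sourceId = as.integer(df$source_id), fate = as.character(df$fate),
        deathWeek = as.integer(df$death_week),
        tangleOnset = as.integer(df$tangle_onset),
        firstWeek = as.integer(df$first_week), nWeeks = as.integer(W))
}
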