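#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @aliases coords,SessionCloud-method
setMethod("coords", "SessionCloud", function(x) x@coords)

#' @rdname accessors
setMethod("neuronIds", "SessionCloud", function(x) x@neuronId)

#' @rdname accessors
setMethod("tangleFlags", "SessionCloud", function(x) x@tangle)

#' @rdname accessors
setMethod("fiducialFlags", "SessionCloud", function(x) x@fiducial)

#' @rdname accessors
setMethod("imagingWeek", "SessionCloud", function(x) x@week)

#' @rdname accessors
setMethod("cloudBounds", "SessionCloud", function(x) x@bounds)

#' @describeIn SessionCloud-class number of nuclei in the session.
#' @param x a SessionCloud.
setMethod("length", "SessionCloud", function(x) nrow(x@coords))

#' @describeIn SessionCloud-class subset nuclei by index or logical mask.
#' @param i index vector.
#' @param j,...,drop ignored.
setMethod("[", "SessionCloud", function(x, i, j, ..., drop = FALSE) {
    initialize(x, coords = x@coords[i, , drop = FALSE],
               neuronId = x@neuronId[i], tangle = x@tangle[i],
               fiducial = x@fiducial[i])
})

setMethod("show", "SessionCloud", function(object) {
    b <- object@bounds
    cat(sprintf(
        "SessionCloud: %d nuclei, week %d\n", length(object), object@week))
    cat(sprintf("  field: %.0f x %.0f x %.0f um (origin %.0f, %.0f, %.0f)\n",
        b[1, 2] - b[1, 1], b[2, 2] - b[2, 1], b[3, 2] - b[3, 1],
        b[1, 1], b[2, 1], b[3, 1]))
    cat(sprintf("  tangle-bearing: %d   fiducials: %d\n",
        sum(object@tangle), sum(object@fiducial)))
    invisible(object)
})

#' @describeIn SimilarityTransform-class scale slot.
#' @param x a SimilarityTransform.
#' @export
transformScale <- function(x) x@scale

#' @describeIn SimilarityTransform-class rotation slot.
#' @export
transformRotation <- function(x) x@rotation

#' @describeIn SimilarityTransform-class translation slot.
#' @export
transformTranslation <- function(x) x@translation

setMethod("show", "SimilarityTransform", function(object) {
    ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
    cat(sprintf(
        "SimilarityTransform: scale %.6g, rotation %.3f deg, t = (%.3g, %.3g, %.3g) um\n",
        object@scale, ang * 180 / pi, object@translation[1],
        object@translation[2], object@translation[3]))
    invisible(object)
})

#' @rdname accessors
setMethod("fates", "NeuronTrackSet", function(x) x@fate)

#' @rdname accessors
setMethod("deathWeeks", "NeuronTrackSet", function(x) x@deathWeek)

#' @rdname accessors
setMethod("tangleOnsets", "NeuronTrackSet", function(x) x@tangleOnset)

#' @rdname accessors
setMethod("everTangled", "NeuronTrackSet", function(x) !is.na(x@tangleOnset))

#' @rdname accessors
setMethod("firstWeeks", "NeuronTrackSet", function(x) x@firstWeek)

#' @rdname accessors
setMethod("trackIds", "NeuronTrackSet", function(x) x@trackId)

#' @rdname accessors
setMethod("trackPositions", "NeuronTrackSet", function(x) x@positions)

#' @describeIn NeuronTrackSet-class number of tracks.
#' @param x a NeuronTrackSet.
setMethod("length", "NeuronTrackSet", function(x) length(x@trackId))

#' @describeIn NeuronTrackSet-class subset tracks.
#' @param i index vector.
#' @param j,...,drop ignored.
setMethod("[", "NeuronTrackSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, positions = x@positions[i, , , drop = FALSE],
               trackId = x@trackId[i], sourceId = x@sourceId[i],
               fate = x@fate[i], deathWeek = x@deathWeek[i],
               tangleOnset = x@tangleOnset[i], firstWeek = x@firstWeek[i])
})

setMethod("show", "NeuronTrackSet", function(object) {
    tab <- table(factor(object@fate,
        levels = c("persisted", "disappeared", "ambiguous")))
    cat(sprintf("NeuronTrackSet: %d tracks over %d weeks\n",
        length(object), object@nWeeks))
    cat(sprintf("  persisted %d, disappeared %d, ambiguous %d, ever-tangled %d\n",
        tab[["persisted"]], tab[["disappeared"]], tab[["ambiguous"]],
        sum(everTangled(object))))
    invisible(object)
})

#' Flatten a NeuronTrackSet to a wide data frame
#'
#' One row per track with columns `track_id`, `source_id`, `fate`,
#' `death_week`, `tangle_onset`, `first_week`, then `x_w<k>`, `y_w<k>`,
#' `z_w<k>` per week (NA where absent). This is the on-disk CSV schema used
#' by [writeTracks()].
#'
#' @param x a [NeuronTrackSet-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame.
#' @export
as.data.frame.NeuronTrackSet <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
    W <- x@nWeeks
    out <- data.frame(track_id = x@trackId, source_id = x@sourceId,
        fate = x@fate, death_week = x@deathWeek,
        tangle_onset = x@tangleOnset, first_week = x@firstWeek)
    for (w in seq_len(W)) {
        out[[sprintf("x_w%d", w)]] <- x@positions[, 1, w]
        out[[sprintf("y_w%d", w)]] <- x@positions[, 2, w]
        out[[sprintf("z_w%d", w)]] <- x@positions[, 3, w]
    }
    out
}

setMethod("as.data.frame", "NeuronTrackSet",
    function(x, row.names = NULL, optional = FALSE, ...)
        as.data.frame.NeuronTrackSet(x, row.names, optional, ...))
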