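#' @import methods
NULL

#' SessionCloud: one imaging session's nucleus centroids
#'
#' A `SessionCloud` holds the 3D centroids (in micrometres) of all nucleus
#' objects segmented from one imaging session, together with per-nucleus
#' labels: a tangle flag (whether a neurofibrillary tangle is associated with
#' the neuron that session) and a fiducial flag (whether the neuron serves as
#' a registration landmark). The `bounds` slot records the imaged field as an
#' axis-aligned box; points are normally inside it but may fall outside after
#' a transform has been applied.
#'
#' @slot coords numeric matrix, n x 3, columns x/y/z in micrometres.
#' @slot neuronId integer vector of per-nucleus identifiers, unique within
#'   the session.
#' @slot tangle logical vector, tangle-bearing flag per nucleus.
#' @slot fiducial logical vector, fiducial-landmark flag per nucleus.
#' @slot week integer scalar, 1-based imaging week of the session.
#' @slot bounds numeric 3 x 2 matrix (rows x/y/z, columns lo/hi) giving the
#'   axis-aligned imaged field in micrometres.
#'
#' @seealso [SessionCloud()] for the constructor, [coords()],
#'   [tangleFlags()], [fiducialFlags()], [cloudBounds()], [imagingWeek()].
#' @name SessionCloud-class
#' @rdname SessionCloud-class
#' @exportClass SessionCloud
setClass("SessionCloud",
    representation(
        coords = "matrix",
        neuronId = "integer",
        tangle = "logical",
        fiducial = "logical",
        week = "integer",
        bounds = "matrix"
    )
)

setValidity("SessionCloud", function(object) {
    msg <- character()
    n <- nrow(object@coords)
    if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
        msg <- c(msg, "'coords' must be a numeric matrix with 3 columns")
    if (n > 0 && any(!is.finite(object@coords)))
        msg <- c(msg, "'coords' must be finite")
    if (length(object@neuronId) != n)
        msg <- c(msg, "'neuronId' length must equal nrow(coords)")
    if (anyDuplicated(object@neuronId))
        msg <- c(msg, "'neuronId' must be unique within a session")
    if (length(object@tangle) != n)
        msg <- c(msg, "'tangle' length must equal nrow(coords)")
    if (length(object@fiducial) != n)
        msg <- c(msg, "'fiducial' length must equal nrow(coords)")
    if (length(object@week) != 1L || is.na(object@week) || object@week < 1L)
        msg <- c(msg, "'week' must be a single integer >= 1")
    b <- object@bounds
    if (!is.numeric(b) || !identical(dim(b), c(3L, 2L)))
        msg <- c(msg, "'bounds' must be a numeric 3 x 2 matrix")
    else if (any(b[, 2] <= b[, 1]))
        msg <- c(msg, "'bounds' must satisfy hi > lo on every axis")
    if (length(msg)) msg else TRUE
})

#' Construct a SessionCloud
#'
#' @param coords numeric n x 3 matrix of centroids in micrometres.
#' @param neuronId integer identifiers (default `seq_len(nrow(coords))`).
#' @param tangle,fiducial logical flags per nucleus (default all `FALSE`).
#' @param week imaging week (default 1).
#' @param bounds 3 x 2 bounds matrix; if `NULL`, taken from the coordinate
#'   range (with a tiny pad so degenerate clouds remain valid).
#' @return A [SessionCloud-class] object.
#' @examples
#' cl <- SessionCloud(matrix(runif(30, 0, 100), ncol = 3),
#'                    bounds = cbind(lo = c(0, 0, 0), hi = c(100, 100, 100)))
#' cl
#' @export
SessionCloud <- function(coords, neuronId = seq_len(nrow(coords)),
                         tangle = logical(nrow(coords)),
                         fiducial = logical(nrow(coords)),
                         week = 1L, bounds = NULL) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    colnames(coords) <- c("x", "y", "z")
    if (is.null(bounds)) {
        if (nrow(coords) == 0)
            stop("'bounds' must be given for an empty cloud")
        rng <- apply(coords, 2, range)
        bounds <- cbind(lo = rng[1, ] - 1e-9, hi = rng[2, ] + 1e-9)
    }
    bounds <- as.matrix(bounds)
    dimnames(bounds) <- list(c("x", "y", "z"), c("lo", "hi"))
    new("SessionCloud", coords = coords, neuronId = as.integer(neuronId),
        tangle = as.logical(tangle), fiducial = as.logical(fiducial),
        week = as.integer(week), bounds = bounds)
}

#' SimilarityTransform: uniform scale + proper rotation + translation
#'
#' Maps a point p to `scale * rotation %*% p + translation`. The rotation is
#' constrained to be proper (orthonormal, determinant +1): reflections are
#' not representable, matching the physical model of repositioning the same
#' tissue under the objective with possible small isotropic stretch.
#'
#' @slot scale positive scalar.
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric 3-vector, micrometres.
#' @seealso [SimilarityTransform()], [estimateTransform()],
#'   [applyTransform()], [invertTransform()].
#' @name SimilarityTransform-class
#' @rdname SimilarityTransform-class
#' @exportClass SimilarityTransform
setClass("SimilarityTransform",
    representation(scale = "numeric", rotation = "matrix",
                   translation = "numeric")
)

setValidity("SimilarityTransform", function(object) {
    msg <- character()
    if (length(object@scale) != 1L || !is.finite(object@scale) ||
        object@scale <= 0)
        msg <- c(msg, "'scale' must be a single positive number")
    R <- object@rotation
    if (!identical(dim(R), c(3L, 3L)))
        msg <- c(msg, "'rotation' must be 3 x 3")
    else {
        if (max(abs(crossprod(R) - diag(3))) > 1e-9)
            msg <- c(msg, "'rotation' must be orthonormal within 1e-9")
        if (abs(det(R) - 1) > 1e-9)
            msg <- c(msg, "'rotation' must have determinant +1 (no reflection)")
    }
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
        msg <- c(msg, "'translation' must be a finite 3-vector")
    if (length(msg)) msg else TRUE
})

#' Construct a SimilarityTransform
#'
#' @param scale positive scalar.
#' @param rotation 3 x 3 proper rotation matrix (default identity).
#' @param translation numeric 3-vector in micrometres (default zero).
#' @return A [SimilarityTransform-class] object.
#' @examples
#' identityTransform()
#' SimilarityTransform(1.02, rotationAboutZ(5 * pi / 180), c(3, -2, 1))
#' @export
SimilarityTransform <- function(scale = 1, rotation = diag(3),
                                translation = c(0, 0, 0)) {
    new("SimilarityTransform", scale = as.numeric(scale),
        rotation = as.matrix(rotation), translation = as.numeric(translation))
}

#' @rdname SimilarityTransform
#' @export
identityTransform <- function() SimilarityTransform()

#' Rotation matrix about the z axis
#'
#' @param theta angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutZ <- function(theta) {
    c_ <- cos(theta); s_ <- sin(theta)
    matrix(c(c_, s_, 0, -s_, c_, 0, 0, 0, 1), 3, 3)
}

#' NeuronTrackSet: longitudinal identities of tracked neurons
#'
#' One row (track) per neuron linked across registered sessions. Positions
#' are stored as an n x 3 x nWeeks array with `NA` where the neuron was not
#' observed. Fates are `"persisted"` (observed in the final session with no
#' gap), `"disappeared"` (absent from some week through the final session;
#' `deathWeek` is the first absent week), or `"ambiguous"` (transiently
#' unobserved and later resighted; excluded from death counts).
#'
#' @slot positions numeric array n x 3 x nWeeks, micrometres, NA when absent.
#' @slot trackId integer track identifiers.
#' @slot sourceId integer identifier of the originating nucleus in its first
#'   session (bookkeeping for simulations; NA when unknown).
#' @slot fate character, one of persisted/disappeared/ambiguous.
#' @slot deathWeek integer, first week of absence for disappeared tracks,
#'   otherwise NA.
#' @slot tangleOnset integer, first week the track is tangle-bearing, NA if
#'   never.
#' @slot firstWeek integer, first week the track was observed.
#' @slot nWeeks integer scalar, number of sessions.
#' @seealso [buildTracks()], [fates()], [deathWeeks()], [tangleOnsets()],
#'   [everTangled()], [trackPositions()].
#' @name NeuronTrackSet-class
#' @rdname NeuronTrackSet-class
#' @exportClass NeuronTrackSet
setClass("NeuronTrackSet",
    representation(
        positions = "array",
        trackId = "integer",
        sourceId = "integer",
        fate = "character",
        deathWeek = "integer",
        tangleOnset = "integer",
        firstWeek = "integer",
        nWeeks = "integer"
    )
)

setValidity("NeuronTrackSet", function(object) {
    msg <- character()
    d <- dim(object@positions)
    n <- length(object@trackId)
    W <- object@nWeeks
    if (length(d) != 3L || d[2] != 3L)
        msg <- c(msg, "'positions' must be an n x 3 x nWeeks array")
    else {
        if (d[1] != n) msg <- c(msg, "positions rows must match trackId")
        if (d[3] != W) msg <- c(msg, "positions depth must match nWeeks")
    }
    for (nm in c("sourceId", "fate", "deathWeek", "tangleOnset", "firstWeek"))
        if (length(slot(object, nm)) != n)
            msg <- c(msg, sprintf("'%s' length must match trackId", nm))
    if (!all(object@fate %in% c("persisted", "disappeared", "ambiguous")))
        msg <- c(msg, "unknown fate label")
    bad <- object@fate == "disappeared" &
        (is.na(object@deathWeek) | object@deathWeek < 2L |
         object@deathWeek > W)
    if (any(bad))
        msg <- c(msg, "disappeared tracks need deathWeek in [2, nWeeks]")
    if (length(d) == 3L && d[1] == n && n > 0) {
        # a disappeared track must be observed at deathWeek-1 and absent after
        for (i in which(object@fate == "disappeared")) {
            w <- object@deathWeek[i]
            if (anyNA(object@positions[i, , w - 1L]))
                msg <- c(msg, "disappeared track absent at deathWeek-1")
            if (any(!is.na(object@positions[i, , seq.int(w, W)])))
                msg <- c(msg, "disappeared track observed at/after deathWeek")
        }
    }
    if (length(msg)) unique(msg) else TRUE
})
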