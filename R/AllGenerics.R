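#' @include AllClasses.R
NULL

#' Accessors for SessionCloud and NeuronTrackSet
#'
#' Slot access goes through these accessors rather than `@`.
#'
#' @param x a [SessionCloud-class] or [NeuronTrackSet-class] object.
#' @return `coords()` the n x 3 coordinate matrix; `neuronIds()` integer ids;
#'   `tangleFlags()`/`fiducialFlags()` logical vectors; `imagingWeek()` the
#'   session week; `cloudBounds()` the 3 x 2 bounds matrix; `fates()`
#'   character fates; `deathWeeks()`/`tangleOnsets()`/`firstWeeks()` integer
#'   vectors; `everTangled()` logical; `trackIds()` integer ids;
#'   `trackPositions()` the n x 3 x nWeeks position array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname accessors
#' @export
setGeneric("tangleFlags", function(x) standardGeneric("tangleFlags"))

#' @rdname accessors
#' @export
setGeneric("fiducialFlags", function(x) standardGeneric("fiducialFlags"))

#' @rdname accessors
#' @export
setGeneric("imagingWeek", function(x) standardGeneric("imagingWeek"))

#' @rdname accessors
#' @export
setGeneric("cloudBounds", function(x) standardGeneric("cloudBounds"))

#' @rdname accessors
#' @export
setGeneric("fates", function(x) standardGeneric("fates"))

#' @rdname accessors
#' @export
setGeneric("deathWeeks", function(x) standardGeneric("deathWeeks"))

#' @rdname accessors
#' @export
setGeneric("tangleOnsets", function(x) standardGeneric("tangleOnsets"))

#' @rdname accessors
#' @export
setGeneric("everTangled", function(x) standardGeneric("everTangled"))

#' @rdname accessors
#' @export
setGeneric("firstWeeks", function(x) standardGeneric("firstWeeks"))

#' @rdname accessors
#' @export
setGeneric("trackIds", function(x) standardGeneric("trackIds"))

#' @rdname accessors
#' @export
setGeneric("trackPositions", function(x) standardGeneric("trackPositions"))

#' Apply a similarity transform
#'
#' Maps points p to `scale * rotation %*% p + translation`. For a
#' [SessionCloud-class] the labels are preserved and the bounds are updated
#' to the axis-aligned bounding box of the transformed bounds corners.
#'
#' @param x an n x 3 matrix or a [SessionCloud-class].
#' @param transform a [SimilarityTransform-class].
#' @return Same class as `x`, transformed.
#' @examples
#' pts <- matrix(rnorm(15), ncol = 3)
#' applyTransform(pts, SimilarityTransform(translation = c(10, 0, 0)))
#' @export
setGeneric("applyTransform",
    function(x, transform) standardGeneric("applyTransform"))
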