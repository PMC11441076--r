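#' @include AllGenerics.R
NULL

# Default voxel geometry of the two-photon stacks: 509 um imaged over 1024
# pixels in XY, 2 um z-steps.

#' Default voxel size of the imaging geometry
#'
#' @return numeric 3-vector, um per voxel in x, y, z.
#' @examples defaultVoxelSize()
#' @export
defaultVoxelSize <- function() c(509 / 1024, 509 / 1024, 2)

.applyTransformMatrix <- function(P, tf) {
    out <- tf@scale * P %*% t(tf@rotation)
    sweep(out, 2, tf@translation, "+")
}

.transformBounds <- function(bounds, tf) {
    corners <- as.matrix(expand.grid(bounds[1, ], bounds[2, ], bounds[3, ]))
    tc <- .applyTransformMatrix(corners, tf)
    rng <- apply(tc, 2, range)
    b <- cbind(lo = rng[1, ], hi = rng[2, ])
    dimnames(b) <- list(c("x", "y", "z"), c("lo", "hi"))
    b
}

#' Estimate a similarity transform from paired fiducials
#'
#' Closed-form least-squares absolute orientation with isotropic scale: finds
#' the [SimilarityTransform-class] minimising
#' `sum_i || scale * R %*% moving[i, ] + t  -  reference[i, ] ||^2`
#' over proper rotations R (reflections excluded), via the SVD of the
#' cross-covariance of the centred point sets. At least 3 non-collinear
#' pairs are required.
#'
#' @param moving,reference n x 3 matrices of paired fiducial centroids (the
#'   transform maps `moving` onto `reference`).
#' @return A [SimilarityTransform-class].
#' @examples
#' P <- matrix(runif(24, 0, 100), ncol = 3)
#' tf <- SimilarityTransform(1.02, rotationAboutZ(0.1), c(3, -2, 1))
#' estimateTransform(P, applyTransform(P, tf))
#' @export
estimateTransform <- function(moving, reference) {
    moving <- as.matrix(moving)
    reference <- as.matrix(reference)
    if (nrow(moving) != nrow(reference))
        stop("'moving' and 'reference' must have equal numbers of points")
    n <- nrow(moving)
    if (n < 3L)
        stop("at least 3 fiducial pairs are required")
    pbar <- colMeans(moving)
    qbar <- colMeans(reference)
    Xc <- sweep(moving, 2, pbar)
    Yc <- sweep(reference, 2, qbar)
    sv <- svd(crossprod(Xc, Yc) / n)    # Sigma = U D V'
    # degeneracy: all points on (or numerically near) a line
    spread <- svd(Xc, nu = 0, nv = 0)$d
    if (spread[2] <= 1e-9 * max(spread[1], 1))
        stop("degenerate fiducials: points are collinear")
    s3 <- sign(det(sv$v %*% t(sv$u)))
    if (s3 == 0) s3 <- 1
    D <- c(1, 1, s3)
    R <- sv$v %*% diag(D) %*% t(sv$u)
    varP <- sum(Xc^2) / n
    scl <- sum(sv$d * D) / varP
    if (scl <= 0)
        stop("degenerate fiducials: non-positive scale estimate")
    tr <- qbar - scl * as.vector(R %*% pbar)
    SimilarityTransform(scl, R, tr)
}

#' @rdname applyTransform
setMethod("applyTransform", "matrix", function(x, transform) {
    stopifnot(is(transform, "SimilarityTransform"))
    .applyTransformMatrix(x, transform)
})

#' @rdname applyTransform
setMethod("applyTransform", "SessionCloud", function(x, transform) {
    stopifnot(is(transform, "SimilarityTransform"))
    initialize(x, coords = .applyTransformMatrix(x@coords, transform),
               bounds = .transformBounds(x@bounds, transform))
})

#' Invert a similarity transform
#'
#' @param transform a [SimilarityTransform-class].
#' @return The inverse [SimilarityTransform-class]; composing the two
#'   returns points to within numerical precision.
#' @export
invertTransform <- function(transform) {
    Rinv <- t(transform@rotation)
    sinv <- 1 / transform@scale
    SimilarityTransform(sinv, Rinv,
        -sinv * as.vector(Rinv %*% transform@translation))
}

#' Fiducial registration report
#'
#' Per-fiducial residuals of a fitted transform, in micrometres and in voxel
#' units of the imaging geometry (default XY pitch 509/1024 um, z pitch
#' 2 um). Well-chosen fiducials typically land within 1-2 voxels.
#'
#' @param transform fitted [SimilarityTransform-class].
#' @param moving,reference the fiducial pairs used in the fit.
#' @param voxelSize um per voxel (3-vector).
#' @return list with `residuals` (per-fiducial um), `rms` (um) and
#'   `rmsVoxels` (residuals expressed in voxel units).
#' @export
registrationReport <- function(transform, moving, reference,
                               voxelSize = defaultVoxelSize()) {
    res <- .applyTransformMatrix(as.matrix(moving), transform) -
        as.matrix(reference)
    perFid <- sqrt(rowSums(res^2))
    resVox <- sweep(res, 2, voxelSize, "/")
    list(residuals = perFid,
         rms = sqrt(mean(perFid^2)),
         rmsVoxels = sqrt(mean(rowSums(resVox^2))))
}

#' Register weekly sessions into a common reference frame
#'
#' Pairs the fiducial-flagged nuclei of each session with those of the
#' reference session by `neuronId`, estimates the per-session similarity
#' transform by absolute orientation, and maps every session into the
#' reference frame.
#'
#' @param sessions list of [SessionCloud-class].
#' @param reference index of the reference session (default 1, the first
#'   week).
#' @param voxelSize um per voxel, for the residual report.
#' @param refine if `TRUE`, after the fiducial fit each session is matched
#'   to the reference by gated mutual nearest neighbours and the transform
#'   is re-estimated on all matched nuclei; averaging over hundreds of
#'   landmarks instead of ~8 fiducials shrinks the transform noise well
#'   below the centroid jitter.
#' @param refineGateUm matching gate for the refinement pass, um.
#' @return list with `sessions` (registered clouds), `transforms` (estimated
#'   [SimilarityTransform-class] per session; identity for the reference) and
#'   `reports` (one [registrationReport()] per session, `NULL` for the
#'   reference; fiducial residuals refer to the fiducial-only fit).
#' @export
registerSessions <- function(sessions, reference = 1L,
                             voxelSize = defaultVoxelSize(),
                             refine = FALSE, refineGateUm = 8) {
    stopifnot(length(sessions) >= 2L)
    ref <- sessions[[reference]]
    refFid <- which(fiducialFlags(ref))
    out <- sessions
    transforms <- vector("list", length(sessions))
    reports <- vector("list", length(sessions))
    transforms[[reference]] <- identityTransform()
    for (w in seq_along(sessions)) {
        if (w == reference) next
        cl <- sessions[[w]]
        movFid <- which(fiducialFlags(cl))
        common <- intersect(neuronIds(ref)[refFid], neuronIds(cl)[movFid])
        if (length(common) < 3L)
            stop(sprintf("session %d shares only %d fiducials with the reference",
                         w, length(common)))
        P <- coords(cl)[match(common, neuronIds(cl)), , drop = FALSE]
        Q <- coords(ref)[match(common, neuronIds(ref)), , drop = FALSE]
        tf <- estimateTransform(P, Q)
        reports[[w]] <- registrationReport(tf, P, Q, voxelSize)
        if (refine) {
            rough <- .applyTransformMatrix(coords(cl), tf)
            m <- matchSessions(ref, SessionCloud(rough, week = imagingWeek(cl),
                bounds = .transformBounds(cloudBounds(cl), tf)),
                gateUm = refineGateUm)
            if (nrow(m$pairs) >= 8L)
                tf <- estimateTransform(
                    coords(cl)[m$pairs$queryIdx, , drop = FALSE],
                    coords(ref)[m$pairs$refIdx, , drop = FALSE])
        }
        transforms[[w]] <- tf
        out[[w]] <- applyTransform(cl, tf)
    }
    list(sessions = out, transforms = transforms, reports = reports)
}

#' Crop registered sessions to their common overlap
#'
#' With `transforms = NULL`, keeps the points inside the intersection of the
#' sessions' axis-aligned bounding boxes and sets every session's bounds to
#' that intersection. When the estimated per-session transforms are supplied
#' (one per session, mapping each session's native frame into the common
#' frame), membership is instead tested in every session's true imaged box:
#' a point is kept only if its back-transformed position lies inside each
#' native field. This removes regions that were never imaged in some week,
#' which an axis-aligned box overstates after a rotation.
#'
#' @param sessions list of >= 2 registered [SessionCloud-class] objects.
#' @param transforms optional list of [SimilarityTransform-class], one per
#'   session (native -> common frame), plus `nativeBounds`, the 3 x 2 box of
#'   a native field (common to all sessions).
#' @param nativeBounds 3 x 2 bounds of the native imaged field, used with
#'   `transforms`.
#' @return list of cropped [SessionCloud-class] objects.
#' @examples
#' a <- SessionCloud(matrix(runif(300), ncol = 3), bounds = cbind(0, 1))
#' b <- applyTransform(a, SimilarityTransform(translation = c(0.5, 0, 0)))
#' lengths <- vapply(cropToOverlap(list(a, b)), length, 0L)
#' @export
cropToOverlap <- function(sessions, transforms = NULL, nativeBounds = NULL) {
    stopifnot(length(sessions) >= 2L)
    lo <- apply(vapply(sessions, function(s) cloudBounds(s)[, 1],
        numeric(3)), 1, max)
    hi <- apply(vapply(sessions, function(s) cloudBounds(s)[, 2],
        numeric(3)), 1, min)
    if (any(hi <= lo))
        stop("empty overlap: session bounding boxes do not intersect")
    inter <- cbind(lo = lo, hi = hi)
    keepFun <- function(P) {
        keep <- P[, 1] >= lo[1] & P[, 1] <= hi[1] &
                P[, 2] >= lo[2] & P[, 2] <= hi[2] &
                P[, 3] >= lo[3] & P[, 3] <= hi[3]
        if (!is.null(transforms)) {
            stopifnot(length(transforms) == length(sessions),
                      !is.null(nativeBounds))
            for (tf in transforms) {
                B <- .applyTransformMatrix(P, invertTransform(tf))
                keep <- keep &
                    B[, 1] >= nativeBounds[1, 1] & B[, 1] <= nativeBounds[1, 2] &
                    B[, 2] >= nativeBounds[2, 1] & B[, 2] <= nativeBounds[2, 2] &
                    B[, 3] >= nativeBounds[3, 1] & B[, 3] <= nativeBounds[3, 2]
            }
        }
        keep
    }
    lapply(sessions, function(s) {
        out <- s[keepFun(coords(s))]
        out@bounds <- inter
        validObject(out)
        out
    })
}
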