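#' @include AllClasses.R
NULL

#' Match nuclei between two registered sessions
#'
#' Mutual-nearest-neighbour matching with a hard distance gate: nucleus i of
#' `ref` and nucleus j of `query` are paired when each is the other's nearest
#' neighbour and their distance is at most `gateUm`. Each nucleus joins at
#' most one pair; ties are broken by smaller index, so the result is
#' deterministic and equals the brute-force mutual-NN of the full distance
#' matrix. Unmatched reference nuclei are candidate disappearances.
#'
#' @param ref,query [SessionCloud-class] objects registered to a common
#'   frame.
#' @param gateUm matching gate in um; the default 8 um is about one nucleus
#'   diameter, below the 12 um packing separation.
#' @return list with `pairs` (data.frame `refIdx`, `queryIdx`, `dist`),
#'   `unmatchedRef` and `unmatchedQuery` (integer indices).
#' @examples
#' cl <- generateBaseCloud(simulationConfig(nNeurons = 80, seed = 1))
#' m <- matchSessions(cl, cl)
#' nrow(m$pairs)
#' @export
matchSessions <- function(ref, query, gateUm = 8) {
    if (gateUm <= 0) stop("'gateUm' must be positive")
    A <- if (is(ref, "SessionCloud")) coords(ref) else as.matrix(ref)
    B <- if (is(query, "SessionCloud")) coords(query) else as.matrix(query)
    fw <- .nnWithin(A, B)
    bw <- .nnWithin(B, A)
    i <- seq_len(nrow(A))
    mutual <- bw$index[fw$index] == i & fw$dist <= gateUm
    pairs <- data.frame(refIdx = i[mutual], queryIdx = fw$index[mutual],
        dist = fw$dist[mutual])
    list(pairs = pairs,
         unmatchedRef = setdiff(i, pairs$refIdx),
         unmatchedQuery = setdiff(seq_len(nrow(B)), pairs$queryIdx))
}

#' Link nuclei across sessions and call fates
#'
#' Builds longitudinal tracks by matching each session against the last-seen
#' positions of all open tracks ([matchSessions()] semantics). A track's fate
#' is `"disappeared"` only when its absence persists from some week through
#' the final session (first absent week = death week); a track that goes
#' unobserved and is later re-matched is `"ambiguous"` and is excluded from
#' death counts. Session nuclei matched to no track open a new track. Tangle
#' flags carried by the session clouds set each track's tangle-onset week.
#'
#' @param sessions list of >= 2 registered (and typically overlap-cropped)
#'   [SessionCloud-class] objects, in week order.
#' @param gateUm matching gate in um.
#' @return A [NeuronTrackSet-class].
#' @examples
#' sim <- simulateLongitudinal(simulationConfig(nNeurons = 200, seed = 4,
#'     sessionTransforms = replicate(4, identityTransform())))
#' tr <- buildTracks(sim$sessions)
#' table(fates(tr))
#' @export
buildTracks <- function(sessions, gateUm = 8) {
    stopifnot(length(sessions) >= 2L)
    W <- length(sessions)
    cl1 <- sessions[[1]]
    n0 <- length(cl1)
    pos <- array(NA_real_, c(n0, 3, W))
    pos[, , 1] <- coords(cl1)
    tangle <- matrix(FALSE, n0, W)
    tangle[, 1] <- tangleFlags(cl1)
    sourceId <- neuronIds(cl1)
    firstWeek <- rep(1L, n0)
    lastSeen <- rep(1L, n0)
    gapped <- rep(FALSE, n0)

    for (w in seq_len(W)[-1]) {
        cl <- sessions[[w]]
        nT <- length(lastSeen)
        last <- t(vapply(seq_len(nT), function(i) pos[i, , lastSeen[i]],
            numeric(3)))
        m <- matchSessions(last, coords(cl), gateUm)
        if (nrow(m$pairs)) {
            ti <- m$pairs$refIdx
            qi <- m$pairs$queryIdx
            pos[cbind(ti, 1L, w)] <- coords(cl)[qi, 1]
            pos[cbind(ti, 2L, w)] <- coords(cl)[qi, 2]
            pos[cbind(ti, 3L, w)] <- coords(cl)[qi, 3]
            tangle[cbind(ti, w)] <- tangleFlags(cl)[qi]
            gapped[ti] <- gapped[ti] | (lastSeen[ti] < w - 1L)
            lastSeen[ti] <- w
        }
        newIdx <- m$unmatchedQuery
        if (length(newIdx)) {
            add <- length(newIdx)
            pos2 <- array(NA_real_, c(nrow(pos) + add, 3, W))
            pos2[seq_len(nrow(pos)), , ] <- pos
            for (k in seq_along(newIdx))
                pos2[nrow(pos) + k, , w] <- coords(cl)[newIdx[k], ]
            pos <- pos2
            tangle <- rbind(tangle, matrix(FALSE, add, W))
            tangle[nrow(tangle) - add + seq_len(add), w] <-
                tangleFlags(cl)[newIdx]
            sourceId <- c(sourceId, neuronIds(cl)[newIdx])
            firstWeek <- c(firstWeek, rep(w, add))
            lastSeen <- c(lastSeen, rep(w, add))
            gapped <- c(gapped, rep(FALSE, add))
        }
    }

    n <- length(lastSeen)
    fate <- character(n)
    deathWeek <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
        if (lastSeen[i] == W) {
            fate[i] <- if (gapped[i]) "ambiguous" else "persisted"
        } else if (gapped[i]) {
            fate[i] <- "ambiguous"
        } else {
            fate[i] <- "disappeared"
            deathWeek[i] <- lastSeen[i] + 1L
        }
    }
    onset <- apply(tangle, 1, function(s)
        if (any(s)) which(s)[1] else NA_integer_)
    new("NeuronTrackSet", positions = pos, trackId = seq_len(n),
        sourceId = as.integer(sourceId), fate = fate,
        deathWeek = deathWeek, tangleOnset = as.integer(onset),
        firstWeek = as.integer(firstWeek), nWeeks = as.integer(W))
}

#' Label connected components of a binary 3D stack
#'
#' 6-connectivity components of `stack > threshold`, via the adjacency graph
#' of foreground voxels.
#'
#' @param stack numeric 3D array.
#' @param threshold voxels strictly above this are foreground.
#' @return integer array of the same dimension: 0 background, 1..k component
#'   labels.
#' @export
labelStack <- function(stack, threshold = 0) {
    d <- dim(stack)
    stopifnot(length(d) == 3L)
    fg <- which(stack > threshold)
    lab <- array(0L, d)
    if (!length(fg)) return(lab)
    vox <- arrayInd(fg, d)
    key <- array(0L, d)
    key[fg] <- seq_along(fg)
    edges <- list()
    for (ax in 1:3) {
        shifted <- vox
        shifted[, ax] <- shifted[, ax] + 1L
        ok <- shifted[, ax] <= d[ax]
        if (!any(ok)) next
        nb <- key[shifted[ok, , drop = FALSE]]
        has <- nb > 0L
        if (any(has))
            edges[[length(edges) + 1L]] <-
                cbind(which(ok)[has], nb[has])
    }
    if (length(edges)) {
        em <- do.call(rbind, edges)
        g <- igraph::graph_from_edgelist(em, directed = FALSE)
        g <- igraph::add_vertices(g,
            max(0L, length(fg) - igraph::vcount(g)))
        memb <- igraph::components(g)$membership
    } else {
        memb <- seq_along(fg)
    }
    lab[fg] <- as.integer(memb)
    lab
}

#' Summarise labelled tangle objects
#'
#' Computes voxel counts and centroids (in um) for each labelled component
#' of a stack, e.g. the output of [labelStack()] on a rolling-ball-isolated
#' tangle channel.
#'
#' @param labels integer 3D array of component labels (0 = background).
#' @param voxelSize um per voxel (3-vector); required.
#' @param week imaging week to record.
#' @return data.frame with `label`, `week`, `x_um`, `y_um`, `z_um`,
#'   `voxel_count`.
#' @export
tangleObjectsFromLabels <- function(labels, voxelSize, week = 1L) {
    if (missing(voxelSize) || is.null(voxelSize))
        stop("'voxelSize' is required to compute object volumes")
    fg <- which(labels > 0L)
    if (!length(fg))
        return(data.frame(label = integer(), week = integer(),
            x_um = numeric(), y_um = numeric(), z_um = numeric(),
            voxel_count = integer()))
    vox <- arrayInd(fg, dim(labels))
    lb <- labels[fg]
    cnt <- as.integer(table(lb))
    ulb <- sort(unique(lb))
    cent <- vapply(ulb, function(l) {
        v <- vox[lb == l, , drop = FALSE]
        (colMeans(v) - 0.5) * voxelSize
    }, numeric(3))
    data.frame(label = ulb, week = as.integer(week),
        x_um = cent[1, ], y_um = cent[2, ], z_um = cent[3, ],
        voxel_count = cnt)
}

#' Filter tangle objects by voxel-count cutoff
#'
#' Retains components with at least `minVoxels` voxels (default 100, which
#' at the default imaging geometry corresponds to ~49 um^3) and attaches
#' their volume in um^3 from the voxel geometry.
#'
#' @param objects data.frame with a `voxel_count` column (e.g. from
#'   [tangleObjectsFromLabels()] or [tangleObjectsFromSessions()]).
#' @param voxelSize um per voxel (3-vector); required.
#' @param minVoxels retention cutoff (components with fewer voxels removed).
#' @return the retained rows with an added `volume_um3` column.
#' @examples
#' filterTangleObjects(data.frame(voxel_count = c(99, 100, 250)),
#'                     defaultVoxelSize())
#' @export
filterTangleObjects <- function(objects, voxelSize, minVoxels = 100L) {
    if (missing(voxelSize) || is.null(voxelSize))
        stop("'voxelSize' is required to compute object volumes")
    stopifnot(is.data.frame(objects), "voxel_count" %in% names(objects))
    keep <- objects$voxel_count >= minVoxels
    out <- objects[keep, , drop = FALSE]
    out$volume_um3 <- out$voxel_count * prod(voxelSize)
    rownames(out) <- NULL
    out
}

#' Cutoff volume implied by a voxel-count threshold
#'
#' @param minVoxels voxel-count cutoff.
#' @param voxelSize um per voxel (3-vector).
#' @return volume in um^3.
#' @examples tangleCutoffVolume()   # ~49 um^3
#' @export
tangleCutoffVolume <- function(minVoxels = 100L,
                               voxelSize = defaultVoxelSize()) {
    minVoxels * prod(voxelSize)
}

#' Assign tangle status to tracks from tangle objects
#'
#' A track becomes tangle-bearing from the first week a tangle-object
#' centroid lies within `radiusUm` of the track's position that week; this
#' overrides any tangle flags carried from the session clouds. A track's
#' `everTangled` status is "ever tangle-bearing during observation", so the
#' ever-tangled count always equals initially-tangled plus newly-tangled.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param tangles data.frame of registered tangle objects with columns
#'   `week`, `x_um`, `y_um`, `z_um` (e.g. filtered by
#'   [filterTangleObjects()]).
#' @param radiusUm association radius, um (default 10).
#' @return the track set with updated `tangleOnset`.
#' @export
assignTangleStatus <- function(tracks, tangles, radiusUm = 10) {
    W <- tracks@nWeeks
    n <- length(tracks)
    onset <- rep(NA_integer_, n)
    for (w in seq_len(W)) {
        tw <- tangles[tangles$week == w, , drop = FALSE]
        if (!nrow(tw)) next
        P <- tracks@positions[, , w, drop = FALSE]
        dim(P) <- c(n, 3L)
        present <- which(!is.na(P[, 1]) & is.na(onset))
        if (!length(present)) next
        nn <- .nnWithin(P[present, , drop = FALSE],
            as.matrix(tw[, c("x_um", "y_um", "z_um")]))
        hit <- nn$dist <= radiusUm
        onset[present[hit]] <- w
    }
    initialize(tracks, tangleOnset = onset)
}

#' Tangle bookkeeping: initial, new, and ever-tangled counts
#'
#' @param tracks a [NeuronTrackSet-class] with tangle onsets assigned.
#' @return list with `initial` (tangle-bearing at each track's first observed
#'   week), `new` (onset after the first observed week), and `ever`
#'   (= initial + new).
#' @export
tangleCounts <- function(tracks) {
    on <- tangleOnsets(tracks)
    fw <- firstWeeks(tracks)
    initial <- sum(!is.na(on) & on == fw)
    newOn <- sum(!is.na(on) & on > fw)
    list(initial = initial, new = newOn, ever = initial + newOn)
}
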