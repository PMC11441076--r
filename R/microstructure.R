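#' @include AllClasses.R
NULL

#' Mean distance to the k nearest neighbours
#'
#' For each requested nucleus, the mean of the k smallest Euclidean
#' distances to the other nuclei in the cloud ("d3" for the default k = 3).
#' Ties are broken by index order, so results are deterministic and equal
#' the brute-force full-sort of the distance matrix.
#'
#' @param cloud a [SessionCloud-class] or an n x 3 coordinate matrix.
#' @param focal optional nucleus indices; default all.
#' @param k neighbour count (default 3).
#' @return numeric vector of mean k-NN distances in um.
#' @examples
#' X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
#' knnMeanDistance(X, focal = 1)   # 1
#' @export
knnMeanDistance <- function(cloud, focal = NULL, k = 3L) {
    X <- if (is(cloud, "SessionCloud")) coords(cloud) else as.matrix(cloud)
    if (nrow(X) < k + 1L)
        stop(sprintf("need at least %d nuclei for k = %d", k + 1L, k))
    d <- rowMeans(.knnDist(X, k))
    if (is.null(focal)) d else d[focal]
}

#' Per-neuron local enlargement of 3-NN distances
#'
#' The single-snapshot microstructure statistic: for each neuron, its mean
#' 3-nearest-neighbour distance (`d3`) divided by the mean `d3` of all other
#' neurons within `radiusUm` (inclusive), minus 1. Values above 0.60 flag a
#' locally rarefied ("enlarged") neighbourhood. Neurons with fewer than
#' `minLocal` neighbours in the ball get `NA` enlargement (emitted, not
#' dropped); `edge_flag` marks neurons whose `radiusUm` ball is clipped by
#' the field bounds. The ratio is invariant under rigid motion and global
#' isotropic scaling of the cloud.
#'
#' @param cloud a [SessionCloud-class].
#' @param radiusUm normalisation radius, um (default 100).
#' @param k neighbour count for d3 (default 3).
#' @param minLocal minimum neighbours within the ball for a defined
#'   enlargement (default 5; stabilises the denominator).
#' @return data.frame with `neuron_id`, `d3`, `local_mean_d3`, `enlargement`,
#'   `n_local`, `edge_flag`.
#' @examples
#' snap <- generateSnapshot(snapshotConfig(nNeurons = 1500,
#'     bounds = c(550, 550, 250), enlargedFraction = 0, seed = 8))
#' mt <- microstructureTable(snap$cloud)
#' summary(mt$enlargement)
#' @export
microstructureTable <- function(cloud, radiusUm = 100, k = 3L,
                                minLocal = 5L) {
    stopifnot(is(cloud, "SessionCloud"))
    X <- coords(cloud)
    loc <- .knnAndLocal(X, k, radiusUm)
    d3 <- loc$d3
    enl <- ifelse(loc$nLocal >= minLocal, d3 / loc$localMean - 1, NA_real_)
    b <- cloudBounds(cloud)
    edge <- (X[, 1] - b[1, 1] < radiusUm) | (b[1, 2] - X[, 1] < radiusUm) |
            (X[, 2] - b[2, 1] < radiusUm) | (b[2, 2] - X[, 2] < radiusUm) |
            (X[, 3] - b[3, 1] < radiusUm) | (b[3, 2] - X[, 3] < radiusUm)
    data.frame(neuron_id = neuronIds(cloud), d3 = d3,
        local_mean_d3 = loc$localMean, enlargement = enl,
        n_local = loc$nLocal, edge_flag = edge)
}

#' Flag neurons with enlarged neighbour distances
#'
#' Strict threshold: enlargement must exceed `threshold` (default 0.60, the
#' ">60%" cutoff); exactly-at-threshold and `NA` records are not flagged.
#'
#' @param records output of [microstructureTable()].
#' @param threshold enlargement cutoff.
#' @return integer vector of flagged `neuron_id`s.
#' @export
flagEnlarged <- function(records, threshold = 0.60) {
    records$neuron_id[!is.na(records$enlargement) &
                      records$enlargement > threshold]
}

#' Select a track's nearest persistent neighbours
#'
#' The `m` tracks that persist across all weeks (no gap, observed week 1
#' through the final week) nearest to the focal track at its first observed
#' week; the set is fixed thereafter. Dying or ambiguous neighbours are
#' skipped in favour of the next-nearest persistent one.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param focalId focal `trackId`.
#' @param m neighbour count (default 4).
#' @return integer vector of `m` neighbour trackIds (nearest first), or
#'   `NULL` if fewer than `m` persistent neighbours exist (the focal is then
#'   excluded from volume analysis).
#' @export
selectPersistentNeighbors <- function(tracks, focalId, m = 4L) {
    i <- match(focalId, trackIds(tracks))
    stopifnot(!is.na(i))
    persistent <- which(fates(tracks) == "persisted" &
                        firstWeeks(tracks) == 1L)
    persistent <- setdiff(persistent, i)
    if (length(persistent) < m) return(NULL)
    w <- firstWeeks(tracks)[i]
    p0 <- tracks@positions[i, , w]
    P <- tracks@positions[persistent, , w, drop = FALSE]
    dim(P) <- c(length(persistent), 3L)
    d2 <- colSums((t(P) - p0)^2)
    trackIds(tracks)[persistent[order(d2)[seq_len(m)]]]
}

#' Tetrahedron volume from 4 vertices
#'
#' `|det(b - a, c - a, d - a)| / 6`; zero (with a warning) for coplanar
#' vertices.
#'
#' @param vertices 4 x 3 matrix of vertex coordinates, um.
#' @return volume in um^3.
#' @examples
#' tetraVolume(rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)))   # 1/6
#' @export
tetraVolume <- function(vertices) {
    vertices <- as.matrix(vertices)
    stopifnot(nrow(vertices) == 4L, ncol(vertices) == 3L)
    M <- sweep(vertices[2:4, , drop = FALSE], 2, vertices[1, ])
    v <- abs(det(M)) / 6
    if (v == 0) warning("degenerate (coplanar) tetrahedron; volume 0")
    v
}

#' Weekly neighbour-tetrahedron volumes around a track
#'
#' The volume of the tetrahedron whose vertices are the focal track's `m = 4`
#' designated persistent neighbours, per week. The neighbour set is fixed
#' ([selectPersistentNeighbors()]), so volume changes reflect neighbour
#' displacement.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param focalId focal `trackId`.
#' @param neighborIds optional explicit neighbour trackIds; default the 4
#'   nearest persistent neighbours.
#' @return data.frame with `week` and `volume_um3`, or `NULL` when no valid
#'   neighbour set exists.
#' @export
neighborVolumeSeries <- function(tracks, focalId, neighborIds = NULL) {
    if (is.null(neighborIds))
        neighborIds <- selectPersistentNeighbors(tracks, focalId, 4L)
    if (is.null(neighborIds)) return(NULL)
    stopifnot(length(neighborIds) == 4L)
    idx <- match(neighborIds, trackIds(tracks))
    stopifnot(!anyNA(idx))
    W <- tracks@nWeeks
    vol <- vapply(seq_len(W), function(w) {
        V <- tracks@positions[idx, , w, drop = FALSE]
        dim(V) <- c(4L, 3L)
        if (anyNA(V)) return(NA_real_)
        suppressWarnings(tetraVolume(V))
    }, numeric(1))
    data.frame(week = seq_len(W), volume_um3 = vol)
}

#' Percent volume change over a measurement window
#'
#' `100 * (V_last - V_first) / V_first` over the supplied volume series
#' (NA weeks dropped).
#'
#' @param volumes numeric vector of weekly volumes, or the data.frame from
#'   [neighborVolumeSeries()].
#' @return percent change.
#' @examples
#' volumeChangePercent(c(1000, 1331))   # +33.1, an isotropic 1.1x scaling
#' @export
volumeChangePercent <- function(volumes) {
    if (is.data.frame(volumes)) volumes <- volumes$volume_um3
    volumes <- volumes[!is.na(volumes)]
    if (length(volumes) < 2L)
        stop("need at least 2 measured volumes")
    if (volumes[1] == 0) stop("first volume is zero")
    100 * (volumes[length(volumes)] - volumes[1]) / volumes[1]
}

#' Neighbour-volume change for dying and persistent tracks
#'
#' For each disappeared track with at least 2 observed weeks before its death
#' week and 4 persistent neighbours, the percent change of the neighbour
#' tetrahedron volume across the 2 weeks preceding disappearance (weeks
#' `deathWeek - 2` to `deathWeek - 1`). Persistent tracks are measured over a
#' matched window (the final 2 weeks).
#'
#' Records whose baseline tetrahedron is nearly degenerate are excluded
#' (volume below `minVolumeUm3`): the percent-change ratio is numerically
#' unstable when the four neighbours are close to coplanar, and sub-um
#' centroid noise then dominates the statistic. When `bounds` are supplied,
#' focal neurons within `edgeMarginUm` of the field boundary are excluded
#' too: after cropping to the common imaged region, a boundary neuron's true
#' nearest persistent neighbours may lie outside the field, and the
#' replacement neighbours do not carry its displacement signal.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param minVolumeUm3 minimum baseline (first-window) tetrahedron volume;
#'   default 500 um^3, about a third of the typical neighbour volume at the
#'   default packing density.
#' @param bounds optional 3 x 2 field bounds for edge exclusion.
#' @param edgeMarginUm edge-exclusion margin, um (about the distance to a
#'   neuron's 4th-nearest persistent neighbour).
#' @return data.frame with `track_id`, `fate`, `pct_change`.
#' @export
dyingVolumeChanges <- function(tracks, minVolumeUm3 = 500, bounds = NULL,
                               edgeMarginUm = 50) {
    W <- tracks@nWeeks
    rows <- list()
    for (i in seq_len(length(tracks))) {
        f <- fates(tracks)[i]
        if (f == "ambiguous") next
        if (!is.null(bounds)) {
            p1 <- tracks@positions[i, , firstWeeks(tracks)[i]]
            if (anyNA(p1) ||
                any(p1 < bounds[, 1] + edgeMarginUm) ||
                any(p1 > bounds[, 2] - edgeMarginUm)) next
        }
        id <- trackIds(tracks)[i]
        if (f == "disappeared") {
            wD <- deathWeeks(tracks)[i]
            if (wD < 3L || firstWeeks(tracks)[i] > wD - 2L) next
            win <- c(wD - 2L, wD - 1L)
        } else {
            win <- c(W - 1L, W)
        }
        ser <- neighborVolumeSeries(tracks, id)
        if (is.null(ser)) next
        v <- ser$volume_um3[win]
        if (anyNA(v) || v[1] < minVolumeUm3) next
        rows[[length(rows) + 1L]] <- data.frame(track_id = id, fate = f,
            pct_change = 100 * (v[2] - v[1]) / v[1])
    }
    if (!length(rows))
        return(data.frame(track_id = integer(), fate = character(),
            pct_change = numeric()))
    do.call(rbind, rows)
}

#' Distance increase equivalent to a percent volume change
#'
#' Converts a neighbour-volume change into the equivalent increase in
#' neighbour distance under isotropic scaling:
#' `baselineD * ((1 + pctChange/100)^(1/3) - 1)`.
#'
#' @param pctChange percent volume change (> -100).
#' @param baselineD baseline neighbour distance, um.
#' @return distance increase in um.
#' @examples
#' volumeToDistanceEquivalent(29.5, 24.0)   # ~2.2 um
#' volumeToDistanceEquivalent(33.1, 10.0)   # 1.0 um exactly
#' @export
volumeToDistanceEquivalent <- function(pctChange, baselineD) {
    stopifnot(all(pctChange > -100))
    baselineD * ((1 + pctChange / 100)^(1 / 3) - 1)
}

#' Death risk of flagged neurons versus the population
#'
#' Fraction of flagged tracks that die within `horizonWeeks` of week 1, and
#' the fold change of that fraction over the population death fraction.
#' Ambiguous tracks are excluded from both numerator and denominator.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param flaggedIds trackIds flagged (e.g. by [flagEnlarged()] on week-1
#'   microstructure).
#' @param horizonWeeks horizon in weeks after week 1 (default all remaining
#'   weeks).
#' @return list with `fractionDying`, `populationFraction`, `fold` (`NA`
#'   with a message when undefined: empty flag set or zero population
#'   deaths).
#' @export
riskGivenFlag <- function(tracks, flaggedIds,
                          horizonWeeks = tracks@nWeeks - 1L) {
    keep <- fates(tracks) != "ambiguous" & firstWeeks(tracks) == 1L
    ids <- trackIds(tracks)[keep]
    died <- fates(tracks)[keep] == "disappeared" &
        !is.na(deathWeeks(tracks)[keep]) &
        deathWeeks(tracks)[keep] <= 1L + horizonWeeks
    popFrac <- mean(died)
    fl <- ids %in% flaggedIds
    if (!any(fl)) {
        message("empty flagged set: risk undefined")
        return(list(fractionDying = NA_real_, populationFraction = popFrac,
            fold = NA_real_))
    }
    frac <- mean(died[fl])
    fold <- if (popFrac > 0) frac / popFrac else NA_real_
    if (is.na(fold)) message("no deaths in population: fold undefined")
    list(fractionDying = frac, populationFraction = popFrac, fold = fold)
}

#' First-week d3 of dying versus nearby persistent neurons
#'
#' Compares the mean 3-NN distance at the first observed week between
#' disappearing tracks and persistent tracks within `nearbyUm` (default
#' 30 um) of any disappearing track. Both a pooled-neuron reduction and the
#' per-fate means are returned.
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param nearbyUm radius defining "nearby" persistent comparators.
#' @param k neighbour count for d3.
#' @return list with `dyingD3`, `persistentD3` (mean um), `perNeuron`
#'   (data.frame of the pooled per-neuron values).
#' @export
dyingVsPersistentD3 <- function(tracks, nearbyUm = 30, k = 3L) {
    w1 <- 1L
    present <- which(firstWeeks(tracks) == w1)
    P <- tracks@positions[present, , w1, drop = FALSE]
    dim(P) <- c(length(present), 3L)
    d3 <- knnMeanDistance(P, k = k)
    f <- fates(tracks)[present]
    dy <- which(f == "disappeared")
    pe <- which(f == "persisted")
    if (!length(dy) || !length(pe))
        stop("need both dying and persistent tracks at week 1")
    nn <- .nnWithin(P[pe, , drop = FALSE], P[dy, , drop = FALSE])
    nearby <- pe[nn$dist <= nearbyUm]
    perNeuron <- rbind(
        data.frame(group = "dying", d3 = d3[dy]),
        data.frame(group = "persistent_nearby", d3 = d3[nearby]))
    list(dyingD3 = mean(d3[dy]),
         persistentD3 = if (length(nearby)) mean(d3[nearby]) else NA_real_,
         perNeuron = perNeuron)
}
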