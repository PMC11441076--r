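#' Simulation configuration for longitudinal session clouds
#'
#' Parameters of the synthetic longitudinal experiment. The defaults emulate
#' the study regime of weekly two-photon imaging of a 509 x 509 x 200 um
#' cortical field: ~1500 labelled nuclei at a hard-core separation of 12 um
#' (giving a mean 3-nearest-neighbour distance of ~24 um), four weekly
#' sessions, a per-week death hazard of 3.6% for non-tangle-bearing and 1%
#' for tangle-bearing neurons, a two-week pre-death neighbour-displacement
#' ramp reaching +29.5% tetrahedron volume at disappearance, per-session
#' similarity-transform misalignment, 0.5 um centroid jitter, and 8 fiducial
#' neurons (one per field octant).
#'
#' @param bounds numeric 3-vector, field size in um (box with origin 0).
#' @param nNeurons number of nuclei.
#' @param minSeparation hard-core minimum pairwise distance, um.
#' @param nWeeks number of weekly sessions.
#' @param pTangleInit fraction of neurons tangle-bearing at week 1.
#' @param tangleRate per-week probability that a non-tangled neuron develops
#'   a tangle.
#' @param hazardNontangle,hazardTangle per-week death probabilities by
#'   current tangle status.
#' @param rampWeeks weeks over which the pre-death neighbour displacement
#'   ramps: displacement is zero `rampWeeks` sessions before death and full
#'   at the last observed session, so the 4-persistent-neighbour tetrahedron
#'   volume grows by `rampVolumePct` across that window.
#' @param rampVolumePct target percent volume increase at disappearance.
#' @param predeathD3Factor factor by which a doomed neuron's initial
#'   neighbourhood is rarefied at week 1 (its 6 nearest neighbours are pushed
#'   radially outward by this factor), so dying neurons start farther from
#'   their neighbours than persisting ones. Default 33.9/24.0.
#' @param jitterSd centroid measurement noise SD per axis, um.
#' @param sessionTransforms list of [SimilarityTransform-class], one per
#'   week, applied to each week's true cloud before jitter; `NULL` draws
#'   small random transforms (week 1 identity).
#' @param nFiducials number of fiducial neurons, drawn one per field octant
#'   (4 upper, 4 lower quadrants) from neurons that persist and are not
#'   displacement targets.
#' @param hazardChangeWeek week from which both hazards are multiplied by
#'   `hazardChangeFactor` (a tau-suppression-style change point); `NA` for
#'   constant hazards.
#' @param hazardChangeFactor hazard multiplier after the change point.
#' @param clusterSigma if non-`NULL`, deaths are spatially clustered around a
#'   random centre with a Gaussian kernel of this SD (um), preserving the
#'   expected number of deaths. Default `NULL` (spatially random deaths).
#' @param seed integer RNG seed; every stochastic step is reproducible.
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nNeurons = 200, seed = 7)
#' cfg$hazardNontangle
#' @export
simulationConfig <- function(bounds = c(509, 509, 200),
                             nNeurons = 1500,
                             minSeparation = 12,
                             nWeeks = 4,
                             pTangleInit = 0.074,
                             tangleRate = 0.023,
                             hazardNontangle = 0.036,
                             hazardTangle = 0.01,
                             rampWeeks = 2,
                             rampVolumePct = 29.5,
                             predeathD3Factor = 33.9 / 24.0,
                             jitterSd = 0.5,
                             sessionTransforms = NULL,
                             nFiducials = 8,
                             hazardChangeWeek = NA,
                             hazardChangeFactor = 0.5,
                             clusterSigma = NULL,
                             seed = 1L) {
    cfg <- list(bounds = as.numeric(bounds), nNeurons = as.integer(nNeurons),
        minSeparation = minSeparation, nWeeks = as.integer(nWeeks),
        pTangleInit = pTangleInit, tangleRate = tangleRate,
        hazardNontangle = hazardNontangle, hazardTangle = hazardTangle,
        rampWeeks = as.integer(rampWeeks), rampVolumePct = rampVolumePct,
        predeathD3Factor = predeathD3Factor, jitterSd = jitterSd,
        sessionTransforms = sessionTransforms,
        nFiducials = as.integer(nFiducials),
        hazardChangeWeek = hazardChangeWeek,
        hazardChangeFactor = hazardChangeFactor,
        clusterSigma = clusterSigma, seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    bad <- character()
    if (length(cfg$bounds) != 3L || any(cfg$bounds <= 0))
        bad <- c(bad, "bounds must be 3 positive extents")
    if (cfg$minSeparation <= 0) bad <- c(bad, "minSeparation must be > 0")
    for (h in c("hazardNontangle", "hazardTangle"))
        if (cfg[[h]] < 0 || cfg[[h]] > 1)
            bad <- c(bad, sprintf("%s must be in [0, 1]", h))
    for (p in c("pTangleInit", "tangleRate"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            bad <- c(bad, sprintf("%s must be in [0, 1]", p))
    if (cfg$nWeeks < 2L) bad <- c(bad, "nWeeks must be >= 2")
    if (cfg$rampWeeks >= cfg$nWeeks)
        bad <- c(bad, "rampWeeks must be < nWeeks")
    if (cfg$rampWeeks < 1L) bad <- c(bad, "rampWeeks must be >= 1")
    if (cfg$rampVolumePct <= -100)
        bad <- c(bad, "rampVolumePct must be > -100")
    if (!is.null(cfg$sessionTransforms) &&
        length(cfg$sessionTransforms) != cfg$nWeeks)
        bad <- c(bad, "sessionTransforms must have one entry per week")
    if (length(bad))
        stop("invalid SimulationConfig: ", paste(bad, collapse = "; "))
    invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(
        "SimulationConfig: %d neurons in %.0f x %.0f x %.0f um, %d weeks, seed %d\n",
        x$nNeurons, x$bounds[1], x$bounds[2], x$bounds[3], x$nWeeks, x$seed))
    cat(sprintf(
        "  hazards: non-tangle %.3f, tangle %.3f per week; ramp %d weeks to +%.1f%%\n",
        x$hazardNontangle, x$hazardTangle, x$rampWeeks, x$rampVolumePct))
    invisible(x)
}

# Hard-core (minimum-separation) point process by batched dart throwing:
# uniform proposals are screened against accepted points with chunked
# distance matrices (BLAS-level), and the rare within-batch conflicts are
# resolved sequentially. Nuclei cannot overlap, and the resulting regular
# spacing mimics cortical nuclei. Errors out explicitly when the requested
# density cannot be packed.
.hardcoreCloud <- function(n, hi, minSep, maxTries = max(20000L, 200L * n)) {
    minSep2 <- minSep^2
    pts <- matrix(NA_real_, n, 3)
    accepted <- 0L
    tries <- 0L
    batch <- max(500L, min(4000L, n))
    while (accepted < n) {
        if (tries > maxTries)
            stop(sprintf(
                "packing failure: placed %d of %d points at separation %g in %s um",
                accepted, n, minSep, paste(round(hi), collapse = " x ")))
        B <- matrix(stats::runif(3L * batch), ncol = 3)
        B <- sweep(B, 2, hi, "*")
        tries <- tries + batch
        ok <- rep(TRUE, batch)
        if (accepted > 0L) {
            for (s in seq.int(1L, accepted, by = 4000L)) {
                e <- min(s + 3999L, accepted)
                d2 <- .pairDist2(B[ok, , drop = FALSE],
                                 pts[s:e, , drop = FALSE])
                bad <- rowSums(d2 < minSep2) > 0L
                ok[which(ok)[bad]] <- FALSE
                if (!any(ok)) break
            }
        }
        keep <- which(ok)
        if (!length(keep)) next
        # resolve the rare conflicts inside the batch, in proposal order
        Bk <- B[keep, , drop = FALSE]
        if (length(keep) > 1L) {
            d2in <- .pairDist2(Bk, Bk)
            diag(d2in) <- Inf
            conf <- which(d2in < minSep2, arr.ind = TRUE)
            conf <- conf[conf[, 1] < conf[, 2], , drop = FALSE]
            if (nrow(conf)) {
                drop <- rep(FALSE, length(keep))
                for (r in seq_len(nrow(conf))) {
                    i <- conf[r, 1]; j <- conf[r, 2]
                    if (!drop[i] && !drop[j]) drop[j] <- TRUE
                }
                Bk <- Bk[!drop, , drop = FALSE]
            }
        }
        add <- min(nrow(Bk), n - accepted)
        if (add > 0L) {
            pts[accepted + seq_len(add), ] <- Bk[seq_len(add), , drop = FALSE]
            accepted <- accepted + add
        }
    }
    pts
}

#' Generate a single hard-core session cloud
#'
#' Places `nNeurons` nucleus centroids uniformly in the field with a hard-core
#' minimum pairwise separation (dart throwing). Deterministic for a fixed
#' `config$seed`. Fails with an explicit packing error when the density is
#' infeasible.
#'
#' @param config a [simulationConfig()].
#' @return A [SessionCloud-class] at week 1 (no tangle or fiducial flags set).
#' @examples
#' cl <- generateBaseCloud(simulationConfig(nNeurons = 100, seed = 3))
#' length(cl)
#' @export
generateBaseCloud <- function(config) {
    .validateSimConfig(config)
    set.seed(config$seed)
    pts <- .hardcoreCloud(config$nNeurons, config$bounds, config$minSeparation)
    SessionCloud(pts, week = 1L,
        bounds = cbind(lo = c(0, 0, 0), hi = config$bounds))
}

.axisAngleRotation <- function(axis, theta) {
    a <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
    diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Random small per-session similarity transforms
#'
#' Week 1 is the identity; later weeks get a rotation about a random axis of
#' up to `maxAngleDeg`, a uniform scale in `scaleRange`, and a translation of
#' up to `maxShiftUm` per axis, emulating session-to-session repositioning
#' and slow tissue stretch. Draws from the current RNG stream.
#'
#' @param nWeeks number of sessions.
#' @param maxAngleDeg,scaleRange,maxShiftUm transform magnitude limits.
#' @return list of [SimilarityTransform-class], length `nWeeks`.
#' @export
randomSessionTransforms <- function(nWeeks, maxAngleDeg = 4,
                                    scaleRange = c(0.99, 1.01),
                                    maxShiftUm = 15) {
    out <- vector("list", nWeeks)
    out[[1]] <- identityTransform()
    for (w in seq_len(nWeeks)[-1]) {
        ax <- stats::rnorm(3)
        th <- stats::runif(1, -maxAngleDeg, maxAngleDeg) * pi / 180
        s <- stats::runif(1, scaleRange[1], scaleRange[2])
        tr <- stats::runif(3, -maxShiftUm, maxShiftUm)
        out[[w]] <- SimilarityTransform(s, .axisAngleRotation(ax, th), tr)
    }
    out
}

.clamp01 <- function(x) pmin(1, pmax(0, x))

.rampFraction <- function(week, deathWeek, rampWeeks) {
    # 0 at deathWeek - rampWeeks, 1 at deathWeek - 1 (the last observed
    # session), clamped outside; rampWeeks == 1 is a step at deathWeek - 1.
    if (rampWeeks == 1L) return(as.numeric(week >= deathWeek - 1L))
    .clamp01((week - (deathWeek - rampWeeks)) / (rampWeeks - 1L))
}

#' Simulate a longitudinal imaging experiment
#'
#' Builds a hard-core base cloud, draws tangle-status trajectories and
#' status-dependent geometric death hazards, rarefies doomed neurons' initial
#' neighbourhoods, ramps their 4 nearest persistent neighbours radially
#' outward so the neighbour tetrahedron volume grows by `rampVolumePct` over
#' the `rampWeeks` sessions before disappearance, selects fiducial neurons
#' (one per field octant, never dying), and emits one observed
#' [SessionCloud-class] per week: the true cloud mapped through that week's
#' session transform plus centroid jitter, with dead neurons removed.
#'
#' @param config a [simulationConfig()].
#' @return A list with elements `sessions` (list of [SessionCloud-class]) and
#'   `truth`, a `GroundTruth` list with `fates` (data.frame: `neuron_id`,
#'   `fate`, `death_week`, `tangle_onset`, `fiducial`), `neighbors` (per
#'   dying neuron, ids of its 4 designated persistent neighbours),
#'   `transforms` (true per-session transforms), `basePositions` (n x 3
#'   week-1 truth coordinates) and `config`.
#' @examples
#' sim <- simulateLongitudinal(simulationConfig(nNeurons = 150, seed = 2))
#' table(sim$truth$fates$fate)
#' @export
simulateLongitudinal <- function(config) {
    .validateSimConfig(config)
    set.seed(config$seed)
    n <- config$nNeurons
    W <- config$nWeeks
    hi <- config$bounds
    base <- .hardcoreCloud(n, hi, config$minSeparation)

    # tangle-status trajectories (tangles persist once formed)
    S <- matrix(FALSE, n, W)
    S[, 1] <- stats::runif(n) < config$pTangleInit
    for (t in seq_len(W)[-1])
        S[, t] <- S[, t - 1] | (stats::runif(n) < config$tangleRate)

    # status-dependent death draw (geometric hazard over weeks 2..W)
    deathWeek <- rep(NA_integer_, n)
    alive <- rep(TRUE, n)
    clusterCenter <- if (!is.null(config$clusterSigma))
        stats::runif(3) * hi else NULL
    for (t in seq_len(W)[-1]) {
        h <- ifelse(S[, t - 1], config$hazardTangle, config$hazardNontangle)
        if (!is.na(config$hazardChangeWeek) && t >= config$hazardChangeWeek)
            h <- h * config$hazardChangeFactor
        if (!is.null(clusterCenter) && any(alive & h > 0)) {
            wgt <- exp(-rowSums(sweep(base, 2, clusterCenter)^2) /
                       (2 * config$clusterSigma^2))
            hw <- h * wgt
            tot <- sum(hw[alive])
            if (tot > 0) h <- pmin(1, hw * sum(h[alive]) / tot)
        }
        dies <- alive & (stats::runif(n) < h)
        deathWeek[dies] <- t
        alive[dies] <- FALSE
    }
    dying <- which(!is.na(deathWeek))
    persist <- which(is.na(deathWeek))

    # rarefy doomed neurons' initial neighbourhoods: push the 6 nearest
    # neighbours radially outward so first-week d3 starts elevated
    base1 <- base
    c0 <- config$predeathD3Factor
    if (length(dying) && c0 != 1) {
        disp <- matrix(0, n, 3)
        d2 <- .pairDist2(base[dying, , drop = FALSE], base)
        d2[cbind(seq_along(dying), dying)] <- Inf
        for (j in seq_along(dying)) {
            nb <- order(d2[j, ])[1:6]
            disp[nb, ] <- disp[nb, ] + (c0 - 1) *
                sweep(base[nb, , drop = FALSE], 2, base[dying[j], ])
        }
        base1 <- base + disp
    }

    # Weekly truth geometry. For a neuron dying at week w the designated
    # neighbour tetrahedron must satisfy V(w-1) = (1 + p/100) * V(w-2), so
    # the analyser's window ratio recovers rampVolumePct exactly. Pushes of
    # focals whose ramp completed in an earlier week are static across any
    # later focal's window and cancel in its ratio; focals ramping in the
    # same week can share vertices and are solved jointly (Gauss-Seidel on
    # one radial scale factor per focal) against targets fixed on the
    # pre-group geometry.
    rampPct <- config$rampVolumePct / 100
    weekPos <- function(t, neighborsList, pushList) {
        pos <- base1
        ids <- as.integer(names(neighborsList))
        if (!length(ids)) return(pos)
        fNow <- vapply(ids, function(i)
            .rampFraction(t, deathWeek[i], config$rampWeeks), numeric(1))
        fPrev <- vapply(ids, function(i)
            .rampFraction(t - 1L, deathWeek[i], config$rampWeeks), numeric(1))
        ord <- order(deathWeek[ids], ids)
        completed <- ord[fNow[ord] > 0 & fNow[ord] <= fPrev[ord]]
        group <- ord[fNow[ord] > fPrev[ord]]
        for (k in completed) {
            cc <- (1 + fNow[k] * rampPct)^(1 / 3)
            nb <- pushList[[k]]
            pos[nb, ] <- pos[nb, ] + (cc - 1) *
                sweep(pos[nb, , drop = FALSE], 2, pos[ids[k], ])
        }
        if (length(group)) {
            target <- vapply(group, function(k)
                .tetraVol(pos[neighborsList[[k]], , drop = FALSE]) *
                    (1 + fNow[k] * rampPct), numeric(1))
            # a vertex shared between two same-week focals is displaced by
            # its first claimer only; later claimers meet their volume
            # targets through the decoupled corrections below
            pushedInGroup <- integer(0)
            for (k in group) {
                cc <- (1 + fNow[k] * rampPct)^(1 / 3)
                nb <- setdiff(pushList[[k]], pushedInGroup)
                if (!length(nb)) next
                pos[nb, ] <- pos[nb, ] + (cc - 1) *
                    sweep(pos[nb, , drop = FALSE], 2, pos[ids[k], ])
                pushedInGroup <- c(pushedInGroup, nb)
            }
            # connected components of the shared-vertex graph among this
            # week's ramping focals; each coupled component is refined (and,
            # on failure, reverted) independently
            comp <- seq_along(group)
            vertexSeen <- list()
            for (g in seq_along(group)) {
                for (vtx in pushList[[group[g]]]) {
                    key <- as.character(vtx)
                    prev <- vertexSeen[[key]]
                    if (!is.null(prev)) {
                        old <- comp[g]; newc <- comp[prev]
                        comp[comp == old] <- newc
                    } else vertexSeen[[key]] <- g
                }
            }
            for (cid in unique(comp)) {
                members <- which(comp == cid)
                if (length(members) < 2L) next
                sets <- pushList[group[members]]
                allv <- unlist(sets, use.names = FALSE)
                sharedV <- unique(allv[duplicated(allv)])
                # shared vertices stay where the composed plain pushes put
                # them; each focal then meets its target exactly by scaling
                # its unshared vertices, which decouples the system
                for (g in members) {
                    k <- group[g]
                    nb <- neighborsList[[k]]
                    mine <- setdiff(pushList[[k]], sharedV)
                    if (!length(mine) || target[g] <= 1e-9) next
                    x0 <- pos[ids[k], ]
                    volAt <- function(cc) {
                        p2 <- pos[nb, , drop = FALSE]
                        sel <- nb %in% mine
                        p2[sel, ] <- p2[sel, , drop = FALSE] + (cc - 1) *
                            sweep(p2[sel, , drop = FALSE], 2, x0)
                        .tetraVol(p2)
                    }
                    gap <- function(cc) volAt(cc) - target[g]
                    if (gap(1) == 0) next
                    # cap the correction so no vertex moves more than a
                    # third of the packing separation (keeps the matching
                    # gate safe)
                    dmax <- sqrt(max(rowSums(
                        sweep(pos[mine, , drop = FALSE], 2, x0)^2)))
                    lim <- config$minSeparation / (3 * dmax)
                    cc <- tryCatch(
                        stats::uniroot(gap, c(1 - lim, 1 + lim),
                            tol = 1e-12)$root,
                        error = function(e) NULL)
                    if (is.null(cc)) next   # no nearby root: keep plain push
                    pos[mine, ] <- pos[mine, , drop = FALSE] + (cc - 1) *
                        sweep(pos[mine, , drop = FALSE], 2, x0)
                    if (isTRUE(getOption("neurofate.debugRamp")))
                        message(sprintf(
                            "week %d focal %d: unshared-scale %.4f", t,
                            ids[k], cc))
                }
            }
        }
        pos
    }

    # designate each dying neuron's 4 nearest persistent neighbours on the
    # week-1 truth geometry (what the analysis sees): week-2 deaths are
    # designated on the base cloud, their week-1 ramp is applied, and later
    # deaths are designated on the resulting geometry. The displacement is
    # applied to the 6 nearest persistent neighbours (pushSets), so the
    # tetrahedron of any 4 of them grows by the same factor and the analysis
    # recovers the ramp even when measurement noise swaps neighbour ranks.
    neighbors <- list()
    pushSets <- list()
    if (length(dying) && length(persist) >= 5L) {
        designate <- function(i, geom, m) {
            d2p <- colSums((t(geom[persist, , drop = FALSE]) - geom[i, ])^2)
            persist[order(d2p)[seq_len(m)]]
        }
        early <- dying[deathWeek[dying] == 2L]
        for (i in sort(early)) {
            six <- designate(i, base1, 5L)
            neighbors[[as.character(i)]] <- six[1:4]
            pushSets[[as.character(i)]] <- six
        }
        posW1 <- weekPos(1L, neighbors, pushSets)
        for (i in sort(dying[deathWeek[dying] > 2L])) {
            six <- designate(i, posW1, 5L)
            neighbors[[as.character(i)]] <- six[1:4]
            pushSets[[as.character(i)]] <- six
        }
    }

    # fiducials: persistent, non-displaced neurons nearest the octant
    # centres (4 upper quadrants, 4 lower)
    designated <- unique(unlist(pushSets, use.names = FALSE))
    eligible <- setdiff(persist, designated)
    if (length(eligible) < config$nFiducials)
        stop("not enough persistent neurons to serve as fiducials")
    qs <- as.matrix(expand.grid(c(0.25, 0.75), c(0.25, 0.75), c(0.25, 0.75)))
    centers <- sweep(qs, 2, hi, "*")
    fid <- integer(0)
    oct <- 1L
    while (length(fid) < config$nFiducials) {
        pool <- setdiff(eligible, fid)
        # keep the 4-upper / 4-lower layout: restrict to the octant's z half
        half <- if (centers[oct, 3] < hi[3] / 2)
            pool[base1[pool, 3] < hi[3] / 2]
        else pool[base1[pool, 3] >= hi[3] / 2]
        if (length(half)) pool <- half
        d2c <- colSums((t(base1[pool, , drop = FALSE]) -
                        centers[oct, ])^2)
        fid <- c(fid, pool[which.min(d2c)])
        oct <- oct %% 8L + 1L
    }
    isFid <- seq_len(n) %in% fid

    # weekly truth coordinates with the pre-death displacement ramp
    # (see weekPos above for the shared-vertex handling)
    truth <- array(NA_real_, c(n, 3, W))
    for (t in seq_len(W))
        truth[, , t] <- weekPos(t, neighbors, pushSets)

    transforms <- config$sessionTransforms
    if (is.null(transforms))
        transforms <- randomSessionTransforms(W)

    baseBounds <- cbind(lo = c(0, 0, 0), hi = hi)
    sessions <- vector("list", W)
    for (t in seq_len(W)) {
        aliveAt <- is.na(deathWeek) | deathWeek > t
        pts <- truth[aliveAt, , t, drop = FALSE]
        dim(pts) <- c(sum(aliveAt), 3L)
        tf <- transforms[[t]]
        mapped <- .applyTransformMatrix(pts, tf)
        mapped <- mapped + matrix(stats::rnorm(length(mapped),
            sd = config$jitterSd), ncol = 3)
        sessions[[t]] <- SessionCloud(mapped,
            neuronId = which(aliveAt), tangle = S[aliveAt, t],
            fiducial = isFid[aliveAt], week = t,
            bounds = .transformBounds(baseBounds, tf))
    }

    fatesDf <- data.frame(
        neuron_id = seq_len(n),
        fate = ifelse(is.na(deathWeek), "persist", "die"),
        death_week = deathWeek,
        tangle_onset = apply(S, 1, function(s)
            if (any(s)) which(s)[1] else NA_integer_),
        fiducial = isFid)
    truthObj <- structure(list(fates = fatesDf, neighbors = neighbors,
        transforms = transforms, basePositions = base1, config = config),
        class = "GroundTruth")
    list(sessions = sessions, truth = truthObj)
}

#' Snapshot configuration for human-like cleared-tissue clouds
#'
#' Emulates a single cleared, stained and imaged thick tissue section: a
#' dense hard-core cloud of segmented neuron centroids in which a small
#' subpopulation sits in locally rarefied neighbourhoods (enlarged
#' 3-nearest-neighbour distances), as seen in Alzheimer's donor cortex.
#' Defaults: 2% enlarged subpopulation with an 80% target distance increase
#' (comfortably past the 60% flagging cutoff), and 9.3% of enlarged neurons
#' tangle-bearing (so ~90.7% of enlarged neurons are tangle-free).
#'
#' @param bounds field extents in um (default a 1200 x 1200 x 500 um slab at
#'   mouse-cortex-like density).
#' @param nNeurons neuron count (desk scale 1e4-1e5).
#' @param minSeparation hard-core separation, um.
#' @param enlargedFraction fraction of neurons planted in rarefied
#'   neighbourhoods.
#' @param enlargementPct target percent increase of the planted neurons' 3-NN
#'   distance over the local mean.
#' @param tangleFraction overall tangle-bearing fraction.
#' @param tangleOnEnlargedFraction tangle-bearing fraction among the planted
#'   enlarged neurons.
#' @param seed integer RNG seed.
#' @return A validated list of class `SnapshotConfig`.
#' @export
snapshotConfig <- function(bounds = c(1200, 1200, 500),
                           nNeurons = 20000,
                           minSeparation = 12,
                           enlargedFraction = 0.02,
                           enlargementPct = 80,
                           tangleFraction = 0.10,
                           tangleOnEnlargedFraction = 0.093,
                           seed = 1L) {
    cfg <- list(bounds = as.numeric(bounds), nNeurons = as.integer(nNeurons),
        minSeparation = minSeparation, enlargedFraction = enlargedFraction,
        enlargementPct = enlargementPct, tangleFraction = tangleFraction,
        tangleOnEnlargedFraction = tangleOnEnlargedFraction,
        seed = as.integer(seed))
    class(cfg) <- "SnapshotConfig"
    bad <- character()
    if (length(cfg$bounds) != 3L || any(cfg$bounds <= 0))
        bad <- c(bad, "bounds must be 3 positive extents")
    if (cfg$minSeparation <= 0) bad <- c(bad, "minSeparation must be > 0")
    for (p in c("enlargedFraction", "tangleFraction",
                "tangleOnEnlargedFraction"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            bad <- c(bad, sprintf("%s must be in [0, 1]", p))
    if (cfg$enlargementPct <= 0)
        bad <- c(bad, "enlargementPct must be > 0")
    if (length(bad))
        stop("invalid SnapshotConfig: ", paste(bad, collapse = "; "))
    cfg
}

#' Generate a single-time-point snapshot cloud
#'
#' Places a hard-core cloud, then plants `enlargedFraction` of the neurons in
#' locally rarefied neighbourhoods: for each planted focal (interior, mutual
#' separation >= 100 um) its nearest neighbours are removed until the focal's
#' 3-NN distance exceeds `(1 + enlargementPct/100)` times the pre-existing
#' mean 3-NN distance of its 100 um neighbourhood; removed neurons are
#' relocated elsewhere (respecting the hard core and a 60 um guard around
#' focals), so the total count is unchanged and the voids resemble locally
#' missing neurons. Tangle flags are then drawn with the configured
#' fractions. Deterministic for a fixed seed.
#'
#' @param config a [snapshotConfig()].
#' @return list with `cloud` (a [SessionCloud-class]) and `truth` (list with
#'   `enlargedId`, the planted neuron ids).
#' @examples
#' snap <- generateSnapshot(snapshotConfig(nNeurons = 2000,
#'     bounds = c(600, 600, 250), enlargedFraction = 0.01, seed = 5))
#' length(snap$truth$enlargedId)
#' @export
generateSnapshot <- function(config) {
    stopifnot(inherits(config, "SnapshotConfig"))
    set.seed(config$seed)
    n <- config$nNeurons
    hi <- config$bounds
    X <- .hardcoreCloud(n, hi, config$minSeparation)
    kE <- round(config$enlargedFraction * n)
    focals <- integer(0)
    if (kE > 0) {
        loc <- .knnAndLocal(X, 3L, 100)
        interior <- which(
            X[, 1] >= 100 & X[, 1] <= hi[1] - 100 &
            X[, 2] >= 100 & X[, 2] <= hi[2] - 100 &
            X[, 3] >= 100 & X[, 3] <= hi[3] - 100)
        if (length(interior) < kE)
            stop("packing failure: too few interior neurons for enlarged set")
        cand <- sample(interior)
        # foci are kept mutually separated so their rarefied neighbourhoods
        # stay distinct; the separation relaxes (never below 60 um) when the
        # requested fraction cannot be packed at 100 um
        for (sep in c(100, 90, 80, 70, 60)) {
            focals <- integer(0)
            sep2 <- sep^2
            for (i in cand) {
                if (length(focals) >= kE) break
                if (length(focals) == 0L ||
                    min(colSums((t(X[focals, , drop = FALSE]) - X[i, ])^2)) >=
                        sep2)
                    focals <- c(focals, i)
            }
            if (length(focals) >= kE) break
        }
        if (length(focals) < kE)
            stop("packing failure: cannot place mutually separated enlarged foci")
        deleted <- integer(0)
        for (f in focals) {
            dd <- sqrt(colSums((t(X) - X[f, ])^2))
            dd[f] <- Inf
            ord <- order(dd)
            target <- (1 + config$enlargementPct / 100) * loc$localMean[f]
            jmax <- 25L
            j <- 0L
            while (j <= jmax && mean(dd[ord[(j + 1L):(j + 3L)]]) < target)
                j <- j + 1L
            if (j > 0L) deleted <- c(deleted, ord[seq_len(j)])
        }
        deleted <- unique(deleted)
        # relocate removed neurons far from the planted voids
        minSep2 <- config$minSeparation^2
        guard2 <- 60^2
        Xf <- X[focals, , drop = FALSE]
        for (d in deleted) {
            repeat {
                p <- stats::runif(3) * hi
                if (min(colSums((t(Xf) - p)^2)) < guard2) next
                dAll <- colSums((t(X) - p)^2)
                dAll[deleted] <- Inf   # not yet placed ones don't block
                dAll[d] <- Inf
                if (min(dAll) >= minSep2) { X[d, ] <- p; break }
            }
            deleted <- setdiff(deleted, d)  # placed; now blocks later darts
        }
    }
    tangle <- logical(n)
    if (length(focals))
        tangle[focals] <- stats::runif(length(focals)) <
            config$tangleOnEnlargedFraction
    others <- setdiff(seq_len(n), focals)
    pOther <- max(0, min(1,
        (config$tangleFraction * n -
         config$tangleOnEnlargedFraction * length(focals)) / length(others)))
    tangle[others] <- stats::runif(length(others)) < pOther
    cloud <- SessionCloud(X, tangle = tangle, week = 1L,
        bounds = cbind(lo = c(0, 0, 0), hi = hi))
    list(cloud = cloud, truth = list(enlargedId = focals))
}

#' Synthetic tangle-object table from simulated sessions
#'
#' Emits one tangle object per tangle-flagged nucleus per session, displaced
#' by at most `offsetUm` from the nucleus centroid, with voxel counts above
#' the retention cutoff. Used to exercise tangle-object association on
#' synthetic data.
#'
#' @param sessions list of [SessionCloud-class].
#' @param offsetUm maximum centroid offset, um.
#' @param voxelRange integer range of voxel counts to draw from.
#' @return data.frame with columns `week`, `x_um`, `y_um`, `z_um`,
#'   `voxel_count`.
#' @export
tangleObjectsFromSessions <- function(sessions, offsetUm = 2,
                                      voxelRange = c(120L, 600L)) {
    out <- list()
    for (cl in sessions) {
        idx <- which(tangleFlags(cl))
        if (!length(idx)) next
        off <- matrix(stats::runif(3 * length(idx), -1, 1), ncol = 3)
        off <- off / pmax(1e-12, sqrt(rowSums(off^2))) *
            stats::runif(length(idx), 0, offsetUm)
        pos <- coords(cl)[idx, , drop = FALSE] + off
        out[[length(out) + 1L]] <- data.frame(week = imagingWeek(cl),
            x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
            voxel_count = sample(seq(voxelRange[1], voxelRange[2]),
                length(idx), replace = TRUE))
    }
    do.call(rbind, out)
}
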