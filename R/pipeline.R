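#' Simulate an experiment and write it to disk
#'
#' Runs [simulateLongitudinal()] and writes sessions, truth, config and
#' manifest with [writeSessionClouds()].
#'
#' @param config a [simulationConfig()].
#' @param dir output directory.
#' @return the manifest, invisibly.
#' @export
simulateToFiles <- function(config, dir) {
    sim <- simulateLongitudinal(config)
    writeSessionClouds(sim, dir)
}

#' Run the full analysis pipeline on weekly session clouds
#'
#' Registration (fiducial absolute orientation into the week-1 frame) ->
#' crop to the common imaged region -> track linking and fate calling ->
#' week-1 microstructure and enlargement flagging -> neighbour-volume
#' changes -> grouped survival summaries. Each stage fails with a
#' stage-tagged error.
#'
#' @param sessions list of [SessionCloud-class] (or a directory path for
#'   [readSessionClouds()]).
#' @param gateUm track-matching gate, um.
#' @param radiusUm enlargement normalisation radius, um.
#' @param enlargeThreshold enlargement flagging cutoff.
#' @param minLocal minimum in-ball neighbours for a defined enlargement.
#' @param nativeBounds 3 x 2 native field box used for exact-overlap
#'   cropping; default the week-1 session bounds.
#' @return list with `registration` (transforms + residual reports),
#'   `sessions` (registered, cropped), `tracks`, `microstructure` (week-1
#'   table), `flagged` (enlarged track ids), `risk` ([riskGivenFlag()]),
#'   `volumeChanges` ([dyingVolumeChanges()]), `fateTable` (by tangle
#'   status), `summary` (loss fractions, hazard ratios, chi-square, weekly
#'   loss).
#' @examples
#' sim <- simulateLongitudinal(simulationConfig(nNeurons = 250, seed = 21))
#' res <- runPipeline(sim$sessions)
#' res$summary$lossPctAll
#' @export
runPipeline <- function(sessions, gateUm = 8, radiusUm = 100,
                        enlargeThreshold = 0.60, minLocal = 5L,
                        nativeBounds = NULL) {
    if (is.character(sessions)) sessions <- readSessionClouds(sessions)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    }
    if (is.null(nativeBounds)) nativeBounds <- cloudBounds(sessions[[1]])
    reg <- stage("registration", registerSessions(sessions, refine = TRUE))
    cropped <- stage("crop", cropToOverlap(reg$sessions,
        transforms = reg$transforms, nativeBounds = nativeBounds))
    tracks <- stage("tracking", buildTracks(cropped, gateUm = gateUm))

    micro <- stage("microstructure", {
        w1 <- which(firstWeeks(tracks) == 1L)
        P <- trackPositions(tracks)[w1, , 1, drop = FALSE]
        dim(P) <- c(length(w1), 3L)
        cl1 <- SessionCloud(P, neuronId = trackIds(tracks)[w1],
            week = 1L, bounds = cloudBounds(cropped[[1]]))
        microstructureTable(cl1, radiusUm = radiusUm, minLocal = minLocal)
    })
    flagged <- flagEnlarged(micro, enlargeThreshold)
    risk <- stage("microstructure", suppressMessages(
        riskGivenFlag(tracks, flagged)))
    volChanges <- stage("microstructure", dyingVolumeChanges(tracks,
        bounds = cloudBounds(cropped[[1]])))

    summaryStats <- stage("survival", {
        grp <- ifelse(everTangled(tracks), "tangle", "nontangle")
        ftAll <- fateTable(tracks)
        ft <- fateTable(tracks, group = grp)
        tot <- attr(ft, "totals")
        haveBoth <- nrow(tot) == 2L && all(tot$n_total > 0)
        chi <- if (haveBoth && all(tot$n_died > 0)) {
            m <- cbind(tot$n_died, tot$n_total - tot$n_died)
            chiSquare2x2(m)
        } else NULL
        hr <- if (haveBoth && tot$n_died[match("tangle", tot$group)] > 0)
            hazardRatio(ft, "nontangle", "tangle") else NULL
        list(lossPctAll = lossFraction(ftAll, "all", digits = NULL),
             byTangle = tot, chiSquare = chi, hazardRatio = hr,
             weeklyLoss = weeklyLoss(ftAll))
    })
    dvc <- volChanges
    vcSummary <- list(
        dyingMeanPct = mean(dvc$pct_change[dvc$fate == "disappeared"]),
        persistentMeanPct = mean(dvc$pct_change[dvc$fate == "persisted"]),
        nDying = sum(dvc$fate == "disappeared"))

    list(registration = reg[c("transforms", "reports")],
         sessions = cropped, tracks = tracks, microstructure = micro,
         flagged = flagged, risk = risk, volumeChanges = volChanges,
         volumeChangeSummary = vcSummary, fateTable = fateTable(tracks,
            group = ifelse(everTangled(tracks), "tangle", "nontangle")),
         summary = summaryStats)
}

#' Reference reproductions of the published worked-example numbers
#'
#' Recomputes, from the bundled count tables ([studyCounts()]), the bespoke
#' summaries: the died/survived-by-tangle-status chi-square, group loss
#' fractions, cumulative hazard ratio, ever-tangled bookkeeping, the
#' tangle-object cutoff volume, and the volume-to-distance conversion. All
#' values are computed at call time; nothing is hard-coded but the counts.
#'
#' @return named list of reproduced values.
#' @examples
#' rr <- referenceReproductions()
#' rr$chiSquare
#' @export
referenceReproductions <- function() {
    cc <- studyCounts()
    rt <- cc$rtg4510
    ft <- fateTableFromCounts(
        c(nontangle = rt$nontangle$n, tangle = rt$tangle$n),
        c(nontangle = rt$nontangle$died, tangle = rt$tangle$died))
    ftAll <- fateTableFromCounts(
        c(rtg4510 = rt$total, control = cc$control$total,
          thytau22 = cc$thytau22$total, wildtype = cc$wildtype$total),
        c(rtg4510 = rt$died, control = cc$control$died,
          thytau22 = cc$thytau22$died, wildtype = cc$wildtype$died))
    hu <- cc$human
    ftHuman <- fateTableFromCounts(
        c(ad = hu$ad$neurons, ctrl = hu$control$neurons),
        c(ad = hu$ad$enlarged, ctrl = hu$control$enlarged))
    list(
        chiSquare = chiSquare2x2(
            rt$tangle$died, rt$tangle$n - rt$tangle$died,
            rt$nontangle$died, rt$nontangle$n - rt$nontangle$died)$statistic,
        lossPct = c(
            rtg4510 = lossFraction(ftAll, "rtg4510"),
            tangle = lossFraction(ft, "tangle"),
            nontangle = lossFraction(ft, "nontangle"),
            control = lossFraction(ftAll, "control"),
            thytau22 = lossFraction(ftAll, "thytau22"),
            wildtype = lossFraction(ftAll, "wildtype")),
        humanEnlargedPct = c(
            ad = lossFraction(ftHuman, "ad", digits = 2L),
            control = lossFraction(ftHuman, "ctrl", digits = 2L)),
        cumulativeHazardRatio = hazardRatio(ft, "nontangle",
            "tangle")$cumulative,
        everTangled = rt$initialTangles + rt$newTangles,
        tangleCutoffUm3 = tangleCutoffVolume(),
        distanceEquivalentUm = volumeToDistanceEquivalent(
            cc$microstructure$volumeChangePct,
            cc$microstructure$persistingD3))
}
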