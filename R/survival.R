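#' Grouped fate table from tracks
#'
#' Per-group died/survived totals and per-week died and at-risk counts.
#' Ambiguous tracks are excluded from every denominator; tracks first seen
#' after week 1 are excluded too (their observation window is incomplete).
#'
#' @param tracks a [NeuronTrackSet-class].
#' @param group factor/character/logical vector, one value per track (e.g.
#'   [everTangled()] or a mouse label). Default: one group.
#' @return data.frame of class `FateTable` with columns `group`, `week`,
#'   `at_risk`, `died`, and attributes `totals` (per-group `n_total`,
#'   `n_died`).
#' @examples
#' sim <- simulateLongitudinal(simulationConfig(nNeurons = 300, seed = 11,
#'     sessionTransforms = replicate(4, identityTransform())))
#' tr <- buildTracks(sim$sessions)
#' ft <- fateTable(tr, group = everTangled(tr))
#' attr(ft, "totals")
#' @export
fateTable <- function(tracks, group = rep("all", length(tracks))) {
    stopifnot(length(group) == length(tracks))
    keep <- fates(tracks) != "ambiguous" & firstWeeks(tracks) == 1L
    g <- factor(group[keep])
    dW <- deathWeeks(tracks)[keep]
    W <- tracks@nWeeks
    rows <- list()
    totals <- list()
    for (lev in levels(g)) {
        sel <- g == lev
        n <- sum(sel)
        dw <- dW[sel]
        atRisk <- integer(W)
        died <- integer(W)
        alive <- n
        for (w in seq_len(W)) {
            atRisk[w] <- alive
            died[w] <- sum(!is.na(dw) & dw == w)
            alive <- alive - died[w]
        }
        rows[[lev]] <- data.frame(group = lev, week = seq_len(W),
            at_risk = atRisk, died = died)
        totals[[lev]] <- data.frame(group = lev, n_total = n,
            n_died = sum(!is.na(dw)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "totals") <- do.call(rbind, c(totals, make.row.names = FALSE))
    class(out) <- c("FateTable", "data.frame")
    out
}

#' Manually constructed fate table
#'
#' Builds a `FateTable` from explicit counts, for reproducing published
#' grouped summaries where only totals (or weekly died counts) are known.
#'
#' @param nTotal named integer vector of group sizes.
#' @param nDied named integer vector of deaths per group.
#' @param weeklyDied optional list of per-week died counts per group; when
#'   omitted, only the totals (and [lossFraction()]) are usable.
#' @return a `FateTable`.
#' @examples
#' ft <- fateTableFromCounts(c(tangle = 235, nontangle = 1486),
#'                           c(tangle = 6, nontangle = 172))
#' lossFraction(ft, "nontangle")   # 11.6
#' @export
fateTableFromCounts <- function(nTotal, nDied, weeklyDied = NULL) {
    stopifnot(identical(names(nTotal), names(nDied)),
              all(nDied <= nTotal))
    rows <- list()
    totals <- list()
    for (gname in names(nTotal)) {
        wk <- if (!is.null(weeklyDied)) weeklyDied[[gname]] else nDied[[gname]]
        W <- length(wk)
        atRisk <- nTotal[[gname]] - c(0, cumsum(wk))[seq_len(W)]
        rows[[gname]] <- data.frame(group = gname, week = seq_len(W),
            at_risk = atRisk, died = as.integer(wk))
        totals[[gname]] <- data.frame(group = gname,
            n_total = as.integer(nTotal[[gname]]),
            n_died = as.integer(nDied[[gname]]))
    }
    out <- do.call(rbind, c(rows, make.row.names = FALSE))
    attr(out, "totals") <- do.call(rbind, c(totals, make.row.names = FALSE))
    class(out) <- c("FateTable", "data.frame")
    out
}

.groupTotals <- function(table, group) {
    tot <- attr(table, "totals")
    row <- tot[tot$group == group, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("no group '%s' in fate table", group))
    row
}

#' Cumulative loss fraction of a group
#'
#' `100 * n_died / n_total`, rounded to `digits` decimals (display rounding
#' of 1 decimal for percentages, 2 for sub-1% fractions as published).
#'
#' @param table a `FateTable`.
#' @param group group label.
#' @param digits decimals to round to; `NULL` for unrounded.
#' @return percent.
#' @examples
#' ft <- fateTableFromCounts(c(all = 1721), c(all = 178))
#' lossFraction(ft, "all")   # 10.3
#' @export
lossFraction <- function(table, group, digits = 1L) {
    row <- .groupTotals(table, group)
    if (row$n_total == 0) stop("empty group")
    pct <- 100 * row$n_died / row$n_total
    if (is.null(digits)) pct else round(pct, digits)
}

#' Per-week loss and across-group summary
#'
#' Week-w loss is `died_w / at_risk_w` per group; the summary aggregates the
#' per-group mean weekly losses with a standard error across groups (the
#' "per-mouse" reduction when groups are animals).
#'
#' @param table a `FateTable` with weekly counts.
#' @param weeks optional subset of weeks (default all weeks with at-risk
#'   neurons; week 1 has no preceding interval and is skipped).
#' @return list with `perWeek` (data.frame `group`, `week`, `pct`),
#'   `meanPct`, `sePct`.
#' @export
weeklyLoss <- function(table, weeks = NULL) {
    tab <- table[table$week >= 2L & table$at_risk > 0, , drop = FALSE]
    if (!is.null(weeks)) tab <- tab[tab$week %in% weeks, , drop = FALSE]
    perWeek <- data.frame(group = tab$group, week = tab$week,
        pct = 100 * tab$died / tab$at_risk)
    byGroup <- tapply(perWeek$pct, perWeek$group, mean)
    se <- if (length(byGroup) > 1)
        stats::sd(byGroup) / sqrt(length(byGroup)) else NA_real_
    list(perWeek = perWeek, meanPct = mean(byGroup), sePct = se)
}

#' Hazard ratio between two groups
#'
#' Two variants are always reported. The cumulative variant divides the
#' groups' overall death fractions, `(diedA/nA) / (diedB/nB)`, the quantity
#' reproducible from printed totals. The weekly variant divides the groups'
#' per-week death rates computed as occurrence over exposure
#' (`sum(died) / sum(at_risk)` across weeks), which stays stable when a
#' group has few deaths. With zero deaths in the reference group the ratio
#' is `Inf` with a warning.
#'
#' @param table a `FateTable` containing both groups.
#' @param groupA numerator group label.
#' @param groupB reference (denominator) group label.
#' @return list with `cumulative` and `weekly`.
#' @examples
#' ft <- fateTableFromCounts(c(nontangle = 1486, tangle = 235),
#'                           c(nontangle = 172, tangle = 6))
#' hazardRatio(ft, "nontangle", "tangle")$cumulative   # ~4.53
#' @export
hazardRatio <- function(table, groupA, groupB) {
    a <- .groupTotals(table, groupA)
    b <- .groupTotals(table, groupB)
    if (a$n_total == 0 || b$n_total == 0) stop("empty group")
    if (b$n_died == 0) {
        warning("zero deaths in reference group: infinite hazard ratio")
        return(list(cumulative = Inf, weekly = Inf))
    }
    cum <- (a$n_died / a$n_total) / (b$n_died / b$n_total)
    sub <- table[table$week >= 2L & table$at_risk > 0, , drop = FALSE]
    rate <- function(g) {
        s <- sub[sub$group == g, , drop = FALSE]
        if (!nrow(s)) return(NA_real_)
        sum(s$died) / sum(s$at_risk)
    }
    rb <- rate(groupB)
    wk <- if (!is.na(rb) && rb > 0) rate(groupA) / rb else Inf
    list(cumulative = cum, weekly = wk)
}

#' Pearson chi-square for a 2 x 2 table
#'
#' Uncorrected Pearson statistic
#' `N * (ad - bc)^2 / ((a+b) (c+d) (a+c) (b+d))` with 1 degree of freedom;
#' no Yates continuity correction (the convention under which the published
#' died/survived-by-tangle-status table gives 17.8).
#'
#' @param a,b,c,d non-negative integer cells (row 1: a, b; row 2: c, d), or
#'   `a` may be a 2 x 2 matrix.
#' @return list with `statistic`, `df` (= 1), `p.value`.
#' @examples
#' chiSquare2x2(6, 229, 172, 1314)$statistic   # ~17.8
#' @export
chiSquare2x2 <- function(a, b, c, d) {
    if (is.matrix(a)) {
        stopifnot(all(dim(a) == 2L))
        m <- a
    } else {
        m <- matrix(base::c(a, c, b, d), 2, 2)
    }
    if (any(m < 0)) stop("cells must be non-negative")
    rs <- rowSums(m); cs <- colSums(m); N <- sum(m)
    if (any(rs == 0) || any(cs == 0))
        stop("zero margin: chi-square undefined")
    stat <- N * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 / prod(rs, cs)
    list(statistic = stat, df = 1L,
         p.value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Annualised loss projected from a snapshot
#'
#' Simple proportional projection: the fraction of neurons flagged as
#' at-risk in a single snapshot, times the per-period death rate of flagged
#' neurons, times the number of periods per year. The projection assumes the
#' flagged pool turns over each period at the same rate; it is linear in
#' every argument.
#'
#' @param flaggedFraction fraction of neurons flagged, in `[0, 1]`.
#' @param perPeriodDeathRate death rate of flagged neurons per period, in
#'   `[0, 1]`.
#' @param periodsPerYear number of periods per year (> 0).
#' @return percent of all neurons lost per year.
#' @examples
#' snapshotLossProjection(0.02, 0.467, 6)   # 5.6 %/yr
#' @export
snapshotLossProjection <- function(flaggedFraction, perPeriodDeathRate,
                                   periodsPerYear) {
    stopifnot(flaggedFraction >= 0, flaggedFraction <= 1,
              perPeriodDeathRate >= 0, perPeriodDeathRate <= 1,
              periodsPerYear > 0)
    100 * flaggedFraction * perPeriodDeathRate * periodsPerYear
}

#' Published worked-example count tables
#'
#' The printed group counts and summary values of the source study, bundled
#' as inputs so the bespoke summaries (loss fractions, chi-square, hazard
#' ratios, the volume-to-distance conversion, the tangle-object cutoff) can
#' be recomputed from counts rather than asserted.
#'
#' @return nested list of counts and constants; see the worked example in
#'   the package README.
#' @examples
#' cc <- studyCounts()
#' with(cc$rtg4510, 100 * died / total)   # ~10.3
#' @export
studyCounts <- function() {
    list(
        rtg4510 = list(total = 1721L, died = 178L,
            tangle = list(n = 235L, died = 6L),
            nontangle = list(n = 1486L, died = 172L),
            initialTangles = 128L, newTangles = 107L),
        control = list(total = 1589L, died = 8L),
        thytau22 = list(total = 845L, died = 24L),
        wildtype = list(total = 860L, died = 1L),
        human = list(ad = list(neurons = 268849L, enlarged = 5391L),
                     control = list(neurons = 425540L, enlarged = 2072L)),
        microstructure = list(volumeChangePct = 29.5,
            persistingD3 = 24.0, dyingD3 = 33.9, controlD3 = 22.4),
        imaging = list(fieldUm = c(509, 509, 200),
            pixelsXY = c(1024L, 1024L), zStepUm = 2)
    )
}
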