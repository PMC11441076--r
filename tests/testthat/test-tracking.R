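test_that("matchSessions pairs identical clouds perfectly", {
    cl <- generateBaseCloud(simulationConfig(nNeurons = 120, seed = 61))
    m <- matchSessions(cl, cl)
    expect_equal(nrow(m$pairs), 120)
    expect_length(m$unmatchedRef, 0)
    expect_length(m$unmatchedQuery, 0)
    expect_error(matchSessions(cl, cl, gateUm = 0), "positive")
})

test_that("the gate separates small jitter from large offsets", {
    cl <- generateBaseCloud(simulationConfig(nNeurons = 100, seed = 62))
    set.seed(62)
    jit <- coords(cl) + matrix(rnorm(300, sd = 1), ncol = 3)  # << gate/2
    m <- matchSessions(coords(cl), jit, gateUm = 8)
    expect_equal(nrow(m$pairs), 100)
    far <- coords(cl) + 10    # every point moved > gate
    m2 <- matchSessions(coords(cl), far, gateUm = 8)
    expect_equal(nrow(m2$pairs), 0)
})

test_that("matching equals the brute-force mutual-NN oracle", {
    set.seed(63)
    for (rep in 1:4) {
        A <- matrix(runif(3 * 80, 0, 60), ncol = 3)
        B <- matrix(runif(3 * 90, 0, 60), ncol = 3)
        gate <- runif(1, 3, 15)
        got <- matchSessions(A, B, gate)$pairs
        want <- bruteMutualNN(A, B, gate)
        expect_equal(as.matrix(got[, c("refIdx", "queryIdx")]), want,
            ignore_attr = TRUE)
    }
})

test_that("a planted disappearance is called at the right week", {
    base <- generateBaseCloud(simulationConfig(nNeurons = 60, seed = 64))
    mkWeek <- function(w, drop = integer(0)) {
        keep <- setdiff(seq_len(60), drop)
        SessionCloud(coords(base)[keep, ], neuronId = keep, week = w,
            bounds = cloudBounds(base))
    }
    sessions <- list(mkWeek(1), mkWeek(2), mkWeek(3, drop = 7),
        mkWeek(4, drop = 7))
    tr <- buildTracks(sessions)
    expect_equal(sum(fates(tr) == "disappeared"), 1L)
    i <- which(fates(tr) == "disappeared")
    expect_equal(deathWeeks(tr)[i], 3L)
})

test_that("a transiently invisible neuron is ambiguous, not dead", {
    base <- generateBaseCloud(simulationConfig(nNeurons = 50, seed = 65))
    mkWeek <- function(w, drop = integer(0)) {
        keep <- setdiff(seq_len(50), drop)
        SessionCloud(coords(base)[keep, ], neuronId = keep, week = w,
            bounds = cloudBounds(base))
    }
    sessions <- list(mkWeek(1), mkWeek(2, drop = 9), mkWeek(3), mkWeek(4))
    tr <- buildTracks(sessions)
    i <- which(tr@sourceId == 9)
    expect_equal(fates(tr)[i], "ambiguous")
    expect_equal(sum(fates(tr) == "disappeared"), 0L)
})

test_that("an all-persist simulation yields zero called deaths", {
    sim <- cleanSim(n = 250, seed = 66, hazardNontangle = 0,
        hazardTangle = 0)
    tr <- buildTracks(sim$sessions)
    expect_equal(sum(fates(tr) == "disappeared"), 0L)
    expect_equal(sum(fates(tr) == "ambiguous"), 0L)
})

test_that("called fates agree with the simulation truth at default noise", {
    nOK <- 0L; nTot <- 0L
    for (s in 71:73) {
        sim <- simulateLongitudinal(simulationConfig(nNeurons = 1500,
            seed = s))
        res <- runPipeline(sim$sessions)
        tr <- res$tracks
        truth <- sim$truth$fates
        m <- match(tr@sourceId, truth$neuron_id)
        keep <- fates(tr) != "ambiguous" & !is.na(m)
        ok <- (fates(tr) == "persisted" & truth$fate[m] == "persist") |
              (fates(tr) == "disappeared" & truth$fate[m] == "die" &
               deathWeeks(tr) == truth$death_week[m])
        nOK <- nOK + sum(ok[keep]); nTot <- nTot + sum(keep)
    }
    expect_gte(nOK / nTot, 0.98)
})

test_that("death counts are invariant under a global rigid motion", {
    sim <- cleanSim(n = 300, seed = 74, hazardNontangle = 0.06,
        hazardTangle = 0.06)
    tr1 <- buildTracks(sim$sessions)
    tf <- SimilarityTransform(1, rotationAboutZ(0.4), c(30, -12, 5))
    moved <- lapply(sim$sessions, applyTransform, transform = tf)
    tr2 <- buildTracks(moved)
    expect_equal(table(fates(tr2)), table(fates(tr1)))
    expect_equal(sort(deathWeeks(tr2)), sort(deathWeeks(tr1)))
})

test_that("tangle objects are filtered at the 100-voxel cutoff", {
    obj <- data.frame(voxel_count = c(99L, 100L, 250L))
    kept <- filterTangleObjects(obj, defaultVoxelSize())
    expect_equal(kept$voxel_count, c(100L, 250L))
    # 100 voxels at the imaging geometry is ~49 um^3
    expect_equal(round(kept$volume_um3[1]), 49)
    expect_error(filterTangleObjects(obj), "voxelSize")
})

test_that("labelled stacks keep exactly the components above the cutoff", {
    st <- array(0, c(100, 8, 8))
    sizes <- c(60, 70, 80, 90, 99, 100, 120, 150, 180, 190)
    x0 <- 1
    for (s in sizes) {
        # a connected component of exactly s voxels: the column-major
        # prefix of a 7 x 5 x 6 sub-box
        block <- array(0, c(7, 5, 6))
        block[seq_len(s)] <- 1
        st[x0:(x0 + 6), 1:5, 1:6] <- block
        x0 <- x0 + 9
    }
    lab <- labelStack(st, 0)
    obj <- tangleObjectsFromLabels(lab, defaultVoxelSize())
    expect_equal(sort(obj$voxel_count), sort(sizes))
    kept <- filterTangleObjects(obj, defaultVoxelSize())
    expect_equal(nrow(kept), 5L)
})

test_that("tangle status is assigned from nearby objects at onset week", {
    base <- generateBaseCloud(simulationConfig(nNeurons = 40, seed = 75))
    sessions <- lapply(1:4, function(w)
        SessionCloud(coords(base), neuronId = 1:40, week = w,
            bounds = cloudBounds(base)))
    tr <- buildTracks(sessions)
    expect_true(all(is.na(tangleOnsets(assignTangleStatus(tr,
        data.frame(week = integer(), x_um = numeric(), y_um = numeric(),
            z_um = numeric()))))))
    target <- coords(base)[5, ]
    tangles <- data.frame(week = 3L, x_um = target[1] + 2,
        y_um = target[2], z_um = target[3])
    tr2 <- assignTangleStatus(tr, tangles, radiusUm = 10)
    i <- which(tr@sourceId == 5)
    expect_equal(tangleOnsets(tr2)[i], 3L)
    expect_equal(sum(everTangled(tr2)), 1L)
})

test_that("ever-tangled bookkeeping reconciles initial plus new tangles", {
    sim <- cleanSim(n = 600, seed = 76, pTangleInit = 0.1, tangleRate = 0.03)
    tr <- buildTracks(sim$sessions)
    cc <- tangleCounts(tr)
    expect_equal(cc$initial + cc$new, cc$ever)
    expect_equal(cc$ever, sum(everTangled(tr)))
    expect_gt(cc$new, 0)
})
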