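test_that("base clouds respect the hard core, the bounds, and the seed", {
    cfg <- simulationConfig(nNeurons = 400, seed = 5)
    cl <- generateBaseCloud(cfg)
    X <- coords(cl)
    expect_equal(nrow(X), 400)
    expect_true(all(X >= 0) && all(X <= rep(cfg$bounds, each = 400)))
    D <- as.matrix(dist(X)); diag(D) <- Inf
    expect_gte(min(D), cfg$minSeparation)
    # determinism
    expect_identical(coords(generateBaseCloud(cfg)), X)
    # two-point invariant case
    tiny <- generateBaseCloud(simulationConfig(nNeurons = 2, seed = 1))
    expect_gte(dist(coords(tiny))[1], 12)
})

test_that("infeasible densities fail with an explicit packing error", {
    expect_error(
        generateBaseCloud(simulationConfig(nNeurons = 500,
            bounds = c(40, 40, 40), seed = 1)),
        "packing failure")
})

test_that("mean 3-NN distance at the default density brackets the cortical scale", {
    # ~1500 nuclei in 509 x 509 x 200 um: Poisson closed form gives d3 ~23.4
    # um, hard core slightly more; persisting-neuron distances sit in between
    cl <- generateBaseCloud(simulationConfig(seed = 2))
    d3 <- mean(knnMeanDistance(cl))
    expect_gt(d3, 20)
    expect_lt(d3, 28)
})

test_that("null hazards give no disappearances and no displacement", {
    sim <- cleanSim(n = 200, seed = 3, hazardNontangle = 0, hazardTangle = 0)
    expect_true(all(sim$truth$fates$fate == "persist"))
    expect_equal(length(sim$sessions), 4L)
    # static cloud across weeks (identity transforms, no jitter, no deaths)
    for (w in 2:4)
        expect_equal(coords(sim$sessions[[w]]), coords(sim$sessions[[1]]))
})

test_that("pooled loss under constant hazard matches the geometric closed form", {
    h <- 0.036
    died <- 0L; total <- 0L; perSeed <- numeric(0)
    for (s in 1:8) {
        sim <- simulateLongitudinal(simulationConfig(nNeurons = 600,
            seed = s, hazardNontangle = h, hazardTangle = 0.01,
            pTangleInit = 0, tangleRate = 0))
        f <- sim$truth$fates
        nonFid <- !f$fiducial
        died <- died + sum(f$fate[nonFid] == "die")
        total <- total + sum(nonFid)
        perSeed <- c(perSeed, mean(f$fate[nonFid] == "die"))
    }
    expected <- 1 - (1 - h)^3
    mcSd <- sd(perSeed) / sqrt(length(perSeed))
    expect_lt(abs(died / total - expected), 3 * mcSd + 1e-12)
})

test_that("fiducials never die and cover upper and lower halves of the field", {
    sim <- cleanSim(n = 400, seed = 7)
    f <- sim$truth$fates
    fid <- f[f$fiducial, ]
    expect_equal(nrow(fid), 8L)
    expect_true(all(fid$fate == "persist"))
    z <- sim$truth$basePositions[fid$neuron_id, 3]
    expect_equal(sum(z < 100), 4L)
})

test_that("dying neurons' neighbour tetrahedra grow by the planted percentage", {
    sim <- cleanSim(n = 1500, seed = 13)
    tr <- buildTracks(sim$sessions)
    dvc <- dyingVolumeChanges(tr)
    d <- dvc$pct_change[dvc$fate == "disappeared"]
    expect_gte(length(d), 30)
    expect_lt(abs(median(d) - 29.5), 1)
    expect_lt(abs(mean(d) - 29.5), 5)
    expect_lt(abs(mean(dvc$pct_change[dvc$fate == "persisted"])), 5)
})

test_that("the hazard change point halves the weekly loss rate", {
    ratios <- numeric(0)
    for (s in 1:4) {
        sim <- simulateLongitudinal(simulationConfig(nNeurons = 1000,
            nWeeks = 8, seed = s, pTangleInit = 0, tangleRate = 0,
            hazardChangeWeek = 5, hazardChangeFactor = 0.5))
        dW <- sim$truth$fates$death_week
        atr <- sapply(2:8, function(w) 1000 - sum(!is.na(dW) & dW < w))
        die <- sapply(2:8, function(w) sum(!is.na(dW) & dW == w))
        rate <- die / atr
        ratios <- c(ratios, mean(rate[4:7]) / mean(rate[1:3]))
    }
    mcSd <- sd(ratios) / sqrt(length(ratios))
    expect_lt(abs(mean(ratios) - 0.5), 3 * mcSd + 0.05)
})

test_that("snapshot planting is recovered and the null cloud stays quiet", {
    # null: no planted enlargement -> intrinsic false-positive rate below
    # 0.5%; the handful of extra flags sit in edge-clipped records (the
    # focal's d3 inflates more than the local mean at box corners), which
    # the small test box over-represents relative to a thick section
    snap0 <- generateSnapshot(snapshotConfig(nNeurons = 8000,
        bounds = c(900, 900, 400), enlargedFraction = 0, seed = 21))
    mt0 <- microstructureTable(snap0$cloud)
    interior0 <- mt0[!mt0$edge_flag, ]
    expect_lte(length(flagEnlarged(interior0)) / nrow(interior0), 0.005)
    expect_lte(length(flagEnlarged(mt0)) / 8000, 0.01)
    # planted 2% at desk scale
    snap <- generateSnapshot(snapshotConfig(nNeurons = 8000,
        bounds = c(900, 900, 360), seed = 22))
    mt <- microstructureTable(snap$cloud)
    fl <- flagEnlarged(mt)
    frac <- length(fl) / 8000
    expect_gte(frac, 0.015)
    expect_lte(frac, 0.025)
    expect_gte(mean(snap$truth$enlargedId %in% fl), 0.8)
    # tangle-negative share among planted enlarged neurons ~90.7%
    tgl <- tangleFlags(snap$cloud)[snap$truth$enlargedId]
    expect_lt(abs(mean(!tgl) - 0.907), 0.06)
    # determinism
    snapB <- generateSnapshot(snapshotConfig(nNeurons = 8000,
        bounds = c(900, 900, 360), seed = 22))
    expect_identical(coords(snapB$cloud), coords(snap$cloud))
})

test_that("rendered stacks place one blob per nucleus and detect back", {
    emptyCl <- SessionCloud(matrix(numeric(0), 0, 3),
        bounds = cbind(lo = c(0, 0, 0), hi = c(50, 50, 20)))
    expect_true(all(renderStack(emptyCl, c(1, 1, 2)) == 0))
    oneCl <- SessionCloud(matrix(c(25, 25, 10), 1),
        bounds = cbind(lo = c(0, 0, 0), hi = c(50, 50, 20)))
    st1 <- renderStack(oneCl, c(1, 1, 2), psfSd = 2)
    peak <- which(st1 == max(st1), arr.ind = TRUE)[1, ]
    expect_equal(unname(peak[1:2]), c(25, 25), tolerance = 1)
    # 50 nuclei: >= 95% of centroids recovered within 2 um
    set.seed(31)
    cl <- SessionCloud(neurofate:::.hardcoreCloud(50, c(100, 100, 60), 12),
        bounds = cbind(lo = c(0, 0, 0), hi = c(100, 100, 60)))
    st <- renderStack(cl, c(1, 1, 2), psfSd = 2)
    det <- detectBlobs(st, c(1, 1, 2))
    nn <- neurofate:::.nnWithin(coords(cl),
        as.matrix(det[, c("x_um", "y_um", "z_um")]))
    expect_gte(mean(nn$dist <= 2), 0.95)
})

test_that("stacks round-trip through multi-page TIFF", {
    set.seed(5)
    st <- array(runif(20 * 15 * 4), c(20, 15, 4))
    path <- withr::local_tempfile(fileext = ".tif")
    writeStackTiff(st, path)
    back <- readStackTiff(path)
    expect_equal(dim(back), dim(st))
    expect_equal(back, st / max(st), tolerance = 1e-6)
})

test_that("invalid configurations are rejected with named fields", {
    expect_error(simulationConfig(hazardNontangle = 1.2), "hazardNontangle")
    expect_error(simulationConfig(rampWeeks = 4, nWeeks = 4), "rampWeeks")
    expect_error(simulationConfig(minSeparation = 0), "minSeparation")
    expect_error(snapshotConfig(enlargedFraction = 2), "enlargedFraction")
})
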