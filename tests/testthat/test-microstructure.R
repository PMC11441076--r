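test_that("knnMeanDistance matches symmetry and the brute-force oracle", {
    X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
    expect_equal(knnMeanDistance(X, focal = 1), 1)
    expect_error(knnMeanDistance(X[1:3, ]), "at least 4")
    set.seed(81)
    Y <- matrix(runif(600, 0, 100), ncol = 3)
    expect_equal(knnMeanDistance(Y), bruteD3(Y), tolerance = 1e-12)
    # degree-1 homogeneity under isotropic scaling
    expect_equal(knnMeanDistance(2.5 * Y), 2.5 * knnMeanDistance(Y),
        tolerance = 1e-9)
})

test_that("enlargement is near zero inside a regular grid", {
    g <- as.matrix(expand.grid(x = seq(0, 180, 20), y = seq(0, 180, 20),
        z = seq(0, 80, 20)))
    cl <- SessionCloud(g, bounds = cbind(lo = c(0, 0, 0),
        hi = c(180, 180, 80)))
    mt <- microstructureTable(cl)
    interior <- !mt$edge_flag
    # the 100 um ball exceeds the slab depth, so use all records but demand
    # tight concentration around zero
    expect_lt(max(abs(mt$enlargement), na.rm = TRUE), 0.25)
    expect_lt(abs(mean(mt$enlargement, na.rm = TRUE)), 0.05)
})

test_that("a planted rarefied neuron exceeds the 60% cutoff", {
    set.seed(82)
    X <- neurofate:::.hardcoreCloud(1200, c(400, 400, 200), 12)
    focal <- which.min(colSums((t(X) - c(200, 200, 100))^2))
    d <- sqrt(colSums((t(X) - X[focal, ])^2))
    push <- which(d > 0 & d < 50)
    X[push, ] <- X[focal, ] + 2 * (X[push, ] - rep(X[focal, ], each = length(push)))
    cl <- SessionCloud(X, bounds = cbind(lo = c(0, 0, 0),
        hi = c(400, 400, 200)))
    mt <- microstructureTable(cl)
    expect_gt(mt$enlargement[focal], 0.60)
    expect_true(focal %in% flagEnlarged(mt))
    # brute-force check of the record itself
    d3b <- bruteD3(X)
    D <- as.matrix(dist(X)); diag(D) <- Inf
    lm <- mean(d3b[D[focal, ] <= 100])
    expect_equal(mt$enlargement[focal], unname(d3b[focal] / lm - 1),
        tolerance = 1e-9)
})

test_that("enlargement is invariant to rigid motion and scaling; flag is strict", {
    set.seed(83)
    X <- matrix(runif(450, 0, 120), ncol = 3)
    cl <- SessionCloud(X, bounds = cbind(lo = c(0, 0, 0), hi = rep(120, 3)))
    mt <- microstructureTable(cl)
    tf <- SimilarityTransform(3, rotationAboutZ(0.7), c(40, 50, 60))
    cl2 <- applyTransform(cl, tf)
    mt2 <- microstructureTable(cl2, radiusUm = 300)  # radius scales too
    expect_equal(mt2$enlargement, mt$enlargement, tolerance = 1e-9)
    # strict inequality at the threshold
    rec <- data.frame(neuron_id = 1:3, enlargement = c(0.60, 0.61, NA))
    expect_equal(flagEnlarged(rec), 2L)
})

test_that("records below minLocal are emitted with NA, not dropped", {
    X <- rbind(matrix(runif(30, 0, 30), ncol = 3),
               c(500, 500, 500) + matrix(runif(12, 0, 10), ncol = 3))
    cl <- SessionCloud(X, bounds = cbind(lo = c(0, 0, 0), hi = rep(520, 3)))
    mt <- microstructureTable(cl, minLocal = 5)
    expect_equal(nrow(mt), nrow(X))
    expect_true(any(is.na(mt$enlargement)))
})

test_that("persistent-neighbour selection equals the filter-and-sort oracle", {
    sim <- cleanSim(n = 300, seed = 84, hazardNontangle = 0.08,
        hazardTangle = 0.08)
    tr <- buildTracks(sim$sessions)
    dy <- which(fates(tr) == "disappeared" & firstWeeks(tr) == 1L)[1:5]
    persistent <- which(fates(tr) == "persisted" & firstWeeks(tr) == 1L)
    P <- trackPositions(tr)[, , 1]
    for (i in dy) {
        got <- selectPersistentNeighbors(tr, trackIds(tr)[i])
        d <- sqrt(colSums((t(P[persistent, ]) - P[i, ])^2))
        want <- trackIds(tr)[persistent[order(d)[1:4]]]
        expect_equal(sort(got), sort(want))
        # the nearest overall neighbour may be dying: it must be skipped
        expect_false(trackIds(tr)[i] %in% got)
    }
})

test_that("tetraVolume matches the unit case and the Cayley-Menger oracle", {
    expect_equal(tetraVolume(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
        c(0, 0, 1))), 1 / 6)
    expect_warning(v0 <- tetraVolume(rbind(c(0, 0, 0), c(1, 0, 0),
        c(0, 1, 0), c(1, 1, 0))), "degenerate")
    expect_equal(v0, 0)
    set.seed(85)
    for (rep in 1:10) {
        v <- matrix(rnorm(12, sd = 20), ncol = 3)
        expect_equal(tetraVolume(v), cayleyMengerVolume(v),
            tolerance = 1e-9)
    }
    # degree-3 homogeneity
    v <- matrix(runif(12, 0, 10), ncol = 3)
    expect_equal(tetraVolume(1.7 * v), 1.7^3 * tetraVolume(v),
        tolerance = 1e-9)
})

test_that("volume change percent follows the cubic scaling law", {
    expect_equal(volumeChangePercent(c(1000, 1000, 1000)), 0)
    v <- matrix(runif(12, 0, 30), ncol = 3)
    ratio <- tetraVolume(1.1 * v) / tetraVolume(v)
    expect_equal(100 * (ratio - 1), 33.1, tolerance = 1e-9)
    expect_error(volumeChangePercent(c(1000)), "at least 2")
    expect_error(volumeChangePercent(c(0, 10)), "zero")
})

test_that("volumeToDistanceEquivalent reproduces the printed conversion", {
    expect_equal(round(volumeToDistanceEquivalent(29.5, 24.0), 1), 2.2)
    expect_equal(volumeToDistanceEquivalent(0, 17), 0)
    expect_equal(volumeToDistanceEquivalent(33.1, 10), 1, tolerance = 1e-9)
})

test_that("riskGivenFlag recovers a planted risk fold", {
    mkTracks <- function(died, n) {
        pos <- array(runif(n * 3 * 2), c(n, 3, 2))
        dw <- ifelse(died, 2L, NA_integer_)
        for (i in which(died)) pos[i, , 2] <- NA
        new("NeuronTrackSet", positions = pos, trackId = seq_len(n),
            sourceId = seq_len(n),
            fate = ifelse(died, "disappeared", "persisted"),
            deathWeek = dw, tangleOnset = rep(NA_integer_, n),
            firstWeek = rep(1L, n), nWeeks = 2L)
    }
    # flags identical to the population -> fold exactly 1
    set.seed(86)
    died <- runif(500) < 0.1
    tr <- mkTracks(died, 500)
    r <- riskGivenFlag(tr, flaggedIds = seq_len(500))
    expect_equal(r$fold, 1)
    # degenerate cases
    expect_message(r0 <- riskGivenFlag(tr, integer(0)), "empty flagged")
    expect_true(is.na(r0$fold))
    trNone <- mkTracks(rep(FALSE, 50), 50)
    expect_message(rn <- riskGivenFlag(trNone, 1:5), "no deaths")
    # planted fold: flagged death probability chosen so that
    # pF / (phi pF + (1 - phi) pU) = 2.75
    phi <- 0.02; pU <- 0.10; pF <- 0.2852
    folds <- replicate(20, {
        n <- 2000
        flagged <- seq_len(round(phi * n))
        p <- rep(pU, n); p[flagged] <- pF
        tr <- mkTracks(runif(n) < p, n)
        riskGivenFlag(tr, flagged)$fold
    })
    mcSd <- sd(folds) / sqrt(length(folds))
    expect_lt(abs(mean(folds) - 2.75), 3 * mcSd + 0.05)
})

test_that("dying neurons start farther from their neighbours than persisters", {
    dd <- c(); pp <- c()
    for (s in 91:93) {
        sim <- cleanSim(n = 700, seed = s)
        tr <- buildTracks(sim$sessions)
        cmp <- dyingVsPersistentD3(tr)
        dd <- c(dd, cmp$perNeuron$d3[cmp$perNeuron$group == "dying"])
        pp <- c(pp, cmp$perNeuron$d3[cmp$perNeuron$group != "dying"])
    }
    expect_gt(mean(dd), mean(pp))
})
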