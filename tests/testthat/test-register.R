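test_that("identical paired points give the identity transform", {
    P <- matrix(runif(24, 0, 100), ncol = 3)
    tf <- estimateTransform(P, P)
    expect_equal(transformScale(tf), 1, tolerance = 1e-12)
    expect_equal(transformRotation(tf), diag(3), tolerance = 1e-12)
    expect_equal(transformTranslation(tf), c(0, 0, 0), tolerance = 1e-9)
})

test_that("a noiseless similarity transform is recovered to 1e-9", {
    set.seed(41)
    for (rep in 1:5) {
        P <- matrix(runif(24, 0, 500), ncol = 3)
        ax <- rnorm(3)
        tf <- SimilarityTransform(runif(1, 0.9, 1.1),
            neurofate:::.axisAngleRotation(ax, runif(1, -0.5, 0.5)),
            runif(3, -50, 50))
        Q <- applyTransform(P, tf)
        est <- estimateTransform(P, Q)
        expect_lt(abs(transformScale(est) - transformScale(tf)), 1e-9)
        expect_lt(max(abs(transformRotation(est) - transformRotation(tf))),
            1e-9)
        expect_lt(max(abs(transformTranslation(est) -
            transformTranslation(tf))), 1e-7)
        expect_lt(registrationReport(est, P, Q)$rms, 1e-9)
    }
    # the specific worked example: s = 1.02, 5 degrees about z, t = (3,-2,1)
    P <- matrix(runif(24, 0, 500), ncol = 3)
    tf <- SimilarityTransform(1.02, rotationAboutZ(5 * pi / 180), c(3, -2, 1))
    est <- estimateTransform(P, applyTransform(P, tf))
    expect_lt(abs(transformScale(est) - 1.02), 1e-9)
    expect_lt(registrationReport(est, P, applyTransform(P, tf))$rms, 1e-9)
})

test_that("0.25 um fiducial jitter keeps the RMS residual within ~2 voxels", {
    set.seed(42)
    tf <- SimilarityTransform(1.02, rotationAboutZ(5 * pi / 180), c(3, -2, 1))
    rms <- replicate(30, {
        P <- matrix(runif(24, 0, 500), ncol = 3)
        Q <- applyTransform(P, tf) + matrix(rnorm(24, sd = 0.25), ncol = 3)
        registrationReport(estimateTransform(P, Q), P, Q)$rms
    })
    expect_true(all(rms <= 1.0))
})

test_that("degenerate fiducial sets are rejected", {
    line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
    expect_error(estimateTransform(line, line + 1), "collinear")
    expect_error(estimateTransform(line[1:2, ], line[1:2, ]), "3 fiducial")
})

test_that("the estimated rotation is proper even for reflected input", {
    set.seed(43)
    P <- matrix(runif(30, 0, 100), ncol = 3)
    Q <- P
    Q[, 1] <- -Q[, 1]    # reflection cannot be represented
    est <- estimateTransform(P, Q)
    expect_equal(det(transformRotation(est)), 1, tolerance = 1e-9)
})

test_that("the fit agrees with vegan's procrustes solution", {
    set.seed(44)
    P <- matrix(runif(36, 0, 100), ncol = 3)
    tf <- SimilarityTransform(1.05,
        neurofate:::.axisAngleRotation(c(1, 2, 3), 0.3), c(5, -8, 2))
    Q <- applyTransform(P, tf) + matrix(rnorm(36, sd = 0.3), ncol = 3)
    est <- estimateTransform(P, Q)
    pr <- vegan::procrustes(Q, P)
    # vegan works on centred configurations; compare after centring
    centre <- function(M) sweep(M, 2, colMeans(M))
    expect_equal(centre(applyTransform(P, est)), centre(unclass(pr$Yrot)),
        tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("residual RMS is invariant to the ordering of fiducial pairs", {
    set.seed(45)
    P <- matrix(runif(24, 0, 500), ncol = 3)
    Q <- applyTransform(P, SimilarityTransform(1.01, rotationAboutZ(0.05),
        c(1, 2, 3))) + matrix(rnorm(24, sd = 0.3), ncol = 3)
    r1 <- registrationReport(estimateTransform(P, Q), P, Q)$rms
    o <- sample(8)
    r2 <- registrationReport(estimateTransform(P[o, ], Q[o, ]),
        P[o, ], Q[o, ])$rms
    expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("applyTransform maps points exactly and composes with its inverse", {
    P <- matrix(runif(30, 0, 100), ncol = 3)
    shift <- SimilarityTransform(translation = c(10, 0, 0))
    expect_equal(applyTransform(P, shift), P + rep(c(10, 0, 0), each = 10))
    expect_equal(applyTransform(P, identityTransform()), P)
    tf <- SimilarityTransform(1.3, rotationAboutZ(1), c(4, 5, 6))
    back <- applyTransform(applyTransform(P, tf), invertTransform(tf))
    expect_equal(back, P, tolerance = 1e-9)
    # pairwise distances scale exactly by s
    expect_equal(as.vector(dist(applyTransform(P, tf))),
        as.vector(1.3 * dist(P)), tolerance = 1e-12)
    # labels preserved on clouds
    cl <- SessionCloud(P, tangle = rep(c(TRUE, FALSE), 5),
        bounds = cbind(lo = c(0, 0, 0), hi = c(100, 100, 100)))
    expect_identical(tangleFlags(applyTransform(cl, tf)), tangleFlags(cl))
})

test_that("cropToOverlap matches per-point membership in the intersection", {
    mk <- function(lo, hi, n = 150, seed = 1) {
        set.seed(seed)
        SessionCloud(sweep(sweep(matrix(runif(3 * n), ncol = 3), 2,
            hi - lo, "*"), 2, lo, "+"),
            bounds = cbind(lo = lo, hi = hi))
    }
    # identical bounds: unchanged
    a <- mk(c(0, 0, 0), c(1, 1, 1), seed = 2)
    expect_equal(length(cropToOverlap(list(a, a))[[1]]), length(a))
    # two unit boxes offset by half a side
    b <- mk(c(0.5, 0, 0), c(1.5, 1, 1), seed = 3)
    cr <- cropToOverlap(list(a, b))
    expect_equal(unname(cloudBounds(cr[[1]])[, 1]), c(0.5, 0, 0))
    expect_true(all(coords(cr[[1]])[, 1] >= 0.5))
    # random boxes: retention equals the brute-force membership test
    set.seed(46)
    clouds <- lapply(1:3, function(i)
        mk(runif(3, 0, 0.3), runif(3, 0.7, 1.2), seed = 40 + i))
    lo <- apply(sapply(clouds, function(s) cloudBounds(s)[, 1]), 1, max)
    hi <- apply(sapply(clouds, function(s) cloudBounds(s)[, 2]), 1, min)
    cr <- cropToOverlap(clouds)
    for (i in 1:3) {
        X <- coords(clouds[[i]])
        inside <- X[, 1] >= lo[1] & X[, 1] <= hi[1] &
                  X[, 2] >= lo[2] & X[, 2] <= hi[2] &
                  X[, 3] >= lo[3] & X[, 3] <= hi[3]
        expect_equal(sort(neuronIds(cr[[i]])),
                     sort(neuronIds(clouds[[i]])[inside]))
    }
    # disjoint boxes: explicit error
    far <- mk(c(5, 5, 5), c(6, 6, 6), seed = 9)
    expect_error(cropToOverlap(list(a, far)), "empty overlap")
})

test_that("registerSessions brings misaligned sessions back to the reference", {
    sim <- simulateLongitudinal(simulationConfig(nNeurons = 300, seed = 51,
        jitterSd = 0.3))
    reg <- registerSessions(sim$sessions)
    # estimated transforms invert the true session transforms
    for (w in 2:4) {
        est <- reg$transforms[[w]]
        tru <- sim$truth$transforms[[w]]
        comp <- transformScale(est) * transformScale(tru)
        expect_equal(comp, 1, tolerance = 0.01)
        expect_lte(reg$reports[[w]]$rms, 1.5)  # ~3x the 0.3 um jitter
    }
    # transforms serialise losslessly
    path <- withr::local_tempfile(fileext = ".json")
    writeTransform(reg$transforms[[2]], path)
    back <- readTransform(path)
    expect_equal(transformRotation(back),
        transformRotation(reg$transforms[[2]]), tolerance = 1e-12)
})
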