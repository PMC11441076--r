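# Shared fixtures: small, fast configurations built in code.

identityTransforms <- function(n) replicate(n, identityTransform())

# a small, clean longitudinal simulation (no misalignment, no jitter)
cleanSim <- function(n = 300, seed = 11, ...) {
    simulateLongitudinal(simulationConfig(nNeurons = n, seed = seed,
        jitterSd = 0, sessionTransforms = identityTransforms(4), ...))
}

# brute-force mean k-NN distance from the full distance matrix
bruteD3 <- function(X, k = 3) {
    D <- as.matrix(dist(X))
    diag(D) <- Inf
    unname(apply(D, 1, function(r) mean(sort(r)[seq_len(k)])))
}

# brute-force mutual nearest neighbours with a gate
bruteMutualNN <- function(A, B, gate) {
    D <- matrix(NA_real_, nrow(A), nrow(B))
    for (i in seq_len(nrow(A)))
        D[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
    fw <- apply(D, 1, which.min)
    bw <- apply(D, 2, which.min)
    i <- seq_len(nrow(A))
    mutual <- bw[fw] == i & D[cbind(i, fw)] <= gate
    cbind(refIdx = i[mutual], queryIdx = fw[mutual])
}

# Cayley-Menger determinant volume of a tetrahedron (independent formula)
cayleyMengerVolume <- function(v) {
    d2 <- as.matrix(dist(v))^2
    cm <- rbind(c(0, 1, 1, 1, 1), cbind(1, d2))
    sqrt(max(0, det(cm) / 288))
}
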