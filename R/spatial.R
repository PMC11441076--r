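# Internal chunked spatial queries. Brute-force distances computed block by
# block so memory stays O(block * n); adequate for the package's desk scales
# (n up to a few 1e4).

.pairDist2 <- function(A, B) {
    # squared Euclidean distances, |A| x |B|
    ra <- rowSums(A * A)
    rb <- rowSums(B * B)
    d2 <- tcrossprod(A, B)
    d2 <- (ra - 2 * d2) + rep(rb, each = nrow(A))
    d2[d2 < 0] <- 0
    d2
}

.knnAndLocal <- function(X, k = 3L, radius = 100, block = 1024L) {
    # One O(n^2) pass: for every point, the mean distance to its k nearest
    # neighbours (d3) plus, reusing the same neighbour lists, the mean d3 of
    # all other points within `radius` (inclusive). Points with fewer than k
    # neighbours inside the radius fall back to a full-row scan.
    n <- nrow(X)
    if (n < k + 1L)
        stop(sprintf("need at least %d points for k = %d neighbours", k + 1L, k))
    r2 <- radius^2
    d3 <- numeric(n)
    nbI <- vector("list", ceiling(n / block))
    nbJ <- vector("list", length(nbI))
    bi <- 0L
    for (s in seq.int(1L, n, by = block)) {
        e <- min(s + block - 1L, n)
        nb <- e - s + 1L
        d2 <- .pairDist2(X[s:e, , drop = FALSE], X)
        d2[cbind(seq_len(nb), s:e)] <- Inf
        wh <- which(d2 <= r2)
        rows <- ((wh - 1L) %% nb) + 1L
        vals <- d2[wh]
        byRow <- split(vals, factor(rows, levels = seq_len(nb)))
        for (i in seq_len(nb)) {
            v <- byRow[[i]]
            if (length(v) >= k) {
                d3[s + i - 1L] <- mean(sqrt(sort(
                    v, partial = seq_len(min(k, length(v))))[seq_len(k)]))
            } else {
                v2 <- d2[i, ]
                d3[s + i - 1L] <- mean(sqrt(sort(
                    v2, partial = seq_len(k))[seq_len(k)]))
            }
        }
        bi <- bi + 1L
        nbI[[bi]] <- rows + (s - 1L)
        nbJ[[bi]] <- ((wh - 1L) %/% nb) + 1L
    }
    I <- unlist(nbI, use.names = FALSE)
    J <- unlist(nbJ, use.names = FALSE)
    nLocal <- tabulate(I, nbins = n)
    sums <- rowsum(d3[J], group = I, reorder = FALSE)
    localMean <- rep(NA_real_, n)
    localMean[as.integer(rownames(sums))] <- sums[, 1]
    localMean <- ifelse(nLocal > 0, localMean / nLocal, NA_real_)
    list(d3 = d3, localMean = localMean, nLocal = nLocal)
}

.knnDist <- function(X, k, block = 512L) {
    # n x k matrix of distances to the k nearest other points, sorted
    # ascending; ties broken by row order (smaller index first).
    n <- nrow(X)
    if (n < k + 1L)
        stop(sprintf("need at least %d points for k = %d neighbours", k + 1L, k))
    out <- matrix(NA_real_, n, k)
    for (s in seq.int(1L, n, by = block)) {
        e <- min(s + block - 1L, n)
        d2 <- .pairDist2(X[s:e, , drop = FALSE], X)
        d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
        if (k <= 8L) {
            # successive row-minima (C-level) beat per-row sorts
            rows <- seq_len(e - s + 1L)
            for (j in seq_len(k)) {
                jm <- max.col(-d2, ties.method = "first")
                out[s:e, j] <- d2[cbind(rows, jm)]
                d2[cbind(rows, jm)] <- Inf
            }
        } else {
            for (i in seq_len(e - s + 1L)) {
                v <- d2[i, ]
                out[s + i - 1L, ] <-
                    sort(sort(v, partial = seq_len(k))[seq_len(k)])
            }
        }
    }
    sqrt(out)
}

.radiusStats <- function(X, values, radius, block = 512L) {
    # For each point, mean of `values` over other points within `radius`
    # (inclusive), and the neighbour count.
    n <- nrow(X)
    r2 <- radius^2
    localMean <- numeric(n)
    nLocal <- integer(n)
    for (s in seq.int(1L, n, by = block)) {
        e <- min(s + block - 1L, n)
        d2 <- .pairDist2(X[s:e, , drop = FALSE], X)
        d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
        inR <- d2 <= r2
        cnt <- rowSums(inR)
        sm <- as.vector(inR %*% values)
        nLocal[s:e] <- cnt
        localMean[s:e] <- ifelse(cnt > 0, sm / cnt, NA_real_)
    }
    list(localMean = localMean, nLocal = nLocal)
}

.tetraVol <- function(v) {
    # unchecked tetrahedron volume (internal; no degeneracy warning)
    abs(det(sweep(v[2:4, , drop = FALSE], 2, v[1, ]))) / 6
}

.nnWithin <- function(A, B, block = 512L) {
    # For each row of A: index in B of nearest row, plus the distance.
    idx <- integer(nrow(A))
    dst <- numeric(nrow(A))
    for (s in seq.int(1L, nrow(A), by = block)) {
        e <- min(s + block - 1L, nrow(A))
        d2 <- .pairDist2(A[s:e, , drop = FALSE], B)
        j <- max.col(-d2, ties.method = "first")
        idx[s:e] <- j
        dst[s:e] <- sqrt(d2[cbind(seq_len(e - s + 1L), j)])
    }
    list(index = idx, dist = dst)
}
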