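#' Render a cloud as a 3D intensity stack
#'
#' One isotropic (in um) Gaussian blob per nucleus, sampled on the voxel
#' grid; a fixture generator for testing blob detection, not a photon-level
#' microscope model. Stack dimensions follow `ceiling(bounds / voxelSize)`.
#'
#' @param cloud a [SessionCloud-class].
#' @param voxelSize um per voxel (3-vector).
#' @param psfSd Gaussian SD in um.
#' @param cutoffSd blob support radius in SDs.
#' @return numeric 3D array (x, y, z).
#' @examples
#' cl <- SessionCloud(matrix(c(25, 25, 25), 1), bounds = cbind(0, c(50, 50, 50)))
#' st <- renderStack(cl, voxelSize = c(1, 1, 2), psfSd = 2)
#' which(st == max(st), arr.ind = TRUE)
#' @export
renderStack <- function(cloud, voxelSize = c(1, 1, 2), psfSd = 2,
                        cutoffSd = 3) {
    stopifnot(all(voxelSize > 0))
    b <- cloudBounds(cloud)
    ext <- b[, 2] - b[, 1]
    d <- pmax(1L, as.integer(ceiling(ext / voxelSize)))
    stack <- array(0, d)
    X <- sweep(coords(cloud), 2, b[, 1])
    for (i in seq_len(nrow(X))) {
        cv <- X[i, ] / voxelSize + 0.5         # voxel-centre coordinates
        rad <- ceiling(cutoffSd * psfSd / voxelSize)
        rng <- lapply(1:3, function(ax)
            max(1L, floor(cv[ax] - rad[ax])):min(d[ax], ceiling(cv[ax] + rad[ax])))
        if (any(vapply(rng, length, 0L) == 0L)) next
        gx <- exp(-((rng[[1]] - cv[1]) * voxelSize[1])^2 / (2 * psfSd^2))
        gy <- exp(-((rng[[2]] - cv[2]) * voxelSize[2])^2 / (2 * psfSd^2))
        gz <- exp(-((rng[[3]] - cv[3]) * voxelSize[3])^2 / (2 * psfSd^2))
        stack[rng[[1]], rng[[2]], rng[[3]]] <-
            stack[rng[[1]], rng[[2]], rng[[3]]] + outer(outer(gx, gy), gz)
    }
    stack
}

#' Detect blobs in a 3D stack
#'
#' Thresholds at `threshold * max(stack)`, labels 6-connected components
#' ([labelStack()]), and returns intensity-weighted centroids in um.
#'
#' @param stack numeric 3D array.
#' @param voxelSize um per voxel (3-vector).
#' @param threshold relative intensity threshold in (0, 1).
#' @return data.frame with `label`, `x_um`, `y_um`, `z_um`, `voxel_count`,
#'   `intensity`.
#' @export
detectBlobs <- function(stack, voxelSize = c(1, 1, 2), threshold = 0.2) {
    mx <- max(stack)
    if (mx <= 0)
        return(data.frame(label = integer(), x_um = numeric(),
            y_um = numeric(), z_um = numeric(), voxel_count = integer(),
            intensity = numeric()))
    lab <- labelStack(stack, threshold * mx)
    fg <- which(lab > 0L)
    vox <- arrayInd(fg, dim(stack))
    lb <- lab[fg]
    wt <- stack[fg]
    ulb <- sort(unique(lb))
    rows <- lapply(ulb, function(l) {
        sel <- lb == l
        v <- vox[sel, , drop = FALSE]
        w <- wt[sel]
        cen <- (colSums(v * w) / sum(w) - 0.5) * voxelSize
        data.frame(label = l, x_um = cen[1], y_um = cen[2], z_um = cen[3],
            voxel_count = sum(sel), intensity = sum(w))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Write / read a stack as multi-page TIFF
#'
#' Z-slices become pages; intensities are rescaled to `[0, 1]` on write
#' (32-bit float pages, lossless for the rescaled values).
#'
#' @param stack numeric 3D array (x, y, z).
#' @param path file path.
#' @return `writeStackTiff()` the path invisibly; `readStackTiff()` the
#'   array (x, y, z), values in `[0, 1]`.
#' @export
writeStackTiff <- function(stack, path) {
    mx <- max(stack)
    if (mx > 0) stack <- stack / mx
    pages <- lapply(seq_len(dim(stack)[3]),
        function(z) t(stack[, , z]))   # TIFF rows = y
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    invisible(path)
}

#' @rdname writeStackTiff
#' @export
readStackTiff <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- dim(pages[[1]])
    out <- array(0, c(d[2], d[1], length(pages)))
    for (z in seq_along(pages)) out[, , z] <- t(pages[[z]])
    out
}
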