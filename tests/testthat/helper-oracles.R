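# Shared fixtures and independent oracles, built in code at test time.

# small, fast phantom configuration (coarse grid, same anatomy family)
smallConfig <- function(..., gridShape = c(48L, 48L, 48L), voxelSpacing = 4,
                        tumorDiameter = 24, noiseSD = 0, seed = 1L) {
    phantomConfig(gridShape = gridShape, voxelSpacing = voxelSpacing,
                  tumorDiameter = tumorDiameter, noiseSD = noiseSD,
                  seed = seed, ...)
}

# brute-force fine-step ray marcher: WEPL to each voxel center along an
# axis-aligned parallel beam, sampling the piecewise-constant RSP grid at
# `step` mm resolution (independent of the cumulative-sum engine)
bruteWEPL <- function(rsp, geometry, step = 0.1) {
    v <- voxelValues(rsp)
    d <- dim(v)
    sp <- spacing(rsp)
    ax <- geometry@axis
    sgn <- geometry@direction
    out <- array(NA_real_, d)
    n <- d[ax]
    coords <- (seq_len(n) - 0.5) * sp[ax]
    entry <- if (sgn > 0) 0 else n * sp[ax]
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        target <- coords[switch(ax, i, j, k)]
        len <- abs(target - entry)
        if (len == 0) { out[i, j, k] <- 0; next }
        m <- max(1L, ceiling(len / step))
        s <- entry + sgn * (seq_len(m) - 0.5) * (len / m)
        idx <- pmin(pmax(ceiling(s / sp[ax]), 1L), n)
        line <- switch(ax, v[, j, k], v[i, , k], v[i, j, ])
        out[i, j, k] <- sum(line[idx]) * (len / m) / 10  # cm
    }
    out
}

# exhaustive Dx% oracle: threshold sweep over observed dose values
bruteDoseIndex <- function(doseVals, x) {
    n <- length(doseVals)
    cand <- sort(unique(doseVals), decreasing = TRUE)
    for (d in cand)
        if (sum(doseVals >= d) / n >= x / 100) return(d)
    min(doseVals)
}

# random dose/mask pair on a small grid
randomDoseMask <- function(n = 24, seed = 42) {
    set.seed(seed)
    dose <- DoseVolume(array(runif(n^3, 0, 110), c(n, n, n)),
                       spacing = c(2, 2, 2))
    mask <- MaskVolume(array(runif(n^3) < 0.2, c(n, n, n)),
                       spacing = c(2, 2, 2))
    if (!any(voxelValues(mask))) stop("empty random mask")
    list(dose = dose, mask = mask)
}

# uniform-water RSP volume
waterRSP <- function(n = 32, spacingMM = 2) {
    RSPVolume(array(1, c(n, n, n)), spacing = rep(spacingMM, 3))
}

# box PTV mask spanning index ranges
boxMask <- function(n, xr, yr, zr, spacingMM = 2) {
    m <- array(FALSE, c(n, n, n))
    m[xr, yr, zr] <- TRUE
    MaskVolume(m, spacing = rep(spacingMM, 3))
}
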