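test_that("AVG and MIP reconstructions match per-voxel oracles", {
    set.seed(11)
    sp <- c(4, 4, 4)
    vols <- lapply(1:10, function(i)
        HUVolume(array(runif(6^3, -800, 200), c(6, 6, 6)), spacing = sp))
    masks <- lapply(1:10, function(i) {
        m <- array(FALSE, c(6, 6, 6)); m[3, 3, 3] <- TRUE
        MaskVolume(m, spacing = sp)
    })
    ser <- new("PhaseSeries", phases = vols, gtvMasks = masks,
               phaseLabels = seq(0, 90, 10), amplitude = 0,
               phaseWeights = rep(0.1, 10))
    avg <- voxelValues(averageCT(ser))
    mip <- voxelValues(mipCT(ser))
    # brute-force per-voxel loop
    for (idx in list(c(1, 1, 1), c(2, 5, 3), c(6, 6, 6))) {
        vals <- vapply(vols, function(v)
            voxelValues(v)[idx[1], idx[2], idx[3]], numeric(1))
        expect_equal(avg[idx[1], idx[2], idx[3]], mean(vals))
        expect_equal(mip[idx[1], idx[2], idx[3]], max(vals))
    }
    expect_true(all(mip >= avg))
    # all phases identical => outputs equal any phase
    ser0 <- generatePhantom(smallConfig(amplitude = 0, noiseSD = 0,
                                        gridShape = c(20L, 20L, 20L),
                                        voxelSpacing = 8,
                                        tumorDiameter = 20))
    expect_equal(voxelValues(averageCT(ser0)),
                 voxelValues(phaseVolumes(ser0)[[1]]))
    expect_equal(voxelValues(mipCT(ser0)),
                 voxelValues(phaseVolumes(ser0)[[1]]))
})

test_that("ITV union matches a brute-force OR and handles edge cases", {
    ser <- generatePhantom(smallConfig())
    itv <- voxelValues(buildITV(gtvMasks(ser)))
    ref <- Reduce(`|`, lapply(gtvMasks(ser), voxelValues))
    expect_identical(itv, ref)
    one <- gtvMasks(ser)[[1]]
    expect_identical(voxelValues(buildITV(list(one))), voxelValues(one))
    # disjoint masks: counts add
    a <- boxMask(10, 1:2, 1:2, 1:2); b <- boxMask(10, 8:9, 8:9, 8:9)
    expect_equal(sum(voxelValues(buildITV(list(a, b)))),
                 sum(voxelValues(a)) + sum(voxelValues(b)))
    expect_error(buildITV(list()), "empty")
})

test_that("uniform expansion is an exact Euclidean dilation", {
    # single voxel at 2 mm spacing, 2 mm margin -> center + 6 face neighbours
    m <- boxMask(7, 4, 4, 4, spacingMM = 2)
    ex <- expandUniform(m, 2)
    expect_equal(sum(voxelValues(ex)), 7)
    # margin 0 is the identity
    expect_identical(voxelValues(expandUniform(m, 0)), voxelValues(m))
    # sphere mask: result equals a brute-force distance check
    n <- 16; sp <- 2
    xs <- (seq_len(n) - 0.5) * sp
    d2 <- outer(outer((xs - 16)^2, (xs - 16)^2, `+`), (xs - 16)^2, `+`)
    sph <- MaskVolume(d2 <= 6^2, spacing = rep(sp, 3))
    margin <- 5
    got <- voxelValues(expandUniform(sph, margin))
    centers <- which(voxelValues(sph), arr.ind = TRUE)
    ref <- array(FALSE, c(n, n, n))
    all_idx <- which(!is.na(d2), arr.ind = TRUE)
    for (r in seq_len(nrow(all_idx))) {
        p <- all_idx[r, ]
        dist2 <- (xs[centers[, 1]] - xs[p[1]])^2 +
            (xs[centers[, 2]] - xs[p[2]])^2 +
            (xs[centers[, 3]] - xs[p[3]])^2
        ref[p[1], p[2], p[3]] <- any(dist2 <= margin^2 + 1e-9)
    }
    expect_identical(got, ref)
    expect_error(expandUniform(m, -1), "nonnegative")
})

test_that("structure sets nest GTV within ITV within PTV", {
    ser <- generatePhantom(smallConfig())
    st <- buildStructureSet(ser, ptvMargin = 5)
    itv <- voxelValues(itvMask(st)); ptv <- voxelValues(ptvMask(st))
    for (g in gtvMasks(st))
        expect_true(all(!voxelValues(g) | itv))
    expect_true(all(!itv | ptv))
    expect_equal(st@ptvMargin, 5)
})

test_that("density override fills the PTV and nothing else", {
    ser <- generatePhantom(smallConfig())
    st <- buildStructureSet(ser, 5)
    avg <- averageCT(ser)
    ovr <- overridePTVDensity(avg, st)
    ptv <- voxelValues(ptvMask(st))
    expect_identical(voxelValues(ovr)[!ptv], voxelValues(avg)[!ptv])
    expect_equal(unique(voxelValues(ovr)[ptv]),
                 mean(voxelValues(avg)[voxelValues(itvMask(st))]))
    # explicit override value
    ovr60 <- overridePTVDensity(avg, st, value = 60)
    expect_true(all(voxelValues(ovr60)[ptv] == 60))
    # uniform region overridden by its own mean is unchanged
    u <- HUVolume(array(120, c(10, 10, 10)), spacing = c(4, 4, 4))
    stU <- new("StructureSet",
               gtvMasks = list(boxMask(10, 4:6, 4:6, 4:6, 4)),
               itv = boxMask(10, 4:6, 4:6, 4:6, 4),
               ptv = boxMask(10, 4:6, 4:6, 4:6, 4), ptvMargin = 0)
    expect_equal(voxelValues(overridePTVDensity(u, stU)), voxelValues(u))
})

test_that("gross tumor density measures the tumor, not the smeared track", {
    cfg <- smallConfig(noiseSD = 0)
    ser <- generatePhantom(cfg)
    expect_equal(grossTumorDensity(ser), cfg@huTumor, tolerance = 1e-9)
    # the ITV-mean on the AVG scan is diluted relative to the tumor density
    st <- buildStructureSet(ser, 5)
    itvMean <- mean(voxelValues(averageCT(ser))[voxelValues(itvMask(st))])
    expect_lt(itvMean, cfg@huTumor)
})

test_that("HU to stopping power conversion is anchored and monotone", {
    cal <- defaultCalibration()
    v <- HUVolume(array(c(0, 115, -700, 2000, -1500), c(5, 1, 1)))
    r <- voxelValues(huToRSP(v, cal))
    expect_equal(r[1, 1, 1], 1.0)                       # water anchor
    ratio <- r[2, 1, 1] / r[3, 1, 1]                    # liver vs lung
    expect_gte(ratio, 3); expect_lte(ratio, 4)
    expect_equal(r[4, 1, 1], max(cal@rsp))              # clamped above
    expect_equal(r[5, 1, 1], min(cal@rsp))              # clamped below
    # monotone on a random HU sample
    set.seed(3)
    hu <- sort(runif(50, -1100, 1700))
    rr <- voxelValues(huToRSP(HUVolume(array(hu, c(50, 1, 1))), cal))
    expect_true(all(diff(rr[, 1, 1]) >= 0))
    # geometry preserved
    vol <- HUVolume(array(0, c(3, 4, 5)), spacing = c(1, 2, 3),
                    origin = c(9, 8, 7))
    out <- huToRSP(vol)
    expect_equal(spacing(out), spacing(vol))
    expect_equal(gridOrigin(out), gridOrigin(vol))
    # non-monotone calibration rejected
    expect_error(new("CalibrationCurve", hu = c(-1000, 0, 1600),
                     rsp = c(0.5, 0.3, 1.8)))
})

test_that("calibration curves round-trip through CSV", {
    cal <- defaultCalibration()
    f <- tempfile(fileext = ".csv")
    writeCalibration(cal, f)
    back <- readCalibration(f)
    expect_equal(back@hu, cal@hu)
    expect_equal(back@rsp, cal@rsp)
    unlink(f)
})
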