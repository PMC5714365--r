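test_that("WEPL tracing reproduces water depth and slab arithmetic", {
    n <- 20
    water <- waterRSP(n, 2)
    g <- beamGeometry(180)  # +y
    w <- voxelValues(traceWEPL(water, g))
    # water identity: WEPL equals geometric depth to the voxel center
    expect_equal(w[5, 7, 9], (7 - 0.5) * 0.2, tolerance = 1e-9)
    # slab phantom: 5 cm at RSP 0.3 then 5 cm at RSP 1.05
    v <- array(0.3, c(4, 50, 4)); v[, 26:50, ] <- 1.05
    slab <- RSPVolume(v, spacing = c(2, 2, 2))
    ws <- voxelValues(traceWEPL(slab, beamGeometry(180)))
    # WEPL at the distal face of voxel 50 = 5*0.3 + 5*1.05
    expect_equal(ws[2, 50, 2] + 0.5 * 1.05 * 0.2, 6.75, tolerance = 1e-9)
    # monotone nondecreasing along every ray
    expect_true(all(apply(ws, c(1, 3), function(r) all(diff(r) >= -1e-12))))
})

test_that("WEPL matches a fine-step brute-force ray marcher on random grids", {
    set.seed(7)
    v <- array(runif(12^3, 0.1, 1.6), c(12, 12, 12))
    rsp <- RSPVolume(v, spacing = c(3, 3, 3))
    for (ang in c(0, 90, 180, 270)) {
        g <- beamGeometry(ang)
        fast <- voxelValues(traceWEPL(rsp, g))
        slow <- bruteWEPL(rsp, g, step = 0.1)
        relerr <- max(abs(fast - slow) / pmax(slow, 0.05))
        expect_lt(relerr, 0.01)
    }
})

test_that("aperture design is projection plus Euclidean margin", {
    # sphere radius 2 cm, margin 1 cm -> BEV disk radius 3 cm
    n <- 48; sp <- 2
    xs <- (seq_len(n) - 0.5) * sp
    d2 <- outer(outer((xs - 48)^2, (xs - 48)^2, `+`), (xs - 48)^2, `+`)
    sph <- MaskVolume(d2 <= 20^2, spacing = rep(sp, 3))
    g <- beamGeometry(180)
    ap <- designAperture(sph, g, margin = 1)
    area <- sum(ap) * sp^2            # mm^2
    expect_lt(abs(area - pi * 30^2) / (pi * 30^2), 0.05)
    # margin 0 equals the projection; dilation is a superset
    proj <- designAperture(sph, g, margin = 0)
    expect_equal(sum(proj) * sp^2, pi * 20^2, tolerance = 0.05 * pi * 20^2)
    expect_true(all(proj <= ap))
})

test_that("compensators fit the distal target surface per ray", {
    n <- 56
    water <- waterRSP(n, 2)
    # box PTV with flat distal face at 10 cm depth (y index 50 at 2 mm)
    ptv <- boxMask(n, 12:20, 30:50, 12:20, 2)
    g <- beamGeometry(180)
    comp <- designCompensator(ptv, water, g, R = 12, smoothingMargin = 1)
    inside <- comp[12:20, 12:20]
    expect_true(all(abs(inside - 2) < 1e-9))
    # stepped distal face -> stepped thickness at the same BEV position
    m <- array(FALSE, c(n, n, n)); m[10:20, 30:50, 10:20] <- TRUE
    m[10:14, 51:55, 10:20] <- TRUE              # deeper column: 11 cm
    ptv2 <- MaskVolume(m, spacing = c(2, 2, 2))
    comp2 <- designCompensator(ptv2, water, g, R = 12)
    expect_equal(comp2[12, 15], 1, tolerance = 1e-9)
    expect_equal(comp2[18, 15], 2, tolerance = 1e-9)
    # per-ray identity: WEPL at distal surface + thickness = R
    surf <- proton4d:::raySurfaceWEPL(voxelValues(ptv2), water, g)
    distal <- matrix(surf$distal, n, n)
    crossing <- matrix(surf$crossing, n, n)
    expect_true(all(abs((distal + comp2)[crossing] - 12) < 1e-9))
    # R short of the deepest surface is rejected
    expect_error(designCompensator(ptv2, water, g, R = 10), "infeasible")
})

test_that("field fitting recovers box and sphere geometry", {
    n <- 32
    water <- waterRSP(n, 4)  # 12.8 cm cube
    # box PTV spanning WEPL 6..12 cm along +y
    ptv <- boxMask(n, 10:20, 16:30, 10:20, 4)
    f <- fitField(ptv, water, beamGeometry(180), rangeSpread = 0)
    expect_equal(f@distalRange, 12, tolerance = 0.1)
    expect_equal(f@modulation, 6, tolerance = 0.2)
    # sphere diameter 4 cm centered at depth 10 cm -> R ~ 12, M ~ 4
    xs <- (seq_len(n) - 0.5) * 4
    d2 <- outer(outer((xs - 64)^2, (xs - 100)^2, `+`), (xs - 64)^2, `+`)
    sph <- MaskVolume(d2 <= 20^2, spacing = rep(4, 3))
    fs <- fitField(sph, water, beamGeometry(180), rangeSpread = 0)
    expect_equal(fs@distalRange, 12, tolerance = 0.25)
    expect_equal(fs@modulation, 4, tolerance = 0.4)
    # 1 cm of unit-RSP material upstream shifts R by 1, M unchanged
    v <- voxelValues(water)
    v[, 1:5, ] <- 1.5   # 2 cm * 1.5 = 3 cm WEPL vs 2 cm water: +1 cm
    denser <- RSPVolume(v, spacing = rep(4, 3))
    fd <- fitField(ptv, denser, beamGeometry(180), rangeSpread = 0)
    expect_equal(fd@distalRange - f@distalRange, 1, tolerance = 0.05)
    expect_equal(fd@modulation, f@modulation, tolerance = 0.05)
})

test_that("broad-beam field dose reduces to the SOBP curve on axis", {
    n <- 40
    water <- waterRSP(n, 4)
    ptv <- boxMask(n, 15:25, 20:30, 15:25, 4)
    f <- fitField(ptv, water, beamGeometry(180), rangeSpread = 0)
    dose <- computeFieldDose(f, water)
    v <- voxelValues(dose)
    # on-axis depth-dose equals the SOBP curve (no compensator variation)
    line <- v[20, , 20] / 100
    depths <- ((1:n) - 0.5) * 0.4 + f@compensator[20, 20]
    ref <- approx(f@sobp@depths, f@sobp@dose, xout = depths, rule = 2)$y
    expect_lt(max(abs(line - ref)), 0.01)
    # outside the aperture (penumbra off) the dose is zero
    expect_true(all(v[1, , 1] == 0))
    # halving the weight halves the dose everywhere (linearity)
    fHalf <- f; fHalf@weight <- f@weight / 2
    expect_equal(2 * voxelValues(computeFieldDose(fHalf, water)), v,
                 tolerance = 1e-12)
})

test_that("plan dose is the weighted sum of field doses", {
    n <- 24
    water <- waterRSP(n, 4)
    ptv <- boxMask(n, 8:16, 8:16, 8:16, 4)
    f1 <- fitField(ptv, water, beamGeometry(180), weight = 0.5,
                   rangeSpread = 0)
    f2 <- fitField(ptv, water, beamGeometry(270), weight = 0.5,
                   rangeSpread = 0)
    plan <- computePlanDose(list(f1, f2), water)
    ref <- voxelValues(computeFieldDose(f1, water)) +
        voxelValues(computeFieldDose(f2, water))
    expect_equal(voxelValues(plan), ref, tolerance = 1e-12)
    # symmetric phantom + symmetric fields -> symmetric dose about the
    # diagonal exchanging the two beam axes
    v <- voxelValues(plan)
    expect_equal(v[10, 12, 12], v[12, 10, 12], tolerance = 1e-6)
    # weight-sum violation is caught
    fbad <- f1; fbad@weight <- 0.6
    expect_error(computePlanDose(list(fbad, f2), water), "sum to 1")
})

test_that("single-field distal 90% surface hugs the distal PTV face", {
    n <- 32
    water <- waterRSP(n, 4)
    ptv <- boxMask(n, 10:22, 12:22, 10:22, 4)
    f <- fitField(ptv, water, beamGeometry(180), rangeSpread = 0)
    v <- voxelValues(computeFieldDose(f, water))
    level <- 0.9 * max(v)
    # deepest voxel above 90% along central rays is within one voxel of the
    # distal PTV face (index 22)
    for (i in c(12, 16, 20)) for (k in c(12, 16, 20)) {
        deepest <- max(which(v[i, , k] >= level))
        expect_lte(abs(deepest - 22), 1)
    }
})

test_that("raising density uniformly shrinks the depth of the distal edge", {
    n <- 32
    water <- waterRSP(n, 4)
    ptv <- boxMask(n, 10:22, 12:22, 10:22, 4)
    f <- fitField(ptv, water, beamGeometry(180), rangeSpread = 0)
    dense <- RSPVolume(voxelValues(water) * 1.05, spacing = rep(4, 3))
    v1 <- voxelValues(computeFieldDose(f, water))
    v2 <- voxelValues(computeFieldDose(f, dense))
    level <- 0.9 * max(v1)
    d1 <- max(which(v1[16, , 16] >= level))
    d2 <- max(which(v2[16, , 16] >= level))
    expect_equal(d2 / d1, 1 / 1.05, tolerance = 0.05)
})

test_that("lateral penumbra blurs the field edge when enabled", {
    n <- 24
    water <- waterRSP(n, 4)
    ptv <- boxMask(n, 8:16, 8:16, 8:16, 4)
    f <- fitField(ptv, water, beamGeometry(180), rangeSpread = 0)
    hard <- voxelValues(computeFieldDose(f, water))
    soft <- voxelValues(computeFieldDose(f, water, penumbraSigma = 3))
    edge <- range(which(apply(f@aperture, 1, any)))
    # outside the aperture the blurred field leaks a little dose
    expect_gt(sum(soft[edge[2] + 1, , ]), 0)
    expect_equal(sum(hard[edge[2] + 1, , ]), 0)
})
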