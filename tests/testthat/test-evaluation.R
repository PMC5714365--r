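test_that("dose indices match exhaustive threshold-sweep oracles", {
    # 100 voxels with doses 1..100: counting definitions, no ties
    d <- DoseVolume(array(c(1:100, rep(0, 25)), c(5, 5, 5)),
                    spacing = c(2, 2, 2))
    m <- MaskVolume(array(c(rep(TRUE, 100), rep(FALSE, 25)), c(5, 5, 5)),
                    spacing = c(2, 2, 2))
    expect_equal(doseIndex(d, m, 95), 6)
    expect_equal(doseIndex(d, m, 99), 2)
    expect_equal(doseIndex(d, m, 100), 1)
    # uniform dose: all indices equal it
    u <- DoseVolume(array(100, c(4, 4, 4)), spacing = c(2, 2, 2))
    mu <- MaskVolume(array(TRUE, c(4, 4, 4)), spacing = c(2, 2, 2))
    for (x in c(95, 99, 100)) expect_equal(doseIndex(u, mu, x), 100)
    # random grids vs the brute-force sweep (exact at achieved levels)
    rd <- randomDoseMask()
    vals <- voxelValues(rd$dose)[voxelValues(rd$mask)]
    for (x in c(90, 95, 99, 100)) {
        got <- doseIndex(rd$dose, rd$mask, x)
        ref <- bruteDoseIndex(vals, x)
        expect_gte(mean(vals >= ref) * 100, x)   # oracle self-check
        expect_lt(abs(got - ref), diff(range(vals)) / length(vals) * 10)
    }
    # monotone: D100 <= D99 <= D95
    expect_lte(doseIndex(rd$dose, rd$mask, 100),
               doseIndex(rd$dose, rd$mask, 99))
    expect_lte(doseIndex(rd$dose, rd$mask, 99),
               doseIndex(rd$dose, rd$mask, 95))
    expect_error(doseIndex(d, MaskVolume(array(FALSE, c(5, 5, 5)),
                                         spacing = c(2, 2, 2)), 95), "empty")
})

test_that("conformity index counts covered volume against covered target", {
    n <- 10
    ptv <- boxMask(n, 3:6, 3:6, 3:6, 2)
    # dose >= level exactly on the PTV -> CI 1
    v <- array(0, c(n, n, n)); v[3:6, 3:6, 3:6] <- 100
    expect_equal(conformityIndex(DoseVolume(v, spacing = c(2, 2, 2)), ptv), 1)
    # covered region = PTV plus an equal disjoint block -> CI 2
    v2 <- v; v2[1:4, 9:10, 1:8] <- 96
    stopifnot(sum(v2 >= 95) == 2 * sum(voxelValues(ptv)))
    expect_equal(conformityIndex(DoseVolume(v2, spacing = c(2, 2, 2)), ptv), 2)
    # random grid vs voxel-counting oracle
    rd <- randomDoseMask(seed = 9)
    ci <- conformityIndex(rd$dose, rd$mask, level = 60)
    ref <- sum(voxelValues(rd$dose) >= 60) /
        sum(voxelValues(rd$dose) >= 60 & voxelValues(rd$mask))
    expect_equal(ci, ref)
    cold <- DoseVolume(array(0, c(24, 24, 24)), spacing = c(2, 2, 2))
    expect_error(conformityIndex(cold, rd$mask), "undefined CI")
})

test_that("4D composition is the weighted voxel-wise mean", {
    a <- DoseVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
    b <- DoseVolume(array(100, c(4, 4, 4)), spacing = c(2, 2, 2))
    expect_equal(voxelValues(compose4D(list(a, b)))[1, 1, 1], 50)
    expect_equal(voxelValues(compose4D(list(b, b, b)))[2, 2, 2], 100)
    # 10 random phases vs brute-force weighted mean
    set.seed(5)
    ph <- lapply(1:10, function(i)
        DoseVolume(array(runif(6^3, 0, 110), c(6, 6, 6)),
                   spacing = c(2, 2, 2)))
    w <- runif(10); w <- w / sum(w)
    got <- voxelValues(compose4D(ph, w))
    ref <- Reduce(`+`, Map(function(p, wi) wi * voxelValues(p), ph, w))
    expect_equal(got, ref, tolerance = 1e-12)
    expect_error(compose4D(ph, rep(0.2, 10)), "sum to 1")
})

test_that("DVH curves are consistent with the dose indices", {
    rd <- randomDoseMask(seed = 21)
    d95 <- doseIndex(rd$dose, rd$mask, 95)
    curve <- dvh(rd$dose, rd$mask, levels = c(0, d95))
    expect_equal(curve$volume[1], 1)
    expect_gte(curve$volume[2], 0.95 - 2 / sum(voxelValues(rd$mask)))
    expect_lte(curve$volume[2], 0.96)
    # monotone nonincreasing on a fine grid
    full <- dvh(rd$dose, rd$mask)
    expect_true(all(diff(full$volume) <= 1e-12))
    # uniform dose: step function dropping at the dose value
    u <- DoseVolume(array(100, c(4, 4, 4)), spacing = c(2, 2, 2))
    mu <- MaskVolume(array(TRUE, c(4, 4, 4)), spacing = c(2, 2, 2))
    s <- dvh(u, mu, levels = c(0, 99.9, 100, 100.1))
    expect_equal(s$volume, c(1, 1, 1, 0))
})

test_that("recomputation on the planning volume reproduces the plan dose", {
    ser <- generatePhantom(smallConfig(amplitude = 0, noiseSD = 0))
    st <- buildStructureSet(ser, 5)
    plan <- buildPlan("AVG", ser, st)
    # zero motion: every phase equals the planning CT
    d <- recomputeOnPhase(plan, phaseVolumes(ser)[[4]])
    expect_equal(voxelValues(d), voxelValues(planDose(plan)),
                 tolerance = 1e-9)
    # hardware immutability: serialized field description is unchanged by
    # recomputation
    before <- planToJSON(plan)
    invisible(recomputeOnPhase(plan, phaseVolumes(ser)[[2]]))
    expect_identical(planToJSON(plan), before)
    # geometry mismatch is an error
    other <- HUVolume(array(0, c(8, 8, 8)), spacing = c(2, 2, 2))
    expect_error(recomputeOnPhase(plan, other), "geometry")
})

test_that("acceptability verdicts use an inclusive two-point band", {
    expect_true(acceptableDeltas(c(-1.9, -1.3, -1.9)))
    expect_true(acceptableDeltas(c(2, -2, 0)))
    expect_false(acceptableDeltas(c(0.5, -2.1, 0)))
})

test_that("zero-motion reports show zero deltas and pass everywhere", {
    ser <- generatePhantom(smallConfig(amplitude = 0, noiseSD = 0))
    st <- buildStructureSet(ser, 5)
    plan <- buildPlan("AVG", ser, st)
    rep <- acceptabilityReport(plan, ser)
    expect_true(all(rep@phaseTable$pass))
    expect_true(rep@verdict4D)
    expect_lt(max(abs(rep@phaseTable[, c("dD95", "dD99", "dD100")])), 1e-6)
    expect_lt(max(abs(rep@compositeDeltas)), 1e-6)
    expect_equal(rep@baseline[["D100"]], 95, tolerance = 1e-9)
})

test_that("composite indices are not the mean of per-phase indices", {
    ser <- generatePhantom(smallConfig(noiseSD = 0, seed = 3))
    st <- buildStructureSet(ser, 5)
    plan <- buildPlan("AVG", ser, st)
    rep <- acceptabilityReport(plan, ser)
    meanD100 <- mean(rep@phaseTable$D100)
    expect_gt(abs(rep@composite[["D100"]] - meanD100), 0.5)
})
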