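#' @include planning.R
NULL

#' Recompute a plan's dose on another CT volume with frozen hardware
#'
#' Replaces the planning CT by (typically) one respiratory phase and
#' recomputes the broad-beam dose with every planning parameter frozen:
#' field ranges, modulations, apertures, compensators, weights and the plan
#' normalization factor are all kept identical to the 3D plan.  Recomputing
#' on the planning CT itself reproduces the plan dose exactly.
#'
#' @param plan a [ProtonPlan].
#' @param phase an [HUVolume] sharing the planning grid.
#' @return A [DoseVolume].
#' @export
recomputeOnPhase <- function(plan, phase) {
    stopifnot(is(plan, "ProtonPlan"), is(phase, "HUVolume"))
    stopIfGeometryMismatch(phase, plan@planningCT, "phase and planning CT")
    rsp <- huToRSP(phase, plan@calibration)
    raw <- computePlanDose(plan@fields, rsp)
    DoseVolume(raw@values * plan@normalization, spacing = raw@spacing,
               origin = raw@origin)
}

#' Target dose index Dx%: minimal dose covering x% of a structure
#'
#' The largest dose level d such that at least x% of the structure's voxels
#' receive at least d.  Computed as a sort-based order statistic with linear
#' interpolation between order statistics at non-integer ranks; D100% is the
#' structure minimum.
#'
#' @param dose a [DoseVolume].
#' @param mask a [MaskVolume] (nonempty).
#' @param x numeric, coverage percentage in (0, 100].
#' @return numeric, dose in % of prescription.
#' @examples
#' d <- DoseVolume(array(1:64, c(4, 4, 4)))
#' m <- MaskVolume(array(TRUE, c(4, 4, 4)))
#' doseIndex(d, m, 100)  # minimum = 1
#' @export
doseIndex <- function(dose, mask, x) {
    stopifnot(is(dose, "DoseVolume"), is(mask, "MaskVolume"))
    stopIfGeometryMismatch(dose, mask, "dose and mask")
    if (!any(mask@values)) stop("empty mask", call. = FALSE)
    if (length(x) != 1L || x <= 0 || x > 100)
        stop("'x' must be in (0, 100]", call. = FALSE)
    s <- sort(dose@values[mask@values])
    n <- length(s)
    r <- n * (1 - x / 100) + 1
    if (r >= n) return(s[n])
    lo <- floor(r)
    s[lo] + (r - lo) * (s[lo + 1] - s[lo])
}

#' All target dose indices of a dose/structure pair
#'
#' @param dose a [DoseVolume].
#' @param mask a [MaskVolume], the target (PTV).
#' @param ciLevel numeric, isodose level for the conformity index
#'   (default 95).
#' @return Named numeric: `D95`, `D99`, `D100` (% of prescription) and `CI`.
#' @export
doseIndices <- function(dose, mask, ciLevel = 95) {
    c(D95 = doseIndex(dose, mask, 95),
      D99 = doseIndex(dose, mask, 99),
      D100 = doseIndex(dose, mask, 100),
      CI = conformityIndex(dose, mask, ciLevel))
}

#' Conformity index
#'
#' Ratio between the total volume receiving at least the reference level and
#' the target volume receiving it.  The reference level defaults to 95 (% of
#' prescription), the coverage level plans are normalized to.
#'
#' @param dose a [DoseVolume].
#' @param ptv a [MaskVolume].
#' @param level numeric, reference isodose in % of prescription (default 95).
#' @return numeric, CI >= 1 when the target is fully covered.
#' @export
conformityIndex <- function(dose, ptv, level = 95) {
    stopifnot(is(dose, "DoseVolume"), is(ptv, "MaskVolume"))
    stopIfGeometryMismatch(dose, ptv, "dose and PTV")
    covered <- dose@values >= level
    denom <- sum(covered & ptv@values)
    if (denom == 0)
        stop("undefined CI: no target voxel reaches the reference level",
             call. = FALSE)
    sum(covered) / denom
}

#' Compose per-phase doses into a 4D dose
#'
#' Voxel-wise weighted mean of the phase doses on the common grid (rigid
#' overlay onto the representative AVG-CT grid; no deformable mapping).
#' Weights default to uniform: all phases of the breathing cycle contribute
#' equally.
#'
#' @param phaseDoses list of [DoseVolume] objects on a common grid.
#' @param weights numeric, nonnegative weights summing to 1 (default
#'   uniform).
#' @return A [DoseVolume].
#' @export
compose4D <- function(phaseDoses, weights = NULL) {
    if (!length(phaseDoses)) stop("no phase doses", call. = FALSE)
    if (is.null(weights))
        weights <- rep(1 / length(phaseDoses), length(phaseDoses))
    if (length(weights) != length(phaseDoses) ||
        abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
        stop("weights must be nonnegative and sum to 1", call. = FALSE)
    ref <- phaseDoses[[1]]
    acc <- array(0, dim(ref@values))
    for (i in seq_along(phaseDoses)) {
        stopIfGeometryMismatch(phaseDoses[[i]], ref, "phase doses")
        acc <- acc + weights[i] * phaseDoses[[i]]@values
    }
    DoseVolume(acc, spacing = ref@spacing, origin = ref@origin)
}

#' Cumulative dose-volume histogram
#'
#' Fraction of the structure receiving at least each dose level; monotone
#' nonincreasing, starting at 1 at level 0.
#'
#' @param dose a [DoseVolume].
#' @param mask a [MaskVolume] (nonempty).
#' @param levels numeric, dose levels (% of prescription); default a 0.5-wide
#'   grid from 0 to just above the structure maximum.
#' @return A data.frame with columns `dose` and `volume` (fraction in
#'   \[0, 1\]).
#' @export
dvh <- function(dose, mask, levels = NULL) {
    stopifnot(is(dose, "DoseVolume"), is(mask, "MaskVolume"))
    stopIfGeometryMismatch(dose, mask, "dose and mask")
    if (!any(mask@values)) stop("empty mask", call. = FALSE)
    v <- dose@values[mask@values]
    if (is.null(levels)) levels <- seq(0, max(v) + 0.5, by = 0.5)
    frac <- vapply(levels, function(l) mean(v >= l), numeric(1))
    data.frame(dose = levels, volume = frac)
}

#' Are index changes within the acceptability tolerance?
#'
#' The acceptability criterion: a recomputed plan is tolerable iff every
#' target dose index changed by no more than the tolerance, in percentage
#' points of the prescription.  The bound is inclusive: a change of exactly
#' the tolerance passes.
#'
#' @param deltas numeric, index changes in percentage points.
#' @param tolerance numeric, bound (default 2).
#' @return logical.
#' @export
acceptableDeltas <- function(deltas, tolerance = 2) {
    all(abs(deltas) <= tolerance + 1e-9)
}

#' Per-phase and 4D acceptability report for a plan
#'
#' Recomputes the plan dose on every phase of the series with frozen beam
#' hardware, computes the PTV dose indices and their deltas against the 3D
#' apparent plan (each strategy's own baseline), applies the inclusive
#' +/- tolerance criterion per phase, then composes the equal-weighted 4D
#' dose and evaluates its deltas the same way.
#'
#' @param plan a [ProtonPlan] built on a volume derived from `series`.
#' @param series a [PhaseSeries].
#' @param tolerance numeric, acceptability bound in percentage points
#'   (default 2).
#' @return A [PhaseReport].
#' @export
acceptabilityReport <- function(plan, series, tolerance = 2) {
    stopifnot(is(plan, "ProtonPlan"), is(series, "PhaseSeries"))
    ptv <- plan@structures@ptv
    base <- doseIndices(plan@dose, ptv)
    n <- nPhases(series)
    rows <- vector("list", n)
    phaseDoses <- vector("list", n)
    for (i in seq_len(n)) {
        d <- recomputeOnPhase(plan, series@phases[[i]])
        phaseDoses[[i]] <- d
        idx <- doseIndices(d, ptv)
        deltas <- idx[c("D95", "D99", "D100")] -
            base[c("D95", "D99", "D100")]
        rows[[i]] <- data.frame(
            phase = series@phaseLabels[i],
            D95 = idx[["D95"]], D99 = idx[["D99"]], D100 = idx[["D100"]],
            CI = idx[["CI"]],
            dD95 = deltas[["D95"]], dD99 = deltas[["D99"]],
            dD100 = deltas[["D100"]],
            pass = acceptableDeltas(deltas, tolerance))
    }
    tab <- do.call(rbind, rows)
    comp <- compose4D(phaseDoses, series@phaseWeights)
    compIdx <- doseIndices(comp, ptv)
    compDeltas <- compIdx[c("D95", "D99", "D100")] -
        base[c("D95", "D99", "D100")]
    new("PhaseReport", strategy = plan@strategy, tolerance = tolerance,
        baseline = base, phaseTable = tab, composite = compIdx,
        compositeDeltas = compDeltas,
        verdict4D = acceptableDeltas(compDeltas, tolerance),
        compositeDose = comp)
}
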