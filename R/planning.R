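#' @include dose-engine.R
NULL

#' Normalize a plan dose to full PTV coverage at the 95% level
#'
#' Scales the dose distribution so that the minimum dose inside the PTV is
#' exactly 95 (% of prescription), i.e. 100% of the PTV is covered by the
#' 95% isodose.
#'
#' @param dose a [DoseVolume].
#' @param ptv a [MaskVolume] (nonempty; every PTV voxel must receive dose).
#' @return A list with elements `dose` (the scaled [DoseVolume]) and
#'   `factor` (the applied scale).
#' @export
normalizeToCoverage <- function(dose, ptv) {
    stopifnot(is(dose, "DoseVolume"), is(ptv, "MaskVolume"))
    stopIfGeometryMismatch(dose, ptv, "dose and PTV")
    if (!any(ptv@values)) stop("empty PTV", call. = FALSE)
    minD <- min(dose@values[ptv@values])
    if (minD <= 0)
        stop("normalization impossible: a PTV voxel receives zero dose",
             call. = FALSE)
    factor <- 95 / minD
    list(dose = DoseVolume(dose@values * factor, spacing = dose@spacing,
                           origin = dose@origin),
         factor = factor)
}

#' Build an AVG, MIP or OVR proton plan on a 4D series
#'
#' Selects the strategy's planning volume (per-voxel mean for AVG, per-voxel
#' maximum for MIP, AVG with the PTV density overridden to the mean
#' gross-tumor HU for OVR), converts it to relative stopping power, fits one
#' field per gantry angle (equal weights), computes the combined broad-beam
#' dose and normalizes it to 100% PTV coverage at the 95% isodose level.
#'
#' The field-specific margin plan (mAVG) is built from the AVG and MIP plans
#' via [fieldSpecificMargins()] and [applyMargins()], or in one step with
#' [buildMAVGPlan()].
#'
#' @param strategy character, "AVG", "MIP" or "OVR".
#' @param series a [PhaseSeries].
#' @param structures a [StructureSet] on the series grid.
#' @param angles numeric vector of gantry angles in degrees (default
#'   `c(180, 270)`: posterior and right-lateral, orthogonal coplanar).
#' @param calibration a [CalibrationCurve].
#' @param apertureMargin,smoothingMargin numeric, cm (defaults 1).
#' @param rangeSpread numeric, beamline range spread in cm (default 0.12),
#'   passed to [fitField()].
#' @return A [ProtonPlan].
#' @export
buildPlan <- function(strategy, series, structures, angles = c(180, 270),
                      calibration = defaultCalibration(),
                      apertureMargin = 1, smoothingMargin = 1,
                      rangeSpread = 0.12) {
    if (!strategy %in% c("AVG", "MIP", "OVR"))
        stop("unknown strategy '", strategy,
             "' (mAVG plans are built with applyMargins/buildMAVGPlan)",
             call. = FALSE)
    stopifnot(is(series, "PhaseSeries"), is(structures, "StructureSet"))
    ct <- switch(strategy,
                 AVG = averageCT(series),
                 MIP = mipCT(series),
                 OVR = overridePTVDensity(averageCT(series), structures,
                                          grossTumorDensity(series)))
    rsp <- huToRSP(ct, calibration)
    nf <- length(angles)
    fields <- lapply(angles, function(a)
        fitField(structures@ptv, rsp, beamGeometry(a), weight = 1 / nf,
                 apertureMargin = apertureMargin,
                 smoothingMargin = smoothingMargin,
                 rangeSpread = rangeSpread))
    raw <- computePlanDose(fields, rsp)
    norm <- normalizeToCoverage(raw, structures@ptv)
    new("ProtonPlan", strategy = strategy, planningCT = ct,
        calibration = calibration, fields = fields,
        normalization = norm$factor, structures = structures,
        dose = norm$dose, fieldMargins = rep(0, nf))
}

#' Field-specific distal proton margins: MIP-minus-AVG range differences
#'
#' The per-field distal range increment is the difference between the
#' distal range fitted on the MIP volume and the one fitted on the AVG
#' volume for the same field: the motion-induced spread of the
#' water-equivalent depth to the distal target surface, measured separately
#' for each beam direction.
#'
#' @param avgPlan,mipPlan [ProtonPlan] objects with identical field count,
#'   angles and order.
#' @return numeric, per-field distal range increment (cm WEPL).  Negative
#'   increments are possible in principle and flagged with a warning.
#' @export
fieldSpecificMargins <- function(avgPlan, mipPlan) {
    stopifnot(is(avgPlan, "ProtonPlan"), is(mipPlan, "ProtonPlan"))
    aAng <- vapply(avgPlan@fields, function(f) f@geometry@gantryAngle,
                   numeric(1))
    mAng <- vapply(mipPlan@fields, function(f) f@geometry@gantryAngle,
                   numeric(1))
    if (length(aAng) != length(mAng) || any(aAng != mAng))
        stop("mismatched field sets between AVG and MIP plans",
             call. = FALSE)
    dR <- distalRange(mipPlan) - distalRange(avgPlan)
    if (any(dR < 0))
        warning("negative field-specific margin encountered")
    dR
}

#' Apply field-specific distal margins to an AVG plan (mAVG)
#'
#' Per field, the distal range grows by that field's margin and the SOBP
#' widens by the same amount (`R <- R + dR`, `M <- M + dR`), keeping the
#' proximal 90% depth, compensator, aperture, angles and weights unchanged:
#' the modified plan retains the AVG plan's proximal coverage and acquires
#' the MIP plan's distal coverage.  The plan dose is recomputed on the AVG
#' volume and re-normalized.
#'
#' @param avgPlan a [ProtonPlan] with strategy "AVG".
#' @param margins numeric, per-field distal increments (cm WEPL), aligned
#'   with the plan's fields (from [fieldSpecificMargins()]).
#' @param rangeSpread numeric, beamline range spread in cm used when the
#'   widened SOBPs are rebuilt (default 0.12, matching [buildPlan()]).
#' @return A [ProtonPlan] with strategy "mAVG".
#' @export
applyMargins <- function(avgPlan, margins, rangeSpread = 0.12) {
    stopifnot(is(avgPlan, "ProtonPlan"))
    if (avgPlan@strategy != "AVG")
        stop("field-specific margins are applied to an AVG plan",
             call. = FALSE)
    if (length(margins) != length(avgPlan@fields))
        stop("one margin per field required", call. = FALSE)
    fields <- Map(function(f, dR) {
        R <- f@distalRange + dR
        M <- f@modulation + dR
        new("BeamField", geometry = f@geometry, distalRange = R,
            modulation = M, aperture = f@aperture,
            compensator = f@compensator, apertureMargin = f@apertureMargin,
            smoothingMargin = f@smoothingMargin, weight = f@weight,
            sobp = if (dR == 0) f@sobp else
                buildSOBP(R, M, rangeSpread = rangeSpread))
    }, avgPlan@fields, as.numeric(margins))
    fields <- unname(fields)
    rsp <- huToRSP(avgPlan@planningCT, avgPlan@calibration)
    raw <- computePlanDose(fields, rsp)
    norm <- normalizeToCoverage(raw, avgPlan@structures@ptv)
    new("ProtonPlan", strategy = "mAVG", planningCT = avgPlan@planningCT,
        calibration = avgPlan@calibration, fields = fields,
        normalization = norm$factor, structures = avgPlan@structures,
        dose = norm$dose, fieldMargins = as.numeric(margins))
}

#' Build the mAVG plan directly from a phase series
#'
#' Convenience wrapper: builds the AVG and MIP precursor plans, derives the
#' field-specific margins and applies them to the AVG plan.
#'
#' @inheritParams buildPlan
#' @return A list with elements `avg`, `mip` and `mavg` ([ProtonPlan]s).
#' @export
buildMAVGPlan <- function(series, structures, angles = c(180, 270),
                          calibration = defaultCalibration(),
                          apertureMargin = 1, smoothingMargin = 1,
                          rangeSpread = 0.12) {
    avg <- buildPlan("AVG", series, structures, angles, calibration,
                     apertureMargin, smoothingMargin, rangeSpread)
    mip <- buildPlan("MIP", series, structures, angles, calibration,
                     apertureMargin, smoothingMargin, rangeSpread)
    margins <- fieldSpecificMargins(avg, mip)
    list(avg = avg, mip = mip,
         mavg = applyMargins(avg, margins, rangeSpread))
}
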