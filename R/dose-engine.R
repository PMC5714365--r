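#' @include beam-model.R ct-ops.R
NULL

#' Construct a coplanar parallel beam geometry
#'
#' Maps a cardinal gantry angle to a grid-axis-aligned parallel beam.  With
#' +x the patient's left and +y anterior: 0 = anterior field (beam travels
#' -y), 90 = left-lateral (-x), 180 = posterior (+y), 270 = right-lateral
#' (+x).  All beams lie in the axial plane (no cranial-caudal component),
#' matching coplanar field arrangements.
#'
#' @param gantryAngle numeric, one of 0, 90, 180, 270 degrees.
#' @return A [BeamGeometry].
#' @export
beamGeometry <- function(gantryAngle) {
    if (length(gantryAngle) != 1L || !gantryAngle %in% c(0, 90, 180, 270))
        stop("unsupported geometry: gantry angle must be 0, 90, 180 or 270",
             call. = FALSE)
    spec <- switch(as.character(gantryAngle),
                   "0"   = c(2L, -1L),   # anterior -> travels -y
                   "90"  = c(1L, -1L),   # left lateral -> travels -x
                   "180" = c(2L, 1L),    # posterior -> travels +y
                   "270" = c(1L, 1L))    # right lateral -> travels +x
    new("BeamGeometry", gantryAngle = as.numeric(gantryAngle),
        axis = spec[1L], direction = spec[2L])
}

## axes spanning the beam's-eye-view plane, in increasing order
bevAxes <- function(geometry) sort(setdiff(1:3, geometry@axis))

## Reorient a 3D array so the beam axis is dimension 1, advancing with
## increasing index; returns a matrix (depth x BEV-pixel) in BEV column
## order, plus the info needed to undo the transform.
toBeamFrame <- function(arr, geometry) {
    ax <- geometry@axis
    if (geometry@direction < 0) {
        idx <- rev(seq_len(dim(arr)[ax]))
        arr <- switch(ax, arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE])
    }
    perm <- c(ax, bevAxes(geometry))
    a <- aperm(arr, perm)
    list(m = matrix(a, nrow = dim(a)[1]), dims = dim(a), perm = perm)
}

fromBeamFrame <- function(m, frame, geometry) {
    a <- array(m, frame$dims)
    arr <- aperm(a, order(frame$perm))
    ax <- geometry@axis
    if (geometry@direction < 0) {
        idx <- rev(seq_len(dim(arr)[ax]))
        arr <- switch(ax, arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE])
    }
    arr
}

#' Water-equivalent path length (WEPL) ray tracing
#'
#' For every voxel, integrates the relative stopping power along the
#' (parallel, axis-aligned) beam direction from the volume entry surface to
#' the voxel center, yielding the cumulative water-equivalent depth in cm.
#' WEPL is nondecreasing along every ray and equals the geometric depth in
#' water (RSP = 1).
#'
#' @param rsp an [RSPVolume].
#' @param geometry a [BeamGeometry].
#' @return A [GridVolume] derivative ([DoseVolume] container reused for the
#'   scalar field) holding WEPL in cm on the same grid.
#' @export
traceWEPL <- function(rsp, geometry) {
    stopifnot(is(rsp, "RSPVolume"), is(geometry, "BeamGeometry"))
    stepCm <- rsp@spacing[geometry@axis] / 10
    fr <- toBeamFrame(rsp@values, geometry)
    cs <- apply(fr$m, 2, cumsum)
    w <- (cs - 0.5 * fr$m) * stepCm
    DoseVolume(fromBeamFrame(w, fr, geometry), spacing = rsp@spacing,
               origin = rsp@origin)
}

## Per-ray WEPL (cm) of the distal and proximal faces of the voxels of a
## mask, in BEV column order.  Columns whose ray misses the mask get NA.
raySurfaceWEPL <- function(mask, rsp, geometry) {
    stepCm <- rsp@spacing[geometry@axis] / 10
    frR <- toBeamFrame(rsp@values, geometry)
    frM <- toBeamFrame(mask, geometry)
    cs <- apply(frR$m, 2, cumsum)
    wDist <- cs * stepCm                        # WEPL at distal voxel face
    wProx <- (cs - frR$m) * stepCm              # WEPL at proximal voxel face
    wDist[!frM$m] <- -Inf
    wProx[!frM$m] <- Inf
    distal <- apply(wDist, 2, max)
    proximal <- apply(wProx, 2, min)
    distal[!is.finite(distal)] <- NA_real_
    proximal[!is.finite(proximal)] <- NA_real_
    list(distal = distal, proximal = proximal,
         bevDim = frR$dims[2:3], crossing = apply(frM$m, 2, any))
}

#' Design the aperture collimator for a field
#'
#' Projects the PTV along the beam axis onto the beam's-eye-view plane and
#' expands the projection uniformly by the aperture margin (Euclidean
#' dilation), the standard double-scattering aperture recipe.
#'
#' @param ptv a [MaskVolume], the planning target volume (nonempty).
#' @param geometry a [BeamGeometry].
#' @param margin numeric, aperture margin in cm (default 1).
#' @return Logical BEV matrix (dimensions = the two non-beam axes in
#'   increasing axis order).
#' @export
designAperture <- function(ptv, geometry, margin = 1) {
    stopifnot(is(ptv, "MaskVolume"), is(geometry, "BeamGeometry"))
    if (!any(ptv@values)) stop("empty PTV", call. = FALSE)
    if (margin < 0) stop("'margin' must be >= 0", call. = FALSE)
    fr <- toBeamFrame(ptv@values, geometry)
    proj <- matrix(apply(fr$m, 2, any), fr$dims[2], fr$dims[3])
    dilateBall(proj, ptv@spacing[bevAxes(geometry)], margin * 10)
}

#' Design the range compensator for a field
#'
#' For every BEV ray crossing the PTV, the compensator thickness (in cm
#' WEPL) is `R - WEPL(distal PTV surface along the ray)`, so that after
#' compensation the prescribed distal isodose surface fits the distal PTV
#' surface.  Rays inside the border-smoothing ring around the PTV projection
#' that miss the PTV take the minimum thickness of the PTV-crossing rays
#' within the smoothing radius (border smoothing); no smearing margin is
#' applied.  Remaining open rays fall back to the minimum thickness over the
#' projection.
#'
#' @param ptv a [MaskVolume] (nonempty).
#' @param rsp an [RSPVolume] on the same grid.
#' @param geometry a [BeamGeometry].
#' @param R numeric, prescribed distal range in cm WEPL; must reach the
#'   deepest distal PTV surface.
#' @param smoothingMargin numeric, border smoothing margin in cm (default 1).
#' @return Numeric BEV matrix of thicknesses (cm WEPL, >= 0).
#' @export
designCompensator <- function(ptv, rsp, geometry, R, smoothingMargin = 1) {
    stopifnot(is(ptv, "MaskVolume"), is(rsp, "RSPVolume"))
    stopIfGeometryMismatch(ptv, rsp, "PTV and RSP volume")
    if (!any(ptv@values)) stop("empty PTV", call. = FALSE)
    surf <- raySurfaceWEPL(ptv@values, rsp, geometry)
    crossing <- matrix(surf$crossing, surf$bevDim[1], surf$bevDim[2])
    distal <- matrix(surf$distal, surf$bevDim[1], surf$bevDim[2])
    deficit <- max(distal[crossing]) - R
    if (deficit > 1e-9)
        stop(sprintf(
            "infeasible compensator: R short of the distal PTV surface by %.3f cm WEPL",
            deficit), call. = FALSE)
    thick <- matrix(0, nrow(crossing), ncol(crossing))
    thick[crossing] <- R - distal[crossing]
    bevSpacing <- ptv@spacing[bevAxes(geometry)]
    ring <- dilateBall(crossing, bevSpacing, smoothingMargin * 10) & !crossing
    ringMin <- ballMin2D(thick, crossing, bevSpacing, smoothingMargin * 10)
    thick[ring] <- ringMin[ring]
    thick[!is.finite(thick)] <- min(thick[crossing])
    thick[!crossing & !ring] <- min(thick[crossing])
    thick
}

#' Fit a treatment field to the PTV
#'
#' Chooses the field's distal range and modulation so that, after
#' compensation, the distal and proximal 90% surfaces bound the PTV:
#' `R` is the deepest distal-surface WEPL over all PTV rays and `M` spans
#' down to the shallowest proximal-surface WEPL (each padded by half a depth
#' step), then attaches the aperture, compensator and SOBP curve.
#'
#' @param ptv a [MaskVolume] (nonempty).
#' @param rsp an [RSPVolume].
#' @param geometry a [BeamGeometry] (or gantry angle, passed to
#'   [beamGeometry()]).
#' @param weight numeric, field weight (default 1).
#' @param apertureMargin numeric, cm (default 1).
#' @param smoothingMargin numeric, cm (default 1).
#' @param rangeSpread numeric, beamline range spread in cm applied to the
#'   field's pristine peaks (default 0.12, a typical double-scattering
#'   energy spread; widens the distal falloff beyond pure straggling).
#' @return A [BeamField].
#' @export
fitField <- function(ptv, rsp, geometry, weight = 1, apertureMargin = 1,
                     smoothingMargin = 1, rangeSpread = 0.12) {
    if (is.numeric(geometry)) geometry <- beamGeometry(geometry)
    stopifnot(is(ptv, "MaskVolume"), is(rsp, "RSPVolume"))
    if (!any(ptv@values)) stop("empty PTV", call. = FALSE)
    surf <- raySurfaceWEPL(ptv@values, rsp, geometry)
    halfStep <- DEPTH_STEP / 2
    R <- max(surf$distal, na.rm = TRUE) + halfStep
    M <- R - (min(surf$proximal, na.rm = TRUE) - halfStep)
    sobp <- buildSOBP(R, M, rangeSpread = rangeSpread)
    aperture <- designAperture(ptv, geometry, apertureMargin)
    comp <- designCompensator(ptv, rsp, geometry, R, smoothingMargin)
    new("BeamField", geometry = geometry, distalRange = R, modulation = M,
        aperture = aperture, compensator = comp,
        apertureMargin = apertureMargin, smoothingMargin = smoothingMargin,
        weight = weight, sobp = sobp)
}

#' Compute the broad-beam dose of one field
#'
#' For every voxel whose ray lies inside the aperture, the residual
#' water-equivalent depth is `WEPL(voxel) + compensator(ray)`; the dose is
#' the field's SOBP curve evaluated at that depth, scaled by the field
#' weight (and by 100: plan doses are carried in % of prescription before
#' normalization).  Outside the aperture the dose is zero unless a lateral
#' Gaussian penumbra is enabled, in which case the BEV fluence is the
#' aperture mask blurred with the given sigma.
#'
#' @param field a [BeamField].
#' @param rsp an [RSPVolume].
#' @param penumbraSigma numeric, lateral penumbra sigma in mm (default 0 =
#'   off; pure-range behaviour).
#' @return A [DoseVolume].
#' @export
computeFieldDose <- function(field, rsp, penumbraSigma = 0) {
    stopifnot(is(field, "BeamField"), is(rsp, "RSPVolume"))
    geometry <- field@geometry
    if (!identical(dim(field@aperture),
                   dim(rsp@values)[bevAxes(geometry)]))
        stop("geometry error: field hardware does not match the volume grid",
             call. = FALSE)
    fr <- toBeamFrame(rsp@values, geometry)
    stepCm <- rsp@spacing[geometry@axis] / 10
    cs <- apply(fr$m, 2, cumsum)
    w <- (cs - 0.5 * fr$m) * stepCm
    residual <- sweep(w, 2, as.vector(field@compensator), `+`)
    sobp <- field@sobp
    stepD <- sobp@depths[2] - sobp@depths[1]
    pos <- residual / stepD + 1
    n <- length(sobp@dose)
    lo <- floor(pos)
    frac <- pos - lo
    lo[lo < 1] <- 1; frac[pos < 1] <- 0
    out <- lo >= n
    lo[out] <- n - 1L; frac[out] <- 1
    dm <- sobp@dose[lo] * (1 - frac) + sobp@dose[pmin(lo + 1L, n)] * frac
    dm[residual > max(sobp@depths)] <- 0
    fl <- as.numeric(field@aperture)
    if (penumbraSigma > 0) {
        sigPix <- penumbraSigma / rsp@spacing[bevAxes(geometry)]
        fl <- as.numeric(gaussianBlur2D(field@aperture * 1, sigPix))
    }
    dm <- sweep(matrix(dm, nrow(fr$m)), 2, fl, `*`)
    dm <- dm * 100 * field@weight
    DoseVolume(fromBeamFrame(dm, fr, geometry), spacing = rsp@spacing,
               origin = rsp@origin)
}

#' Compute the combined dose of a set of fields
#'
#' Weighted superposition of the per-field broad-beam doses (the field
#' weights must sum to 1), before any plan normalization.
#'
#' @param fields list of [BeamField] objects.
#' @param rsp an [RSPVolume].
#' @param penumbraSigma numeric, mm, passed to [computeFieldDose()].
#' @return A [DoseVolume].
#' @export
computePlanDose <- function(fields, rsp, penumbraSigma = 0) {
    if (!length(fields)) stop("no fields", call. = FALSE)
    wsum <- sum(vapply(fields, function(f) f@weight, numeric(1)))
    if (abs(wsum - 1) > 1e-6)
        stop("field weights must sum to 1", call. = FALSE)
    acc <- NULL
    for (f in fields) {
        d <- computeFieldDose(f, rsp, penumbraSigma)
        acc <- if (is.null(acc)) d@values else acc + d@values
    }
    DoseVolume(acc, spacing = rsp@spacing, origin = rsp@origin)
}
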