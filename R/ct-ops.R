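#' @include volumes.R
NULL

#' Average-intensity (AVG) CT reconstruction of a 4D series
#'
#' Per-voxel arithmetic mean of the CT numbers over all respiratory phases.
#'
#' @param series a [PhaseSeries] (>= 2 phases on a common grid).
#' @return An [HUVolume] on the series grid.
#' @seealso [mipCT()]
#' @export
averageCT <- function(series) {
    stopifnot(is(series, "PhaseSeries"))
    ref <- series@phases[[1]]
    acc <- Reduce(`+`, lapply(series@phases, voxelValues))
    HUVolume(acc / nPhases(series), spacing = ref@spacing,
             origin = ref@origin)
}

#' Maximum-intensity-projection (MIP) CT reconstruction of a 4D series
#'
#' Per-voxel maximum of the CT numbers over all respiratory phases.
#'
#' @param series a [PhaseSeries].
#' @return An [HUVolume] on the series grid.
#' @seealso [averageCT()]
#' @export
mipCT <- function(series) {
    stopifnot(is(series, "PhaseSeries"))
    ref <- series@phases[[1]]
    acc <- Reduce(pmax, lapply(series@phases, voxelValues))
    HUVolume(acc, spacing = ref@spacing, origin = ref@origin)
}

#' Internal target volume (ITV): union of per-phase GTV masks
#'
#' @param gtvMasks nonempty list of [MaskVolume] objects on a common grid.
#' @return A [MaskVolume]: the per-voxel union.
#' @export
buildITV <- function(gtvMasks) {
    if (!length(gtvMasks)) stop("empty GTV mask list", call. = FALSE)
    ref <- gtvMasks[[1]]
    for (m in gtvMasks) stopIfGeometryMismatch(m, ref, "GTV masks")
    acc <- Reduce(`|`, lapply(gtvMasks, voxelValues))
    MaskVolume(acc, spacing = ref@spacing, origin = ref@origin)
}

#' Uniform Euclidean expansion of a binary mask
#'
#' Dilates a mask by a physical margin in all directions: a voxel belongs to
#' the result iff its center lies within `margin` mm of the center of a set
#' voxel (Euclidean ball structuring element on the voxel lattice).
#'
#' @param mask a [MaskVolume].
#' @param margin numeric, expansion margin in mm (>= 0; 0 is the identity).
#' @return A [MaskVolume].
#' @export
expandUniform <- function(mask, margin) {
    stopifnot(is(mask, "MaskVolume"))
    if (length(margin) != 1L || !is.finite(margin) || margin < 0)
        stop("'margin' must be a single nonnegative number (mm)",
             call. = FALSE)
    MaskVolume(dilateBall(mask@values, mask@spacing, margin),
               spacing = mask@spacing, origin = mask@origin)
}

#' Build GTV/ITV/PTV target structures from a phase series
#'
#' Merges the per-phase GTV masks into the ITV and expands it uniformly by
#' the planning margin to the PTV.  The planning margin is a configuration
#' parameter (default 5 mm) and is recorded in the structure set.
#'
#' @param series a [PhaseSeries].
#' @param ptvMargin numeric, uniform ITV-to-PTV margin in mm (default 5).
#' @return A [StructureSet].
#' @export
buildStructureSet <- function(series, ptvMargin = 5) {
    stopifnot(is(series, "PhaseSeries"))
    itv <- buildITV(series@gtvMasks)
    ptv <- expandUniform(itv, ptvMargin)
    new("StructureSet", gtvMasks = series@gtvMasks, itv = itv, ptv = ptv,
        ptvMargin = as.numeric(ptvMargin))
}

#' Density-override (OVR) CT: replace PTV by the average gross-tumor HU
#'
#' Replaces every voxel inside the PTV of an AVG CT by the average
#' gross-tumor density; all other voxels are unchanged.  This makes the
#' planning density inside the target insensitive to the tumor's
#' motion-smeared appearance on the AVG reconstruction.
#'
#' By default the override value is the tumor's intrinsic density measured
#' where the tumor actually is: the per-phase mean HU over each phase's GTV,
#' averaged over phases ([grossTumorDensity()]).  Passing `value = NULL`
#' with no series instead uses the mean HU of the AVG volume over the ITV;
#' that average is diluted by lung wherever the tumor track crosses low
#' density tissue, which defeats part of the override's purpose.
#'
#' @param avg an [HUVolume], normally the AVG reconstruction.
#' @param structures a [StructureSet] on the same grid (nonempty PTV).
#' @param value numeric, the override HU; if `NULL`, the mean HU of `avg`
#'   over the ITV is used.
#' @return An [HUVolume].
#' @export
overridePTVDensity <- function(avg, structures, value = NULL) {
    stopifnot(is(avg, "HUVolume"), is(structures, "StructureSet"))
    stopIfGeometryMismatch(avg, structures@ptv, "volume and PTV")
    ptv <- structures@ptv@values
    itv <- structures@itv@values
    if (!any(ptv)) stop("empty PTV", call. = FALSE)
    if (!any(itv)) stop("empty ITV", call. = FALSE)
    if (is.null(value)) value <- mean(avg@values[itv])
    v <- avg@values
    v[ptv] <- value
    HUVolume(v, spacing = avg@spacing, origin = avg@origin)
}

#' Average gross-tumor density of a 4D series
#'
#' The tumor's intrinsic CT density: for each phase, the mean HU over that
#' phase's GTV on that phase's scan; averaged over phases.  Unlike the mean
#' over the motion-smeared ITV, this measurement is not diluted by the
#' low-density tissue the tumor track sweeps through.
#'
#' @param series a [PhaseSeries].
#' @return numeric, HU.
#' @export
grossTumorDensity <- function(series) {
    stopifnot(is(series, "PhaseSeries"))
    mean(vapply(seq_len(nPhases(series)), function(i)
        mean(series@phases[[i]]@values[series@gtvMasks[[i]]@values]),
        numeric(1)))
}

#' Default HU to relative stopping power calibration curve
#'
#' Piecewise-linear calibration with anchors (-1000 -> 0.001, -700 -> 0.29,
#' -300 -> 0.71, 0 -> 1.00, 60 -> 1.04, 120 -> 1.07, 1600 -> 1.85): water at
#' 0 HU maps to 1 and representative liver (~115 HU) has 3-4 times the
#' stopping power of representative lung (~-700 HU), matching the clinical
#' contrast that drives range perturbation at a moving liver-lung interface.
#' Replaceable by any user calibration via [readCalibration()] or
#' [CalibrationCurve-class].
#'
#' @return A [CalibrationCurve].
#' @examples
#' cal <- defaultCalibration()
#' huToRSP(HUVolume(array(0, c(2, 2, 2))), cal)  # water -> 1
#' @export
defaultCalibration <- function() {
    new("CalibrationCurve",
        hu = c(-1000, -700, -300, 0, 60, 120, 1600),
        rsp = c(0.001, 0.29, 0.71, 1.00, 1.04, 1.07, 1.85))
}

#' Convert a CT volume to relative stopping power
#'
#' Per-voxel piecewise-linear interpolation of a calibration curve; HU values
#' outside the calibration domain are clamped to the end breakpoints.  The
#' mapping is monotone in HU and preserves the grid geometry.
#'
#' @param vol an [HUVolume].
#' @param cal a [CalibrationCurve] (default [defaultCalibration()]).
#' @return An [RSPVolume] on the same grid.
#' @export
huToRSP <- function(vol, cal = defaultCalibration()) {
    stopifnot(is(vol, "HUVolume"), is(cal, "CalibrationCurve"))
    validObject(cal)
    v <- approx(cal@hu, cal@rsp, xout = as.vector(vol@values),
                rule = 2)$y
    RSPVolume(array(v, dim(vol@values)), spacing = vol@spacing,
              origin = vol@origin)
}
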