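#' @include proton4d-package.R
NULL

## ---------------------------------------------------------------------------
## Volume containers
## ---------------------------------------------------------------------------

#' GridVolume: virtual base class for 3D voxel grids
#'
#' All volumetric objects in the package (CT numbers, stopping power, dose,
#' binary masks) share a regular 3D grid described by a voxel array, a per-axis
#' spacing in mm and a world origin in mm.  The world coordinate of voxel
#' `(i, j, k)` is `origin + (c(i, j, k) - 0.5) * spacing` (voxel centers).
#' Axis convention: x = patient right-to-left, y = posterior-to-anterior,
#' z = caudal-to-cranial (superior is +z).
#'
#' @slot values 3D array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm (all > 0).
#' @slot origin numeric(3), world position (mm) of the grid corner.
#'
#' @aliases GridVolume-class
#' @exportClass GridVolume
setClass("GridVolume",
         contains = "VIRTUAL",
         slots = c(values = "array", spacing = "numeric", origin = "numeric"),
         prototype = prototype(spacing = c(2, 2, 2), origin = c(0, 0, 0)))

setValidity("GridVolume", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "'values' must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "'spacing' must be 3 positive finite numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
    if (length(msg)) msg else TRUE
})

#' HUVolume: a CT volume in Hounsfield units
#'
#' Carrier for individual respiratory-phase CT scans and for the derived
#' AVG/MIP/OVR planning volumes (water = 0 HU, air ~ -1000 HU).
#'
#' @param values 3D numeric array of CT numbers (HU).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) grid origin in mm.
#' @return An `HUVolume` object.
#' @examples
#' v <- HUVolume(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' spacing(v)
#' @aliases HUVolume-class
#' @exportClass HUVolume
#' @export
setClass("HUVolume", contains = "GridVolume")

setValidity("HUVolume", function(object) {
    if (any(!is.finite(object@values))) "HU values must be finite" else TRUE
})

#' RSPVolume: relative proton stopping power volume
#'
#' Per-voxel proton stopping power relative to water (water = 1), obtained from
#' an [HUVolume] through a [CalibrationCurve] via [huToRSP()].
#'
#' @param values 3D numeric array of relative stopping powers (>= 0).
#' @param spacing,origin grid geometry, as for [HUVolume()].
#' @return An `RSPVolume` object.
#' @aliases RSPVolume-class
#' @exportClass RSPVolume
#' @export
setClass("RSPVolume", contains = "GridVolume")

setValidity("RSPVolume", function(object) {
    if (any(!is.finite(object@values)) || any(object@values < 0))
        "stopping-power values must be finite and >= 0" else TRUE
})

#' DoseVolume: a 3D dose grid in percent of prescription
#'
#' Dose distributions are carried in % of the prescribed dose; plan doses are
#' normalized so that the minimum PTV dose is 95 (see
#' [normalizeToCoverage()]).
#'
#' @param values 3D numeric array of dose values (>= 0, % of prescription).
#' @param spacing,origin grid geometry, as for [HUVolume()].
#' @return A `DoseVolume` object.
#' @aliases DoseVolume-class
#' @exportClass DoseVolume
#' @export
setClass("DoseVolume", contains = "GridVolume")

setValidity("DoseVolume", function(object) {
    if (any(!is.finite(object@values)) || any(object@values < 0))
        "dose values must be finite and >= 0" else TRUE
})

#' MaskVolume: a binary structure mask
#'
#' Logical 3D grid marking a structure (GTV, ITV, PTV) on the same geometry as
#' the volume it annotates.
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing,origin grid geometry, as for [HUVolume()].
#' @return A `MaskVolume` object.
#' @aliases MaskVolume-class
#' @exportClass MaskVolume
#' @export
setClass("MaskVolume", contains = "GridVolume")

setValidity("MaskVolume", function(object) {
    if (!is.logical(object@values)) "mask values must be logical" else TRUE
})

## ---------------------------------------------------------------------------
## Phase series, calibration, structures
## ---------------------------------------------------------------------------

#' PhaseSeries: a 10-phase 4D CT series with per-phase tumor masks
#'
#' Ordered respiratory-phase volumes labelled 0%, 10%, ..., 90% (0% =
#' end-of-inspiration, 50% = end-of-expiration) together with the gross tumor
#' volume (GTV) contour on each phase, the peak-to-peak motion amplitude and
#' the phase weights used for 4D dose composition.
#'
#' @slot phases list of [HUVolume] objects, one per phase.
#' @slot gtvMasks list of [MaskVolume] objects, one per phase.
#' @slot phaseLabels numeric, phase labels in percent (0, 10, ..., 90).
#' @slot amplitude numeric, peak-to-peak cranial-caudal amplitude in cm.
#' @slot phaseWeights numeric, nonnegative weights summing to 1.
#'
#' @aliases PhaseSeries-class
#' @exportClass PhaseSeries
setClass("PhaseSeries",
         slots = c(phases = "list", gtvMasks = "list",
                   phaseLabels = "numeric", amplitude = "numeric",
                   phaseWeights = "numeric"))

setValidity("PhaseSeries", function(object) {
    msg <- character()
    n <- length(object@phases)
    if (n < 2L) msg <- c(msg, "need at least 2 phases")
    if (length(object@gtvMasks) != n)
        msg <- c(msg, "one GTV mask per phase required")
    if (length(object@phaseLabels) != n)
        msg <- c(msg, "one label per phase required")
    if (length(object@phaseWeights) != n ||
        abs(sum(object@phaseWeights) - 1) > 1e-9 ||
        any(object@phaseWeights < 0))
        msg <- c(msg, "phase weights must be nonnegative and sum to 1")
    if (n >= 2L) {
        ref <- object@phases[[1L]]
        okgeom <- vapply(c(object@phases, object@gtvMasks), function(v)
            sameGeometry(v, ref), logical(1))
        if (!all(okgeom)) msg <- c(msg, "all volumes must share grid geometry")
        if (any(!vapply(object@gtvMasks, function(m) any(m@values), logical(1))))
            msg <- c(msg, "each GTV mask must be nonempty")
    }
    if (length(msg)) msg else TRUE
})

#' CalibrationCurve: piecewise-linear HU to stopping-power calibration
#'
#' Breakpoints mapping CT numbers to relative proton stopping power,
#' interpolated linearly between anchors and clamped to the end breakpoints
#' outside the covered HU domain.
#'
#' @slot hu numeric, strictly increasing HU breakpoints covering at least
#'   \[-1000, 1600\].
#' @slot rsp numeric, nonnegative nondecreasing stopping powers at the
#'   breakpoints.
#'
#' @seealso [defaultCalibration()], [huToRSP()]
#' @aliases CalibrationCurve-class
#' @exportClass CalibrationCurve
setClass("CalibrationCurve", slots = c(hu = "numeric", rsp = "numeric"))

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    if (length(object@hu) < 2L || length(object@hu) != length(object@rsp))
        msg <- c(msg, "'hu' and 'rsp' must be equal-length vectors (>= 2)")
    else {
        if (any(diff(object@hu) <= 0))
            msg <- c(msg, "HU breakpoints must be strictly increasing")
        if (any(object@rsp < 0) || any(diff(object@rsp) < 0))
            msg <- c(msg, "RSP must be nonnegative and nondecreasing")
        if (object@hu[1L] > -1000 || object@hu[length(object@hu)] < 1600)
            msg <- c(msg, "calibration must cover at least [-1000, 1600] HU")
    }
    if (length(msg)) msg else TRUE
})

#' StructureSet: GTV/ITV/PTV target structures
#'
#' The per-phase gross tumor masks, their union (the internal target volume,
#' ITV) and the ITV expanded by a uniform setup margin (the planning target
#' volume, PTV), all on the planning grid.
#'
#' @slot gtvMasks list of per-phase [MaskVolume] objects.
#' @slot itv [MaskVolume], union of the GTV masks.
#' @slot ptv [MaskVolume], ITV dilated by `ptvMargin`.
#' @slot ptvMargin numeric, uniform PTV expansion margin in mm.
#'
#' @seealso [buildStructureSet()]
#' @aliases StructureSet-class
#' @exportClass StructureSet
setClass("StructureSet",
         slots = c(gtvMasks = "list", itv = "MaskVolume", ptv = "MaskVolume",
                   ptvMargin = "numeric"))

setValidity("StructureSet", function(object) {
    msg <- character()
    itv <- object@itv@values; ptv <- object@ptv@values
    for (g in object@gtvMasks)
        if (any(g@values & !itv)) { msg <- c(msg, "GTV not contained in ITV"); break }
    if (any(itv & !ptv)) msg <- c(msg, "ITV not contained in PTV")
    if (length(object@ptvMargin) != 1L || object@ptvMargin < 0)
        msg <- c(msg, "'ptvMargin' must be a single nonnegative number (mm)")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Depth-dose curves and beam hardware
## ---------------------------------------------------------------------------

#' DepthDoseCurve: a 1D proton depth-dose curve in water-equivalent depth
#'
#' Dose (relative units) sampled on a uniform water-equivalent depth grid (cm).
#'
#' @param depths numeric, strictly increasing uniform depth grid (cm WEPL).
#' @param dose numeric, nonnegative dose values, same length as `depths`.
#' @param nominalRange numeric, nominal range of the curve (cm), `NA` if
#'   unspecified.
#' @return A `DepthDoseCurve` object.
#' @aliases DepthDoseCurve-class
#' @exportClass DepthDoseCurve
#' @export
setClass("DepthDoseCurve",
         slots = c(depths = "numeric", dose = "numeric",
                   nominalRange = "numeric"))

setValidity("DepthDoseCurve", function(object) {
    msg <- character()
    if (length(object@depths) < 2L ||
        length(object@depths) != length(object@dose))
        msg <- c(msg, "'depths' and 'dose' must be equal-length vectors (>= 2)")
    else {
        if (any(diff(object@depths) <= 0))
            msg <- c(msg, "'depths' must be strictly increasing")
        if (any(object@dose < 0) || any(!is.finite(object@dose)))
            msg <- c(msg, "'dose' must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' SOBPCurve: a spread-out Bragg peak
#'
#' A [DepthDoseCurve] formed as a nonnegative weighted sum of pristine Bragg
#' peaks, with plateau normalized to 1.  The distal range `distalRange` is the
#' depth of the distal 90% isodose level and `modulation` is the distance
#' between proximal and distal 90% levels, per the double-scattering
#' convention.
#'
#' @slot distalRange numeric, depth of the distal 90% level (cm WEPL).
#' @slot modulation numeric, 90%-to-90% SOBP width (cm WEPL).
#' @slot peakRanges numeric, nominal ranges of the component pristine peaks.
#' @slot peakWeights numeric, nonnegative component weights.
#'
#' @seealso [buildSOBP()]
#' @aliases SOBPCurve-class
#' @exportClass SOBPCurve
setClass("SOBPCurve", contains = "DepthDoseCurve",
         slots = c(distalRange = "numeric", modulation = "numeric",
                   peakRanges = "numeric", peakWeights = "numeric"))

#' BeamGeometry: a coplanar parallel beam direction
#'
#' Beams are parallel (no source divergence) and restricted to the four
#' cardinal axial directions; the beam axis has no cranial-caudal component.
#' With +x = patient's left, +y = anterior, the gantry convention is:
#' 0 = anterior field (beam travels -y), 90 = left-lateral (-x),
#' 180 = posterior (+y), 270 = right-lateral (+x).  See [beamGeometry()].
#'
#' @slot gantryAngle numeric, gantry angle in degrees (0/90/180/270).
#' @slot axis integer, grid axis the beam travels along (1 = x, 2 = y).
#' @slot direction integer, +1 if the beam advances with increasing voxel
#'   index along `axis`, -1 otherwise.
#'
#' @aliases BeamGeometry-class
#' @exportClass BeamGeometry
setClass("BeamGeometry",
         slots = c(gantryAngle = "numeric", axis = "integer",
                   direction = "integer"),
         prototype = prototype(gantryAngle = 180, axis = 2L, direction = 1L))

setValidity("BeamGeometry", function(object) {
    msg <- character()
    if (!object@axis %in% c(1L, 2L))
        msg <- c(msg, "beam axis must be 1 (x) or 2 (y): coplanar fields only")
    if (!object@direction %in% c(-1L, 1L))
        msg <- c(msg, "'direction' must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' BeamField: one fully designed treatment field
#'
#' A double-scattering field: direction, prescribed distal range `R` and
#' modulation `M` (both on the 90% isodose definitions, cm WEPL), the
#' beam's-eye-view (BEV) aperture mask and range-compensator thickness map,
#' the design margins, the SOBP depth-dose curve and the field weight.
#'
#' @slot geometry [BeamGeometry].
#' @slot distalRange numeric, R (cm WEPL).
#' @slot modulation numeric, M (cm WEPL), 0 < M <= R.
#' @slot aperture logical matrix, BEV aperture opening.
#' @slot compensator numeric matrix, BEV compensator thickness (cm WEPL, >= 0).
#' @slot apertureMargin numeric, lateral aperture margin (cm, default 1).
#' @slot smoothingMargin numeric, compensator border-smoothing margin (cm,
#'   default 1).
#' @slot weight numeric, field weight in (0, 1].
#' @slot sobp [SOBPCurve] used to convert residual depth to dose.
#'
#' @seealso [fitField()], [computeFieldDose()]
#' @aliases BeamField-class
#' @exportClass BeamField
setClass("BeamField",
         slots = c(geometry = "BeamGeometry", distalRange = "numeric",
                   modulation = "numeric", aperture = "matrix",
                   compensator = "matrix", apertureMargin = "numeric",
                   smoothingMargin = "numeric", weight = "numeric",
                   sobp = "SOBPCurve"))

setValidity("BeamField", function(object) {
    msg <- character()
    if (object@modulation <= 0 || object@modulation > object@distalRange)
        msg <- c(msg, "need 0 < M <= R")
    if (!any(object@aperture)) msg <- c(msg, "aperture mask must be nonempty")
    if (any(object@compensator < 0))
        msg <- c(msg, "compensator thickness must be >= 0")
    if (object@weight <= 0 || object@weight > 1)
        msg <- c(msg, "field weight must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Plans and reports
## ---------------------------------------------------------------------------

#' ProtonPlan: a complete planning strategy instance
#'
#' One of the four strategies (AVG, MIP, OVR, mAVG): the planning CT the
#' strategy is designed on, the HU-to-stopping-power calibration, the designed
#' fields, the coverage normalization factor and the normalized 3D (apparent)
#' plan dose.
#'
#' @slot strategy character, one of "AVG", "MIP", "OVR", "mAVG".
#' @slot planningCT [HUVolume] the plan was designed on.
#' @slot calibration [CalibrationCurve].
#' @slot fields list of [BeamField] objects (equal weights summing to 1).
#' @slot normalization numeric, scale factor making min PTV dose equal 95.
#' @slot structures [StructureSet].
#' @slot dose [DoseVolume], the normalized 3D plan dose.
#' @slot fieldMargins numeric, per-field distal range increment applied on top
#'   of the AVG design (cm WEPL; zero for non-mAVG plans).
#'
#' @seealso [buildPlan()], [applyMargins()]
#' @aliases ProtonPlan-class
#' @exportClass ProtonPlan
setClass("ProtonPlan",
         slots = c(strategy = "character", planningCT = "HUVolume",
                   calibration = "CalibrationCurve", fields = "list",
                   normalization = "numeric", structures = "StructureSet",
                   dose = "DoseVolume", fieldMargins = "numeric"))

setValidity("ProtonPlan", function(object) {
    msg <- character()
    if (!object@strategy %in% c("AVG", "MIP", "OVR", "mAVG"))
        msg <- c(msg, "unknown strategy")
    if (length(object@fields) < 1L)
        msg <- c(msg, "plan needs at least one field")
    else {
        w <- vapply(object@fields, function(f) f@weight, numeric(1))
        if (abs(sum(w) - 1) > 1e-6)
            msg <- c(msg, "field weights must sum to 1")
        if (max(w) - min(w) > 1e-9)
            msg <- c(msg, "fields must be equally weighted")
    }
    if (length(object@normalization) != 1L || object@normalization <= 0)
        msg <- c(msg, "normalization factor must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' PhantomConfig: parameters of the synthetic moving-liver phantom
#'
#' Describes the liver-dome geometry, tissue CT numbers, tumor and breathing
#' motion emulated by [generatePhantom()].  Defaults emulate a liver-dome
#' tumor with 1.3 cm peak-to-peak cranial-caudal motion between lung
#' (-900 to -300 HU) and liver (100-130 HU) tissue on a 96^3 grid at 2 mm
#' isotropic spacing.
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot voxelSpacing numeric, isotropic voxel spacing in mm.
#' @slot amplitude numeric, peak-to-peak cranial-caudal amplitude in cm.
#' @slot tumorCenter numeric(3), tumor center (mm, world) at the 0% phase.
#' @slot tumorDiameter numeric, tumor diameter in mm.
#' @slot huLiver numeric(2), liver HU interval.
#' @slot huLung numeric(2), lung HU interval.
#' @slot huTumor numeric, tumor HU.
#' @slot huSoftTissue numeric, chest/abdominal wall HU.
#' @slot nPhases integer, number of respiratory phases (default 10).
#' @slot noiseSD numeric, sd of the seeded static Gaussian HU noise field.
#' @slot seed integer, RNG seed for the noise field.
#' @slot flankOffset numeric, height (mm) of the dome-flank surface above
#'   the tumor center at the tumor's axial position.
#' @slot flankSlope numeric(2), surface gradient (mm of height per mm) along
#'   x and y; the flank ascends toward the anterior-left dome top.
#' @slot domeTop numeric, z (mm) at which the rising flank plateaus (the
#'   dome top).
#' @slot liverFloor numeric, z (mm) below which everything is liver (the
#'   liver bulk under the lung bases).
#' @slot shellThickness numeric, body-wall (soft tissue) thickness at the
#'   lateral grid faces (mm).
#'
#' @seealso [phantomConfig()], [generatePhantom()]
#' @aliases PhantomConfig-class
#' @exportClass PhantomConfig
setClass("PhantomConfig",
         slots = c(gridShape = "integer", voxelSpacing = "numeric",
                   amplitude = "numeric", tumorCenter = "numeric",
                   tumorDiameter = "numeric", huLiver = "numeric",
                   huLung = "numeric", huTumor = "numeric",
                   huSoftTissue = "numeric", nPhases = "integer",
                   noiseSD = "numeric", seed = "integer",
                   flankOffset = "numeric", flankSlope = "numeric",
                   domeTop = "numeric", liverFloor = "numeric",
                   shellThickness = "numeric"))

setValidity("PhantomConfig", function(object) {
    msg <- character()
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
        msg <- c(msg, "'gridShape' must be 3 integers >= 8")
    if (object@voxelSpacing <= 0) msg <- c(msg, "'voxelSpacing' must be > 0")
    if (object@nPhases < 2L) msg <- c(msg, "need at least 2 phases")
    if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
    if (object@tumorDiameter <= 0) msg <- c(msg, "tumor diameter must be > 0")
    if (length(object@huLiver) != 2L || diff(object@huLiver) < 0)
        msg <- c(msg, "'huLiver' must be a nondecreasing interval")
    if (length(object@huLung) != 2L || diff(object@huLung) < 0)
        msg <- c(msg, "'huLung' must be a nondecreasing interval")
    ## tumor sphere must fit inside the grid at all phases (it translates
    ## cranially by up to `amplitude` cm)
    ext <- object@gridShape * object@voxelSpacing
    r <- object@tumorDiameter / 2
    lo <- object@tumorCenter - r
    hi <- object@tumorCenter + r
    hi[3] <- hi[3] + 10 * object@amplitude
    if (any(lo < 0) || any(hi > ext))
        msg <- c(msg, "tumor sphere leaves the grid during the breathing cycle")
    if (length(msg)) msg else TRUE
})

#' PhaseReport: per-phase and 4D acceptability report for a plan
#'
#' Produced by [acceptabilityReport()]: per-phase dose indices of the plan
#' recomputed with frozen beam hardware, their deltas against the 3D apparent
#' plan, per-phase verdicts under the +/- tolerance criterion, and the same
#' quantities for the equal-weighted 4D composite dose.
#'
#' @slot strategy character, plan strategy label.
#' @slot tolerance numeric, acceptability bound in percentage points
#'   (inclusive, default 2).
#' @slot baseline numeric, named 3D-plan indices (D95, D99, D100, CI).
#' @slot phaseTable data.frame, one row per phase with indices, deltas and
#'   verdict.
#' @slot composite numeric, named indices of the 4D composite dose.
#' @slot compositeDeltas numeric, named deltas of the composite D95/D99/D100
#'   versus baseline (percentage points).
#' @slot verdict4D logical, whether the composite passes the criterion.
#' @slot compositeDose [DoseVolume], the 4D composite dose.
#'
#' @aliases PhaseReport-class
#' @exportClass PhaseReport
setClass("PhaseReport",
         slots = c(strategy = "character", tolerance = "numeric",
                   baseline = "numeric", phaseTable = "data.frame",
                   composite = "numeric", compositeDeltas = "numeric",
                   verdict4D = "logical", compositeDose = "DoseVolume"))
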