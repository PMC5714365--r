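#' @include utils.R
NULL

## ---------------------------------------------------------------------------
## Constructors
## ---------------------------------------------------------------------------

newGridVolume <- function(class, values, spacing, origin) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
        stop("'values' must be a 3D array", call. = FALSE)
    new(class, values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' @rdname HUVolume-class
#' @export
HUVolume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
    storage.mode(values) <- "double"
    newGridVolume("HUVolume", values, spacing, origin)
}

#' @rdname RSPVolume-class
#' @export
RSPVolume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
    storage.mode(values) <- "double"
    newGridVolume("RSPVolume", values, spacing, origin)
}

#' @rdname DoseVolume-class
#' @export
DoseVolume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
    storage.mode(values) <- "double"
    newGridVolume("DoseVolume", values, spacing, origin)
}

#' @rdname MaskVolume-class
#' @export
MaskVolume <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
    storage.mode(values) <- "logical"
    newGridVolume("MaskVolume", values, spacing, origin)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' Voxel values of a grid volume
#'
#' @param x a [GridVolume] derivative.
#' @return The underlying 3D array.
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname voxelValues
#' @export
setMethod("voxelValues", "GridVolume", function(x) x@values)

#' Voxel spacing (mm) of a grid volume
#'
#' @param x a [GridVolume] derivative.
#' @return numeric(3), per-axis spacing in mm.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname spacing
#' @export
setMethod("spacing", "GridVolume", function(x) x@spacing)

#' World origin (mm) of a grid volume
#'
#' @param x a [GridVolume] derivative.
#' @return numeric(3), grid-corner position in mm.
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname gridOrigin
#' @export
setMethod("gridOrigin", "GridVolume", function(x) x@origin)

#' @rdname PhaseSeries-class
#' @param x,object a `PhaseSeries`.
#' @export
setGeneric("nPhases", function(x) standardGeneric("nPhases"))

#' @rdname PhaseSeries-class
#' @export
setMethod("nPhases", "PhaseSeries", function(x) length(x@phases))

#' @rdname PhaseSeries-class
#' @export
setGeneric("phaseLabels", function(x) standardGeneric("phaseLabels"))

#' @rdname PhaseSeries-class
#' @export
setMethod("phaseLabels", "PhaseSeries", function(x) x@phaseLabels)

#' @rdname PhaseSeries-class
#' @export
setGeneric("phaseVolumes", function(x) standardGeneric("phaseVolumes"))

#' @rdname PhaseSeries-class
#' @export
setMethod("phaseVolumes", "PhaseSeries", function(x) x@phases)

#' @rdname PhaseSeries-class
#' @export
setGeneric("gtvMasks", function(x) standardGeneric("gtvMasks"))

#' @rdname PhaseSeries-class
#' @export
setMethod("gtvMasks", "PhaseSeries", function(x) x@gtvMasks)

#' @rdname StructureSet-class
#' @param x,object a `StructureSet`.
#' @export
setMethod("gtvMasks", "StructureSet", function(x) x@gtvMasks)

#' @rdname StructureSet-class
#' @export
setGeneric("itvMask", function(x) standardGeneric("itvMask"))

#' @rdname StructureSet-class
#' @export
setMethod("itvMask", "StructureSet", function(x) x@itv)

#' @rdname StructureSet-class
#' @export
setGeneric("ptvMask", function(x) standardGeneric("ptvMask"))

#' @rdname StructureSet-class
#' @export
setMethod("ptvMask", "StructureSet", function(x) x@ptv)

#' Distal range and modulation accessors
#'
#' `distalRange()` returns the prescribed distal 90% range R (cm WEPL) and
#' `modulation()` the 90%-to-90% SOBP width M (cm WEPL) of a field, SOBP or
#' plan (per-field vector for plans).
#'
#' @param x a [BeamField], [SOBPCurve] or [ProtonPlan].
#' @return numeric (scalar, or per-field vector for plans).
#' @export
setGeneric("distalRange", function(x) standardGeneric("distalRange"))

#' @rdname distalRange
#' @export
setGeneric("modulation", function(x) standardGeneric("modulation"))

#' @rdname distalRange
#' @export
setMethod("distalRange", "BeamField", function(x) x@distalRange)

#' @rdname distalRange
#' @export
setMethod("modulation", "BeamField", function(x) x@modulation)

#' @rdname distalRange
#' @export
setMethod("distalRange", "SOBPCurve", function(x) x@distalRange)

#' @rdname distalRange
#' @export
setMethod("modulation", "SOBPCurve", function(x) x@modulation)

#' @rdname distalRange
#' @export
setMethod("distalRange", "ProtonPlan", function(x)
    vapply(x@fields, function(f) f@distalRange, numeric(1)))

#' @rdname distalRange
#' @export
setMethod("modulation", "ProtonPlan", function(x)
    vapply(x@fields, function(f) f@modulation, numeric(1)))

#' @rdname ProtonPlan-class
#' @param x,object a `ProtonPlan`.
#' @export
setGeneric("planStrategy", function(x) standardGeneric("planStrategy"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planStrategy", "ProtonPlan", function(x) x@strategy)

#' @rdname ProtonPlan-class
#' @export
setGeneric("planFields", function(x) standardGeneric("planFields"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planFields", "ProtonPlan", function(x) x@fields)

#' @rdname ProtonPlan-class
#' @export
setGeneric("planDose", function(x) standardGeneric("planDose"))

#' @rdname ProtonPlan-class
#' @export
setMethod("planDose", "ProtonPlan", function(x) x@dose)

#' @rdname ProtonPlan-class
#' @export
setGeneric("normalizationFactor", function(x)
    standardGeneric("normalizationFactor"))

#' @rdname ProtonPlan-class
#' @export
setMethod("normalizationFactor", "ProtonPlan", function(x) x@normalization)

#' @rdname BeamField-class
#' @param x,object a `BeamField`.
#' @export
setGeneric("apertureMask", function(x) standardGeneric("apertureMask"))

#' @rdname BeamField-class
#' @export
setMethod("apertureMask", "BeamField", function(x) x@aperture)

#' @rdname BeamField-class
#' @export
setGeneric("compensatorMap", function(x) standardGeneric("compensatorMap"))

#' @rdname BeamField-class
#' @export
setMethod("compensatorMap", "BeamField", function(x) x@compensator)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "GridVolume", function(object) {
    d <- dim(object@values)
    cat(sprintf("%s: %d x %d x %d voxels, spacing %s mm\n",
                class(object), d[1], d[2], d[3],
                paste(format(object@spacing), collapse = " x ")))
    v <- object@values
    if (is.logical(v)) {
        cat(sprintf("  %d voxels set (%.2f cm^3)\n", sum(v),
                    sum(v) * prod(object@spacing) / 1000))
    } else {
        cat(sprintf("  value range [%.4g, %.4g], mean %.4g\n",
                    min(v), max(v), mean(v)))
    }
    invisible(NULL)
})

setMethod("show", "PhaseSeries", function(object) {
    d <- dim(object@phases[[1]]@values)
    cat(sprintf("PhaseSeries: %d phases (%s%%), grid %d x %d x %d\n",
                nPhases(object),
                paste(object@phaseLabels, collapse = ","), d[1], d[2], d[3]))
    cat(sprintf("  peak-to-peak amplitude: %.2f cm cranial-caudal\n",
                object@amplitude))
    invisible(NULL)
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf("CalibrationCurve: %d breakpoints, HU [%g, %g] -> RSP [%g, %g]\n",
                length(object@hu), min(object@hu), max(object@hu),
                min(object@rsp), max(object@rsp)))
    invisible(NULL)
})

setMethod("show", "StructureSet", function(object) {
    vol <- function(m) sum(m@values) * prod(m@spacing) / 1000
    cat(sprintf("StructureSet: %d GTV phases; ITV %.1f cm^3; PTV %.1f cm^3 (margin %g mm)\n",
                length(object@gtvMasks), vol(object@itv), vol(object@ptv),
                object@ptvMargin))
    invisible(NULL)
})

setMethod("show", "DepthDoseCurve", function(object) {
    cat(sprintf("%s: %d depth samples on [%.2f, %.2f] cm, peak dose %.3f\n",
                class(object), length(object@depths), min(object@depths),
                max(object@depths), max(object@dose)))
    if (is(object, "SOBPCurve"))
        cat(sprintf("  R = %.3f cm, M = %.3f cm (90%%-90%%), %d pristine peaks\n",
                    object@distalRange, object@modulation,
                    length(object@peakRanges)))
    invisible(NULL)
})

setMethod("show", "BeamField", function(object) {
    cat(sprintf("BeamField: gantry %g deg, R = %.2f cm, M = %.2f cm, weight %.2f\n",
                object@geometry@gantryAngle, object@distalRange,
                object@modulation, object@weight))
    cat(sprintf("  aperture: %d BEV pixels open; compensator thickness [%.2f, %.2f] cm\n",
                sum(object@aperture), min(object@compensator),
                max(object@compensator)))
    invisible(NULL)
})

setMethod("show", "ProtonPlan", function(object) {
    cat(sprintf("ProtonPlan (%s): %d fields, normalization %.4f\n",
                object@strategy, length(object@fields), object@normalization))
    for (f in object@fields)
        cat(sprintf("  gantry %3g deg: R = %6.2f cm, M = %6.2f cm\n",
                    f@geometry@gantryAngle, f@distalRange, f@modulation))
    invisible(NULL)
})

setMethod("show", "PhantomConfig", function(object) {
    cat(sprintf("PhantomConfig: grid %s at %g mm, %d phases, amplitude %.2f cm\n",
                paste(object@gridShape, collapse = "x"), object@voxelSpacing,
                object@nPhases, object@amplitude))
    cat(sprintf("  tumor: %g mm diameter at (%s) mm, %g HU; liver [%g, %g] HU; lung [%g, %g] HU\n",
                object@tumorDiameter,
                paste(object@tumorCenter, collapse = ", "),
                object@huTumor, object@huLiver[1], object@huLiver[2],
                object@huLung[1], object@huLung[2]))
    invisible(NULL)
})

setMethod("show", "PhaseReport", function(object) {
    cat(sprintf("PhaseReport (%s plan), tolerance +/- %g points\n",
                object@strategy, object@tolerance))
    cat(sprintf("  3D baseline: D95 = %.1f, D99 = %.1f, D100 = %.1f, CI = %.2f\n",
                object@baseline["D95"], object@baseline["D99"],
                object@baseline["D100"], object@baseline["CI"]))
    tab <- object@phaseTable
    cat("  per-phase deltas (points):\n")
    print(tab[, c("phase", "dD95", "dD99", "dD100", "pass")],
          row.names = FALSE, digits = 3)
    cat(sprintf("  4D composite: D95 = %.1f (%+.1f), D99 = %.1f (%+.1f), D100 = %.1f (%+.1f) -> %s\n",
                object@composite["D95"], object@compositeDeltas["D95"],
                object@composite["D99"], object@compositeDeltas["D99"],
                object@composite["D100"], object@compositeDeltas["D100"],
                if (object@verdict4D) "PASS" else "FAIL"))
    invisible(NULL)
})
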