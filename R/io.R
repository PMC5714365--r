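#' @include evaluation.R
NULL

#' Read and write grid volumes as NIfTI
#'
#' Thin wrappers around RNifti preserving spacing (mm); masks are stored as
#' 0/1 volumes.
#'
#' @param vol a [GridVolume] derivative.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param what class of volume to return: one of `"HUVolume"`,
#'   `"DoseVolume"`, `"RSPVolume"`, `"MaskVolume"`.
#' @return `writeVolume()` returns `path` invisibly; `readVolume()` the
#'   requested volume object.
#' @export
writeVolume <- function(vol, path) {
    stopifnot(is(vol, "GridVolume"))
    v <- vol@values
    if (is.logical(v)) { v <- v * 1L }
    img <- RNifti::asNifti(v, pixdim = vol@spacing)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path, what = "HUVolume") {
    img <- RNifti::readNifti(path)
    sp <- attr(img, "pixdim")[1:3]
    arr <- array(as.numeric(img), dim(img)[1:3])
    switch(what,
           HUVolume = HUVolume(arr, spacing = sp),
           DoseVolume = DoseVolume(arr, spacing = sp),
           RSPVolume = RSPVolume(arr, spacing = sp),
           MaskVolume = MaskVolume(arr > 0.5, spacing = sp),
           stop("unknown volume class '", what, "'", call. = FALSE))
}

#' Write a phase series to a directory
#'
#' One NIfTI per phase (`phase_00.nii.gz`, ...) and per GTV mask
#' (`gtv_00.nii.gz`, ...), plus a JSON sidecar (`series.json`) recording
#' phase labels, amplitude and weights.
#'
#' @param series a [PhaseSeries].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePhantom <- function(series, dir) {
    stopifnot(is(series, "PhaseSeries"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(nPhases(series))) {
        lab <- sprintf("%02d", series@phaseLabels[i])
        writeVolume(series@phases[[i]], file.path(dir, paste0("phase_", lab, ".nii.gz")))
        writeVolume(series@gtvMasks[[i]], file.path(dir, paste0("gtv_", lab, ".nii.gz")))
    }
    side <- list(phaseLabels = series@phaseLabels,
                 amplitude_cm = series@amplitude,
                 phaseWeights = series@phaseWeights,
                 spacing_mm = series@phases[[1]]@spacing)
    jsonlite::write_json(side, file.path(dir, "series.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' Read a phase series written by [writePhantom()]
#'
#' @param dir directory containing `phase_*.nii.gz`, `gtv_*.nii.gz` and
#'   `series.json`.
#' @return A [PhaseSeries].
#' @export
readPhantom <- function(dir) {
    side <- jsonlite::read_json(file.path(dir, "series.json"),
                                simplifyVector = TRUE)
    labs <- side$phaseLabels
    phases <- lapply(labs, function(l)
        readVolume(file.path(dir, sprintf("phase_%02d.nii.gz", l)), "HUVolume"))
    masks <- lapply(labs, function(l)
        readVolume(file.path(dir, sprintf("gtv_%02d.nii.gz", l)), "MaskVolume"))
    new("PhaseSeries", phases = phases, gtvMasks = masks,
        phaseLabels = as.numeric(labs),
        amplitude = as.numeric(side$amplitude_cm),
        phaseWeights = as.numeric(side$phaseWeights))
}

#' Read / write a calibration curve as two-column CSV
#'
#' CSV with columns `hu` and `rsp`.
#'
#' @param path CSV file path.
#' @param cal a [CalibrationCurve].
#' @return `readCalibration()` a [CalibrationCurve]; `writeCalibration()`
#'   `path` invisibly.
#' @export
readCalibration <- function(path) {
    d <- read.csv(path)
    if (!all(c("hu", "rsp") %in% names(d)))
        stop("calibration CSV needs columns 'hu' and 'rsp'", call. = FALSE)
    new("CalibrationCurve", hu = as.numeric(d$hu), rsp = as.numeric(d$rsp))
}

#' @rdname readCalibration
#' @export
writeCalibration <- function(cal, path) {
    stopifnot(is(cal, "CalibrationCurve"))
    write.csv(data.frame(hu = cal@hu, rsp = cal@rsp), path,
              row.names = FALSE)
    invisible(path)
}

#' Export a depth-dose curve as two-column CSV
#'
#' @param curve a [DepthDoseCurve].
#' @param path CSV file path (columns `depth_cm`, `dose`).
#' @return `path`, invisibly.
#' @export
writeDepthDose <- function(curve, path) {
    stopifnot(is(curve, "DepthDoseCurve"))
    write.csv(data.frame(depth_cm = curve@depths, dose = curve@dose), path,
              row.names = FALSE)
    invisible(path)
}

#' Serialize a plan description to JSON
#'
#' Strategy, per-field gantry angle, distal range, modulation, margins and
#' weight, the applied field-specific margins and the normalization factor.
#' The serialization contains the full beam-hardware description except the
#' (grid-sized) aperture and compensator maps; it is the record that
#' per-phase recomputation must keep frozen.
#'
#' @param plan a [ProtonPlan].
#' @param path JSON file path, or `NULL` to return the JSON string.
#' @return The JSON string (invisibly when written to a file).
#' @export
planToJSON <- function(plan, path = NULL) {
    stopifnot(is(plan, "ProtonPlan"))
    obj <- list(
        strategy = plan@strategy,
        ptvMargin_mm = plan@structures@ptvMargin,
        normalization = plan@normalization,
        fieldMargins_cm = plan@fieldMargins,
        fields = lapply(plan@fields, function(f) list(
            gantryAngle = f@geometry@gantryAngle,
            distalRange_cm = f@distalRange,
            modulation_cm = f@modulation,
            apertureMargin_cm = f@apertureMargin,
            smoothingMargin_cm = f@smoothingMargin,
            weight = f@weight)))
    js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
    if (!is.null(path)) {
        writeLines(js, path)
        return(invisible(as.character(js)))
    }
    as.character(js)
}
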