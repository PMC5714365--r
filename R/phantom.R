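#' @include volumes.R
NULL

#' Configure the synthetic moving-liver phantom
#'
#' Creates a [PhantomConfig] describing an idealized liver-dome anatomy.
#' The liver surface is a planar dome flank that ascends from the
#' posterior-right toward an anterior-left dome top (plateau at `domeTop`),
#' with lung above the surface and a soft-tissue body wall at the lateral
#' grid faces; below `liverFloor` everything is liver (the liver bulk under
#' the lung bases).  A spherical tumor sits just beneath the flank, abutting
#' the diaphragmatic surface, and translates rigidly with the liver in the
#' cranial-caudal direction following a sinusoidal breathing surrogate
#' ([motionDisplacement()]).  The planar flank makes the motion-induced
#' water-equivalent path-length change uniform across the rays of a coplanar
#' field, the regime in which a single per-field distal margin is the
#' appropriate compensation.
#'
#' The defaults emulate a patient at the upper end of the clinically
#' observed 0.5-1.3 cm peak-to-peak liver-dome motion range.  Liver voxels
#' take a deterministic axial HU gradient across the liver interval that
#' moves with the liver (100-130 HU by default); lung voxels a static axial
#' gradient across the lung interval.  A single seeded Gaussian noise field
#' (identical across phases) emulates CT noise without changing geometry,
#' so a zero-amplitude series is bit-identical across phases.
#'
#' @param gridShape integer(3), voxels per axis (default 96^3).
#' @param voxelSpacing numeric, isotropic spacing in mm (default 2).
#' @param amplitude numeric, peak-to-peak cranial-caudal amplitude in cm
#'   (default 1.3).
#' @param tumorCenter numeric(3), tumor center in mm at the 0% phase
#'   (default grid-centered axially, just below the dome flank).
#' @param tumorDiameter numeric, mm (default 24).
#' @param huLiver numeric(2), liver HU interval (default `c(100, 130)`).
#' @param huLung numeric(2), lung HU interval (default `c(-900, -300)`).
#' @param huTumor numeric, tumor HU (default 60, soft-tissue-like and
#'   distinct from liver).
#' @param huSoftTissue numeric, body-wall HU (default 40).
#' @param nPhases integer, number of phases (default 10).
#' @param noiseSD numeric, HU noise standard deviation (default 10).
#' @param seed integer, seed for the noise field (default 1).
#' @param flankOffset numeric, height (mm) of the flank surface above the
#'   tumor center at the tumor's axial position (default 30; the tumor
#'   sphere abuts the surface).
#' @param flankSlope numeric(2), surface rise per mm along x and y
#'   (default `c(2, 2)`).
#' @param domeTop numeric, plateau z of the dome top in mm (default 160).
#' @param liverFloor numeric, z in mm below which all tissue is liver
#'   (default 30).
#' @param shellThickness numeric, body-wall thickness in mm (default 10).
#' @return A [PhantomConfig].
#' @examples
#' cfg <- phantomConfig(gridShape = c(48, 48, 48), voxelSpacing = 4)
#' cfg
#' @export
phantomConfig <- function(gridShape = c(96L, 96L, 96L), voxelSpacing = 2,
                          amplitude = 1.3, tumorCenter = NULL,
                          tumorDiameter = 24, huLiver = c(100, 130),
                          huLung = c(-900, -300), huTumor = 60,
                          huSoftTissue = 40, nPhases = 10L, noiseSD = 10,
                          seed = 1L, flankOffset = 30,
                          flankSlope = c(2, 2), domeTop = NULL,
                          liverFloor = NULL, shellThickness = 10) {
    ext <- gridShape * voxelSpacing
    if (is.null(tumorCenter))
        tumorCenter <- c(ext[1] / 2, ext[2] / 2, 0.52 * ext[3])
    if (is.null(domeTop)) domeTop <- min(0.83 * ext[3], ext[3] - 16)
    if (is.null(liverFloor)) liverFloor <- 0.16 * ext[3]
    new("PhantomConfig", gridShape = as.integer(gridShape),
        voxelSpacing = as.numeric(voxelSpacing),
        amplitude = as.numeric(amplitude),
        tumorCenter = as.numeric(tumorCenter),
        tumorDiameter = as.numeric(tumorDiameter),
        huLiver = as.numeric(huLiver), huLung = as.numeric(huLung),
        huTumor = as.numeric(huTumor),
        huSoftTissue = as.numeric(huSoftTissue),
        nPhases = as.integer(nPhases), noiseSD = as.numeric(noiseSD),
        seed = as.integer(seed), flankOffset = as.numeric(flankOffset),
        flankSlope = as.numeric(flankSlope), domeTop = as.numeric(domeTop),
        liverFloor = as.numeric(liverFloor),
        shellThickness = as.numeric(shellThickness))
}

#' Cranial-caudal displacement of the liver at a respiratory phase
#'
#' Sinusoidal breathing surrogate anchored to the 4D CT phase convention:
#' zero displacement at the 0% phase (end-of-inspiration) and the full
#' peak-to-peak amplitude at the 50% phase (end-of-expiration, liver shifted
#' cranially):
#' `displacement = amplitude * (1 - cos(2 * pi * phase / 100)) / 2`.
#'
#' @param phaseLabel numeric, phase label(s) in percent; must be multiples of
#'   10 in \[0, 90\].
#' @param amplitude numeric, peak-to-peak amplitude in cm (>= 0).
#' @return numeric, cranial displacement in cm (same length as `phaseLabel`).
#' @examples
#' motionDisplacement(0, 1.3)   # 0 at end-inspiration
#' motionDisplacement(50, 1.3)  # full amplitude at end-expiration
#' @export
motionDisplacement <- function(phaseLabel, amplitude) {
    if (length(amplitude) != 1L || amplitude < 0)
        stop("'amplitude' must be a single nonnegative number (cm)",
             call. = FALSE)
    if (any(!phaseLabel %in% seq(0, 90, by = 10)))
        stop("invalid phase label: must be one of 0, 10, ..., 90",
             call. = FALSE)
    amplitude * (1 - cos(2 * pi * phaseLabel / 100)) / 2
}

#' Generate a deterministic synthetic 4D phase series
#'
#' Builds `nPhases` HU volumes and per-phase GTV masks from a
#' [PhantomConfig].  Per phase, the liver surface (the planar dome flank
#' clamped between `liverFloor` and `domeTop`) and the embedded tumor sphere
#' translate cranially by [motionDisplacement()]; voxels below the shifted
#' surface get liver HU, voxels above get lung HU, the lateral body wall
#' gets soft-tissue HU, and the tumor sphere gets `huTumor` (the tumor may
#' abut or slightly bulge through the diaphragmatic surface, as dome lesions
#' do).  A single seeded noise field is added to every phase, so identical
#' seeds give bit-identical output.
#'
#' @param config a [PhantomConfig].
#' @return A [PhaseSeries] with uniform phase weights.
#' @examples
#' cfg <- phantomConfig(gridShape = c(40, 40, 40), voxelSpacing = 4,
#'                      noiseSD = 0)
#' ser <- generatePhantom(cfg)
#' ser
#' @export
generatePhantom <- function(config) {
    stopifnot(is(config, "PhantomConfig"))
    validObject(config)
    d <- config@gridShape
    sp <- rep(config@voxelSpacing, 3)
    ext <- d * sp
    xs <- axisCoords(d[1], sp[1], 0)
    ys <- axisCoords(d[2], sp[2], 0)
    zs <- axisCoords(d[3], sp[3], 0)

    cx <- config@tumorCenter[1]; cy <- config@tumorCenter[2]
    cz <- config@tumorCenter[3]
    r <- config@tumorDiameter / 2

    ## planar dome flank ascending along +x/+y, clamped to floor and top
    surf <- outer(cz + config@flankOffset + config@flankSlope[1] * (xs - cx),
                  config@flankSlope[2] * (ys - cy), `+`)
    surf <- pmin(pmax(surf, config@liverFloor), config@domeTop)

    ## static body wall at the lateral faces
    th <- config@shellThickness
    wall2 <- outer(xs < th | xs > ext[1] - th,
                   ys < th | ys > ext[2] - th, `|`)
    wall <- array(wall2, d)

    ## static lung HU gradient along z
    lungZ <- config@huLung[1] +
        diff(config@huLung) * pmin(pmax(zs / ext[3], 0), 1)

    ## seeded static noise field
    noise <- if (config@noiseSD > 0) {
        set.seed(config@seed)
        array(rnorm(prod(d), 0, config@noiseSD), d)
    } else NULL

    labels <- seq(0, by = 100 / config@nPhases, length.out = config@nPhases)
    if (config@nPhases == 10L) labels <- seq(0, 90, by = 10)
    dx2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)

    phases <- vector("list", config@nPhases)
    masks <- vector("list", config@nPhases)
    for (p in seq_len(config@nPhases)) {
        disp <- 10 * config@amplitude *
            (1 - cos(2 * pi * labels[p] / 100)) / 2  # mm, cranial
        liver <- array(FALSE, d)
        for (k in seq_len(d[3]))
            liver[, , k] <- surf + disp >= zs[k]
        ## liver HU gradient in the moving liver frame
        liverZ <- config@huLiver[1] + diff(config@huLiver) *
            pmin(pmax((zs - disp) / ext[3], 0), 1)
        hu <- array(rep(lungZ, each = d[1] * d[2]), d)
        liverArr <- array(rep(liverZ, each = d[1] * d[2]), d)
        hu[liver] <- liverArr[liver]
        hu[wall] <- config@huSoftTissue
        ## tumor sphere, rigid with the liver
        tum <- array(FALSE, d)
        for (k in seq_len(d[3])) {
            dz2 <- (zs[k] - cz - disp)^2
            if (dz2 <= r^2) tum[, , k] <- dx2 <= r^2 - dz2
        }
        if (!any(tum))
            stop("geometry error: tumor not resolved on the grid",
                 call. = FALSE)
        hu[tum] <- config@huTumor
        if (!is.null(noise)) hu <- hu + noise
        phases[[p]] <- HUVolume(hu, spacing = sp)
        masks[[p]] <- MaskVolume(tum, spacing = sp)
    }
    new("PhaseSeries", phases = phases, gtvMasks = masks,
        phaseLabels = labels, amplitude = config@amplitude,
        phaseWeights = rep(1 / config@nPhases, config@nPhases))
}
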