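#' @include volumes.R
NULL

## depth grid step for all 1D beam-model curves (cm WEPL); finer than any
## design margin decided downstream
DEPTH_STEP <- 0.05

#' Analytic pristine Bragg curve
#'
#' Closed-form depth-dose model of a monoenergetic proton beam in water: a
#' power-law stopping approximation (exponent p = 1.77 of the range-energy
#' relation) giving dose proportional to
#' `(R - z)^(1/p - 1) + k (R - z)^(1/p)` before the peak, convolved with a
#' Gaussian range-straggling kernel of width `sigma = 0.012 * R^0.935` cm.
#' The entrance term produces the slowly rising plateau, the convolution the
#' smooth peak and distal falloff.  The curve is normalized to 1 at the peak.
#'
#' @param rangeCm numeric, nominal range R in cm WEPL (> 0).
#' @param maxDepth numeric, extent of the depth grid (default `rangeCm + 3`).
#' @param step numeric, depth grid step in cm (default 0.05).
#' @param rangeSpread numeric, additional Gaussian range spread in cm
#'   (beamline energy spread, added in quadrature to the intrinsic
#'   straggling; default 0: pure straggling).
#' @return A [DepthDoseCurve] with `nominalRange = rangeCm`.
#' @examples
#' pb <- pristineBragg(12)
#' pb@depths[which.max(pb@dose)]  # peak close to 12 cm
#' @export
pristineBragg <- function(rangeCm, maxDepth = rangeCm + 3,
                          step = DEPTH_STEP, rangeSpread = 0) {
    if (length(rangeCm) != 1L || !is.finite(rangeCm) || rangeCm <= 0)
        stop("'rangeCm' must be a single positive number", call. = FALSE)
    depths <- seq(0, maxDepth, by = step)
    p <- 1.77
    k <- 0.012 * (1 + 0.6 * p)          # entrance-slope coefficient
    ## bin-averaged unstraggled curve (integrable singularity at z = R):
    ## antiderivative of (R-z)^(1/p-1) + k (R-z)^(1/p)
    anti <- function(z) {
        u <- pmax(rangeCm - z, 0)
        -(p * u^(1 / p) + k * p / (1 + p) * u^(1 + 1 / p))
    }
    lo <- depths - step / 2
    hi <- depths + step / 2
    q <- (anti(pmin(hi, rangeCm)) - anti(pmin(lo, rangeCm))) / step
    q[q < 0] <- 0
    ## Gaussian range straggling (plus any beamline range spread)
    sigma <- sqrt((0.012 * rangeCm^0.935)^2 + rangeSpread^2)
    half <- max(1L, ceiling(4 * sigma / step))
    kern <- dnorm((-half:half) * step, sd = sigma)
    kern <- kern / sum(kern)
    qpad <- c(rep(q[1], half), q, rep(0, half))
    n <- length(q)
    dose <- numeric(n)
    for (i in seq_along(kern))
        dose <- dose + kern[i] * qpad[i:(i + n - 1)]
    new("DepthDoseCurve", depths = depths, dose = dose / max(dose),
        nominalRange = rangeCm)
}

#' Depth of the distal / proximal 90% isodose level
#'
#' `findDistal90()` returns the deepest depth at which the dose falls through
#' 90% of the curve maximum; `findProximal90()` the shallowest depth at which
#' it rises through that level (the first grid depth if the curve starts
#' above the level).  Crossings are linearly interpolated between samples.
#' The SOBP distal range and width are defined on these levels.
#'
#' @param curve a [DepthDoseCurve] with positive maximum.
#' @return numeric, depth in cm WEPL.
#' @examples
#' d <- seq(0, 12, by = 0.05)
#' rect <- new("DepthDoseCurve", depths = d,
#'             dose = as.numeric(d >= 3 & d <= 9), nominalRange = NA_real_)
#' findDistal90(rect)    # ~9
#' findProximal90(rect)  # ~3
#' @export
findDistal90 <- function(curve) {
    stopifnot(is(curve, "DepthDoseCurve"))
    dose <- curve@dose; depths <- curve@depths
    if (max(dose) <= 0) stop("curve maximum must be > 0", call. = FALSE)
    level <- 0.9 * max(dose)
    idx <- which(dose >= level)
    if (!length(idx)) stop("dose never reaches the 90% level", call. = FALSE)
    i <- max(idx)
    if (i == length(dose)) return(depths[i])
    depths[i] + (dose[i] - level) / (dose[i] - dose[i + 1]) *
        (depths[i + 1] - depths[i])
}

#' @rdname findDistal90
#' @export
findProximal90 <- function(curve) {
    stopifnot(is(curve, "DepthDoseCurve"))
    dose <- curve@dose; depths <- curve@depths
    if (max(dose) <= 0) stop("curve maximum must be > 0", call. = FALSE)
    level <- 0.9 * max(dose)
    idx <- which(dose >= level)
    if (!length(idx)) stop("dose never reaches the 90% level", call. = FALSE)
    i <- min(idx)
    if (i == 1L) return(depths[1L])
    depths[i - 1] + (level - dose[i - 1]) / (dose[i] - dose[i - 1]) *
        (depths[i] - depths[i - 1])
}

## 80%-20% distal falloff width of a depth-dose curve (cm)
distalFalloff8020 <- function(curve) {
    dose <- curve@dose; depths <- curve@depths
    lvl <- function(f) {
        level <- f * max(dose)
        i <- max(which(dose >= level))
        if (i == length(dose)) return(depths[i])
        depths[i] + (dose[i] - level) / (dose[i] - dose[i + 1]) *
            (depths[i + 1] - depths[i])
    }
    lvl(0.2) - lvl(0.8)
}

#' Synthesize a spread-out Bragg peak (SOBP)
#'
#' Superposes pristine Bragg peaks with nonnegative weights (solved by
#' nonnegative least squares against a flat unit target) so that the summed
#' curve has a flat high-dose plateau and, on the 90% isodose definitions,
#' distal range `R` and width `M`.  Pristine peaks are spaced at 0.4 times
#' the 80%-20% distal falloff of the deepest peak; the nominal deepest range
#' and the plateau start are calibrated iteratively so that the measured
#' distal 90% depth equals `R` and the proximal 90% depth equals `R - M`
#' (each within a small fraction of the depth step).  The returned curve is
#' normalized to a plateau level of 1.
#'
#' @param R numeric, distal 90% range in cm WEPL.
#' @param M numeric, 90%-to-90% modulation width in cm WEPL (0 < M <= R).
#' @param step numeric, depth grid step in cm (default 0.05).
#' @param flatTol numeric, required plateau flatness (default 0.02: the
#'   plateau stays within +/- 2% of its mean); an `optimization-failure`
#'   error reporting the achieved flatness is thrown when the target cannot
#'   be met.
#' @param rangeSpread numeric, beamline range spread in cm passed to
#'   [pristineBragg()] (default 0).
#' @return An [SOBPCurve].
#' @examples
#' s <- buildSOBP(10, 5)
#' c(findDistal90(s), findDistal90(s) - findProximal90(s))  # ~10, ~5
#' @export
buildSOBP <- function(R, M, step = DEPTH_STEP, flatTol = 0.02,
                      rangeSpread = 0) {
    if (length(R) != 1L || length(M) != 1L || !is.finite(R) || !is.finite(M))
        stop("'R' and 'M' must be single numbers", call. = FALSE)
    if (M <= 0 || M > R) stop("need 0 < M <= R", call. = FALSE)
    maxDepth <- R + 3
    depths <- seq(0, maxDepth, by = step)

    ref <- pristineBragg(R, maxDepth, step, rangeSpread)
    falloff <- distalFalloff8020(ref)
    spacingCm <- max(step, 0.4 * falloff)

    distNom <- R            # nominal range of the deepest pristine peak
    proxNom <- max(R - M, 2 * step)  # nominal plateau start

    buildOnce <- function(distNom, proxNom) {
        proxNom <- min(max(proxNom, 2 * step), distNom - step)
        ranges <- rev(seq(distNom, proxNom, by = -spacingCm))
        if (length(ranges) < 2L)
            ranges <- c(max(distNom - spacingCm, step), distNom)
        A <- vapply(ranges, function(r)
            pristineBragg(r, maxDepth, step, rangeSpread)@dose,
            numeric(length(depths)))
        ## flat target ends one falloff width short of the deepest peak:
        ## forcing dose 1 into the distal falloff region makes the least
        ## squares solution overshoot ("horn") just before the falloff
        fitIdx <- which(depths >= proxNom & depths <= distNom - 0.8 * falloff)
        w <- pracma::lsqnonneg(A[fitIdx, , drop = FALSE],
                               rep(1, length(fitIdx)))$x
        dose <- as.vector(A %*% w)
        list(ranges = ranges, weights = w, dose = dose)
    }

    best <- NULL
    bestErr <- Inf
    evalFit <- function(fit, proxNom) {
        cur <- new("DepthDoseCurve", depths = depths, dose = fit$dose,
                   nominalRange = R)
        d90 <- findDistal90(cur)
        p90 <- findProximal90(cur)
        errD <- d90 - R
        ## at near-full modulation the entrance sits at/above the 90% level
        ## and the proximal 90% depth degenerates to the surface
        errP <- if (p90 <= step) 0 else p90 - (R - M)
        list(errD = errD, errP = errP, err = max(abs(errD), abs(errP)))
    }
    for (it in 1:8) {
        fit <- buildOnce(distNom, proxNom)
        e <- evalFit(fit, proxNom)
        if (e$err < bestErr) {
            bestErr <- e$err
            best <- c(fit, list(proxNom = proxNom, distNom = distNom))
        }
        if (e$err < step / 3) break
        distNom <- distNom - 0.8 * e$errD
        proxNom <- proxNom - 0.8 * e$errP
    }
    ## the discrete peak set makes the proximal response piecewise-smooth in
    ## the plateau start; a short line search around the best iterate
    ## resolves the residual quantization error
    if (bestErr > step / 3) {
        ctrP <- best$proxNom
        ctrD <- best$distNom
        for (dp in seq(-spacingCm, spacingCm, length.out = 9)) {
            fit <- buildOnce(ctrD, ctrP + dp)
            e <- evalFit(fit, ctrP + dp)
            if (e$err < bestErr) {
                bestErr <- e$err
                best <- c(fit, list(proxNom = ctrP + dp, distNom = ctrD))
            }
        }
    }
    dose <- best$dose
    ## Plateau flatness is measured on the designed flat region, inset by the
    ## shoulder widths: the rise from the 90% level to the plateau (proximal)
    ## and the falloff back to it (distal) each span a few 80-20 falloff
    ## widths and belong to the 90-90 definitions of R and M, not to plateau
    ## ripple.  At near-full modulation the proximal 90% level sits in the
    ## entrance ramp below the designed plateau.
    cur <- new("DepthDoseCurve", depths = depths, dose = dose,
               nominalRange = R)
    d90 <- findDistal90(cur)
    inset <- max(spacingCm, 3 * falloff)
    plat <- which(depths >= best$proxNom + inset & depths <= d90 - inset)
    if (length(plat) < 2L)
        plat <- which(depths >= d90 - M / 2 & depths <= d90 - spacingCm)
    level <- mean(dose[plat])
    ripple <- max(abs(dose[plat] - level)) / level
    if (ripple > flatTol)
        stop(sprintf(
            "optimization failure: SOBP plateau flatness %.3f exceeds tolerance %.3f",
            ripple, flatTol), call. = FALSE)
    new("SOBPCurve", depths = depths, dose = dose / level,
        nominalRange = R, distalRange = R, modulation = M,
        peakRanges = fit$ranges, peakWeights = fit$weights / level)
}
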