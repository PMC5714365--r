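#' @include evaluation.R
NULL

#' Plot per-phase dose-index deltas of one or more plans
#'
#' For each report, draws the per-phase changes of D95%, D99% and D100%
#' against the 3D baseline, with the acceptability band shaded.
#'
#' @param reports a [PhaseReport] or list of them.
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plotPhaseDeltas <- function(reports, main = "Respiration-induced index changes") {
    if (is(reports, "PhaseReport")) reports <- list(reports)
    nr <- length(reports)
    old <- par(mfrow = c(nr, 1), mar = c(4, 4, 2, 1))
    on.exit(par(old))
    for (rep in reports) {
        tab <- rep@phaseTable
        ylim <- range(c(-rep@tolerance, rep@tolerance,
                        tab$dD95, tab$dD99, tab$dD100))
        plot(NA, xlim = range(tab$phase), ylim = ylim,
             xlab = "respiratory phase (%)",
             ylab = "index change (points)",
             main = sprintf("%s (%s plan)", main, rep@strategy))
        rect(min(tab$phase), -rep@tolerance, max(tab$phase), rep@tolerance,
             col = "grey90", border = NA)
        lines(tab$phase, tab$dD100, type = "b", pch = 16)
        lines(tab$phase, tab$dD99, type = "b", pch = 0)
        lines(tab$phase, tab$dD95, type = "b", pch = 2)
        abline(h = 0, lty = 3)
        legend("bottomleft", pch = c(16, 0, 2),
               legend = c("D100%", "D99%", "D95%"), bty = "n", cex = 0.8)
    }
    invisible(NULL)
}

#' Overlay cumulative DVH curves
#'
#' @param doses named list of [DoseVolume] objects (names used in the
#'   legend).
#' @param mask a [MaskVolume], the structure to histogram.
#' @param main plot title.
#' @return Invisibly, `NULL`.
#' @export
plotDVH <- function(doses, mask, main = "Dose-volume histogram") {
    stopifnot(length(doses) >= 1)
    levels <- seq(0, max(vapply(doses, function(d) max(d@values[mask@values]),
                                numeric(1))) + 1, by = 0.5)
    curves <- lapply(doses, function(d) dvh(d, mask, levels))
    plot(NA, xlim = range(levels), ylim = c(0, 1.02),
         xlab = "dose (% of prescription)", ylab = "fractional volume",
         main = main)
    for (i in seq_along(curves))
        lines(curves[[i]]$dose, curves[[i]]$volume, col = i, lwd = 2)
    if (!is.null(names(doses)))
        legend("bottomleft", legend = names(doses), col = seq_along(doses),
               lwd = 2, bty = "n", cex = 0.8)
    invisible(NULL)
}
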