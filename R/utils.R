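#' @include AllClasses.R
NULL

## Internal geometry helpers -------------------------------------------------

sameGeometry <- function(a, b, tol = 1e-6) {
    identical(dim(a@values), dim(b@values)) &&
        max(abs(a@spacing - b@spacing)) <= tol &&
        max(abs(a@origin - b@origin)) <= tol
}

stopIfGeometryMismatch <- function(a, b, what = "volumes") {
    if (!sameGeometry(a, b))
        stop("geometry error: ", what, " do not share grid geometry",
             call. = FALSE)
    invisible(TRUE)
}

## world coordinates of voxel centers along one axis (mm)
axisCoords <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

## Zero/FALSE-padded integer shift of an n-dimensional array.
shiftArray <- function(a, offset, fill = FALSE) {
    d <- dim(a)
    nd <- length(d)
    out <- array(fill, d)
    src <- dst <- vector("list", nd)
    for (ax in seq_len(nd)) {
        o <- offset[ax]
        if (abs(o) >= d[ax]) return(out)
        if (o >= 0) {
            dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o)
        } else {
            dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax]
        }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
}

shiftMatrix <- function(a, offset, fill = FALSE) {
    d <- dim(a)
    out <- matrix(fill, d[1], d[2])
    o1 <- offset[1]; o2 <- offset[2]
    if (abs(o1) >= d[1] || abs(o2) >= d[2]) return(out)
    r1 <- if (o1 >= 0) (1 + o1):d[1] else 1:(d[1] + o1)
    s1 <- if (o1 >= 0) 1:(d[1] - o1) else (1 - o1):d[1]
    r2 <- if (o2 >= 0) (1 + o2):d[2] else 1:(d[2] + o2)
    s2 <- if (o2 >= 0) 1:(d[2] - o2) else (1 - o2):d[2]
    out[r1, r2] <- a[s1, s2]
    out
}

## Integer offsets whose physical displacement lies within a Euclidean ball.
ballOffsets <- function(spacing, margin) {
    r <- floor(margin / spacing + 1e-9)
    g <- as.matrix(expand.grid(lapply(r, function(k) -k:k)))
    d2 <- g^2 %*% spacing^2
    g[d2 <= margin^2 + 1e-9, , drop = FALSE]
}

## Euclidean dilation of a logical array by a physical margin (mm):
## a voxel is set iff its center lies within `margin` of a set voxel center.
dilateBall <- function(mask, spacing, margin) {
    if (margin == 0) return(mask)
    offs <- ballOffsets(spacing, margin)
    out <- array(FALSE, dim(mask))
    if (length(dim(mask)) == 3L) {
        for (i in seq_len(nrow(offs)))
            out <- out | shiftArray(mask, offs[i, ])
    } else {
        for (i in seq_len(nrow(offs)))
            out <- out | shiftMatrix(mask, offs[i, ])
    }
    out
}

## Minimum over a Euclidean ball neighbourhood of values defined on `valid`
## pixels (2D).  Pixels with no valid neighbour inside the ball get Inf.
ballMin2D <- function(values, valid, spacing, margin) {
    v <- ifelse(valid, values, Inf)
    out <- matrix(Inf, nrow(v), ncol(v))
    offs <- ballOffsets(spacing, margin)
    for (i in seq_len(nrow(offs)))
        out <- pmin(out, shiftMatrix(v, offs[i, ], fill = Inf))
    out
}

## Separable 2D Gaussian blur (sigma in pixels per axis), zero-padded edges.
gaussianBlur2D <- function(m, sigmaPix) {
    blur1 <- function(x, s) {
        if (s <= 0) return(x)
        half <- max(1L, ceiling(3 * s))
        k <- dnorm(-half:half, sd = s)
        k <- k / sum(k)
        n <- nrow(x)
        pad <- rbind(matrix(0, half, ncol(x)), x, matrix(0, half, ncol(x)))
        out <- matrix(0, n, ncol(x))
        for (i in seq_along(k))
            out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
        out
    }
    t(blur1(t(blur1(m, sigmaPix[1])), sigmaPix[2]))
}
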