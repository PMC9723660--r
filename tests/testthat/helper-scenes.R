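# Shared fixtures, built in code.

# two-point unbuffered standard curve: (pH 7.4, R 0.45), (pH 5.0, R 1.59)
twoPointCurve <- function() {
    fitCalibration(data.frame(ph_true = c(7.4, 5.0),
                              ratio = c(0.45, 1.59)))
}

# the same line declared over the sensor's full linear range (pH 4.6-7.6),
# for scene-recovery tests whose fields span that range
sensorCurve <- function() {
    fitCalibration(data.frame(ph_true = c(7.6, 4.6),
                              ratio = -0.475 * c(7.6, 4.6) + 3.965))
}

# small scene for imaging round trips: ~35 cells on 200 x 100 um
smallScene <- function(nFrames = 1L, seed = 7L) {
    SceneConfig(fieldWidthUm = 200, fieldHeightUm = 100,
                nFrames = nFrames, seed = seed)
}

# a layout of well-separated cells on a grid (deterministic)
gridLayout <- function(config, pitchUm = 20) {
    nx <- floor(config@fieldWidthUm / pitchUm)
    ny <- floor(config@fieldHeightUm / pitchUm)
    g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
    new("CellLayout",
        cells = data.frame(cell_id = seq_len(nrow(g)),
                           x_um = (g$ix - 0.5) * pitchUm,
                           y_um = (g$iy - 0.5) * pitchUm),
        fieldWidthUm = config@fieldWidthUm,
        fieldHeightUm = config@fieldHeightUm)
}

# brute-force IDW oracle: scalar loops, no vectorization shared with the
# implementation
idwOracle <- function(x, y, z, xt, yt, power = 2, k = Inf) {
    out <- numeric(length(xt))
    for (q in seq_along(xt)) {
        d <- numeric(length(x))
        for (i in seq_along(x))
            d[i] <- sqrt((x[i] - xt[q])^2 + (y[i] - yt[q])^2)
        if (is.finite(k) && k < length(d)) {
            keep <- order(d)[seq_len(k)]
            dd <- d[keep]; zz <- z[keep]
        } else { dd <- d; zz <- z }
        if (any(dd < 1e-9)) out[q] <- mean(zz[dd < 1e-9])
        else {
            w <- dd^(-power)
            s <- 0; sw <- 0
            for (i in seq_along(w)) { s <- s + w[i] * zz[i]; sw <- sw + w[i] }
            out[q] <- s / sw
        }
    }
    out
}

# brute-force max |delta pH| within a window: all-pairs scan
gradientOracle <- function(values, resolutionUm, windowUm) {
    nr <- nrow(values); nc <- ncol(values)
    best <- 0
    for (a in seq_len(nr * nc)) for (b in seq_len(nr * nc)) {
        if (b <= a) next
        ia <- (a - 1) %% nr + 1; ja <- (a - 1) %/% nr + 1
        ib <- (b - 1) %% nr + 1; jb <- (b - 1) %/% nr + 1
        d <- resolutionUm * sqrt((ia - ib)^2 + (ja - jb)^2)
        if (d <= windowUm)
            best <- max(best, abs(values[ia, ja] - values[ib, jb]))
    }
    best
}

makeMap <- function(values, resolutionUm = 3, frame = 0L) {
    new("InterpolatedMap", values = values, originUm = c(0, 0),
        resolutionUm = resolutionUm, frame = as.integer(frame),
        nObservations = length(values))
}
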