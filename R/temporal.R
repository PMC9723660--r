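## Temporal summaries and gradient analytics: acidification trajectories,
## microscale gradient magnitude and stability, onset detection, and the
## zone-of-influence / diffusion-time arithmetic.

#' Per-frame pH summary statistics
#'
#' Arithmetic mean and sample sd of ok-flagged per-cell pH, per frame.
#' Frames with no usable cells report n = 0 and NA statistics.
#'
#' @param obs observation data.frame with ph filled
#' @param frames frames to summarize (default: all present)
#' @return data.frame frame, time_h, n_cells, mean_ph, sd_ph
#' @export
frameStats <- function(obs, frames = sort(unique(obs$frame))) {
    out <- lapply(frames, function(f) {
        o <- obs[obs$frame == f & obs$qc_flag == "ok" & !is.na(obs$ph), ]
        data.frame(frame = f,
                   time_h = if (nrow(o)) o$time_h[1] else NA_real_,
                   n_cells = nrow(o),
                   mean_ph = if (nrow(o)) mean(o$ph) else NA_real_,
                   sd_ph = if (nrow(o) > 1L) stats::sd(o$ph) else
                       if (nrow(o) == 1L) 0 else NA_real_)
    })
    do.call(rbind, out)
}

#' Maximum pH difference over a spatial window
#'
#' The largest |pH_a - pH_b| over all node pairs of the map whose centres
#' are at most \code{windowUm} apart — the magnitude of the steepest
#' microscale gradient at that length scale. Ties are broken by the first
#' pair in row-major order. Implemented by scanning all integer node
#' offsets within the window, so it is exact.
#'
#' @param map an \code{\linkS4class{InterpolatedMap}}
#' @param windowUm window length (um); must be >= the node spacing
#' @return list(max_delta_ph, window_um, location) where location is a
#'   data.frame of the two node positions (row, col, x_um, y_um, ph)
#' @export
gradientMetric <- function(map, windowUm) {
    stopifnot(is(map, "InterpolatedMap"))
    r <- map@resolutionUm
    if (windowUm < r)
        stop("windowUm must be at least the map resolution")
    v <- map@values
    nr <- nrow(v); nc <- ncol(v)
    kmax <- min(floor(windowUm / r), nr - 1L)
    best <- -Inf; bestA <- c(1L, 1L); bestB <- c(1L, 1L)
    for (di in 0:kmax) {
        jmax <- min(floor(sqrt(max(0, (windowUm / r)^2 - di^2))), nc - 1L)
        for (dj in (-jmax):jmax) {
            if (di == 0L && dj <= 0L) next  # each offset once
            i1 <- seq_len(nr - di)
            j1 <- if (dj >= 0) seq_len(nc - dj) else seq.int(1 - dj, nc)
            a <- v[i1, j1, drop = FALSE]
            b <- v[i1 + di, j1 + dj, drop = FALSE]
            dif <- abs(a - b)
            m <- max(dif)
            if (m > best + 1e-15) {
                best <- m
                w <- which(dif == m, arr.ind = TRUE)[1L, ]  # row-major tie
                bestA <- c(i1[w[1]], j1[w[2]])
                bestB <- bestA + c(di, dj)
            }
        }
    }
    loc <- data.frame(row = c(bestA[1], bestB[1]),
                      col = c(bestA[2], bestB[2]))
    loc$x_um <- map@originUm[1] + (loc$col - 0.5) * r
    loc$y_um <- map@originUm[2] + (loc$row - 0.5) * r
    loc$ph <- v[cbind(loc$row, loc$col)]
    list(max_delta_ph = if (is.finite(best)) best else 0,
         window_um = windowUm, location = loc)
}

## local gradient magnitude: max |delta pH| to the 8 neighbours divided by
## the centre distance
.localGradient <- function(v, r) {
    nr <- nrow(v); nc <- ncol(v)
    g <- matrix(0, nr, nc)
    for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
        di <- off[1]; dj <- off[2]
        dist <- r * sqrt(di^2 + dj^2)
        i1 <- seq_len(nr - di)
        j1 <- if (dj >= 0) seq_len(nc - dj) else seq.int(1 - dj, nc)
        d <- abs(v[i1, j1, drop = FALSE] -
                 v[i1 + di, j1 + dj, drop = FALSE]) / dist
        g[i1, j1] <- pmax(g[i1, j1], d)
        g[i1 + di, j1 + dj] <- pmax(g[i1 + di, j1 + dj], d)
    }
    g
}

#' Stability of gradient zones between consecutive maps
#'
#' Ranks nodes of each map by local gradient magnitude (largest
#' neighbour-to-neighbour |delta pH| per um over the 8-neighbourhood) and
#' returns the Jaccard index of the two top-fraction node sets. Identical
#' maps (or maps differing by a constant) give 1; independent random maps
#' give ~= f^2 / (2f - f^2) in expectation (0.053 for f = 0.1). A planted
#' static gradient is considered temporally stable when consecutive-frame
#' Jaccard stays >= 0.5.
#'
#' @param mapA,mapB two \code{\linkS4class{InterpolatedMap}}s on the same grid
#' @param topFraction fraction of nodes ranked as gradient zone
#'   (default 0.1)
#' @return Jaccard index in [0, 1]
#' @export
gradientStability <- function(mapA, mapB, topFraction = 0.1) {
    stopifnot(is(mapA, "InterpolatedMap"), is(mapB, "InterpolatedMap"))
    if (!identical(dim(mapA@values), dim(mapB@values)) ||
        mapA@resolutionUm != mapB@resolutionUm)
        stop("maps must share an identical grid")
    n <- length(mapA@values)
    m <- max(1L, floor(topFraction * n))
    topSet <- function(map) {
        g <- .localGradient(map@values, map@resolutionUm)
        rowMajor <- (row(g) - 1L) * ncol(g) + col(g)  # tie-break order
        ord <- order(-as.vector(g), as.vector(rowMajor))
        ord[seq_len(m)]
    }
    a <- topSet(mapA); b <- topSet(mapB)
    length(intersect(a, b)) / length(union(a, b))
}

#' Acidification onset against a control series
#'
#' First frame whose mean pH falls below the control baseline (mean of the
#' control's frame means) minus k times the sd of the control frame means;
#' NA if never. A simple exceedance rule standing in for per-frame
#' hypothesis testing.
#'
#' @param series frame summary of the treatment scene
#'   (\code{\link{frameStats}} output)
#' @param control frame summary of the fungus-free control scene
#' @param k exceedance multiplier (default 3)
#' @return the onset frame, or NA if the series never crosses
#' @export
onsetTime <- function(series, control, k = 3) {
    if (nrow(control) < 2L) stop("control series too short")
    base <- mean(control$mean_ph, na.rm = TRUE)
    sdc <- stats::sd(control$mean_ph, na.rm = TRUE)
    thr <- base - k * sdc
    hit <- which(!is.na(series$mean_ph) &
                 (if (k == 0) series$mean_ph < base
                  else series$mean_ph < thr))
    if (!length(hit)) NA_integer_ else series$frame[min(hit)]
}

#' Width of the hyphal zone of influence
#'
#' The acidification lead time multiplied by the hyphal tip extension
#' rate: 18 h x 100 um/h = 1800 um.
#'
#' @param leadTimeH hours by which acidification precedes hyphal arrival
#' @param extensionRateUmPerH hyphal tip extension rate (um/h)
#' @return zone width in micrometres
#' @examples
#' influenceZoneWidth(18, 100)  # 1800
#' @export
influenceZoneWidth <- function(leadTimeH, extensionRateUmPerH) {
    stopifnot(leadTimeH >= 0, extensionRateUmPerH >= 0)
    leadTimeH * extensionRateUmPerH
}

#' Characteristic diffusion time over a distance
#'
#' t = x^2 / (geometryFactor * D), the mean-squared-displacement time for
#' a species of diffusivity D to cover x. The default geometry factor 2 is
#' the 1-D convention <x^2> = 2 D t; it is exposed because published
#' figures vary in the convention used.
#'
#' @param distanceUm distance x (um, > 0)
#' @param dCm2PerS diffusion coefficient (cm^2/s); default the proton
#'   diffusivity 9.3e-5
#' @param geometryFactor 2 (1-D), 4 (2-D) or 6 (3-D)
#' @return time in seconds
#' @examples
#' diffusionTime(20)  # 0.0215 s for a proton over 20 um
#' @export
diffusionTime <- function(distanceUm, dCm2PerS = 9.3e-5,
                          geometryFactor = 2) {
    stopifnot(distanceUm > 0, dCm2PerS > 0, geometryFactor > 0)
    xCm <- distanceUm * 1e-4
    xCm^2 / (geometryFactor * dCm2PerS)
}

#' Write temporal-analysis artifacts
#'
#' Summary CSV (frame,time_h,n_cells,mean_ph,sd_ph), gradient CSV
#' (frame,max_delta_ph,window_um,jaccard_vs_prev) and a one-page JSON
#' report (onset frame, zone width, diffusion time).
#'
#' @param summary frame summary data.frame
#' @param gradients gradient data.frame
#' @param report named list for the JSON report
#' @param dir output directory
#' @return (invisibly) files written
#' @export
writeAnalysis <- function(summary, gradients = NULL, report = NULL, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(dir, "summary.csv")
    utils::write.csv(summary, files, row.names = FALSE)
    if (!is.null(gradients)) {
        f <- file.path(dir, "gradients.csv")
        utils::write.csv(gradients, f, row.names = FALSE)
        files <- c(files, f)
    }
    if (!is.null(report)) {
        f <- file.path(dir, "report.json")
        jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
        files <- c(files, f)
    }
    invisible(files)
}
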