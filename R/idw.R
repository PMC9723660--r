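## Inverse-distance-weighted interpolation of per-cell pH onto regular
## micrometre grids, with leave-one-out cross-validated selection of the
## finest trustworthy grid resolution.

.ZERO_DIST <- 1e-9

## Core predictor: observations (x, y, z) -> predictions at (xt, yt).
## Vectorized over targets in chunks to bound the distance-matrix size.
.idwCore <- function(x, y, z, xt, yt, power, k, chunk = 2048L) {
    n <- length(x)
    useAll <- is.infinite(k) || k >= n
    out <- numeric(length(xt))
    for (s in seq(1L, length(xt), by = chunk)) {
        e <- min(s + chunk - 1L, length(xt))
        ## n x m distances
        d <- sqrt(outer(x, xt[s:e], "-")^2 + outer(y, yt[s:e], "-")^2)
        if (!useAll) {
            ## keep the k nearest per target, drop the rest
            keepMask <- apply(d, 2L, function(col) {
                thr <- sort.int(col, partial = k)[k]
                col <= thr
            })
            d[!keepMask] <- Inf
        }
        w <- d^(-power)
        coincident <- d < .ZERO_DIST
        anyCo <- colSums(coincident) > 0L
        pred <- colSums(w * z) / colSums(w)
        if (any(anyCo)) {
            for (jj in which(anyCo))
                pred[jj] <- mean(z[coincident[, jj]])
        }
        out[s:e] <- pred
    }
    out
}

#' Inverse-distance-weighted prediction
#'
#' Predicts z at target locations as the weighted mean of the observations,
#' weights proportional to Euclidean distance^(-power) over the k nearest
#' observations (all observations if \code{k = Inf}). A target closer than
#' 1e-9 um to one or more observations returns the mean of those
#' coincident values exactly.
#'
#' @param x,y,z observation coordinates (um) and values
#' @param xt,yt target coordinates
#' @param params an \code{\link{IDWParams}}
#' @return predicted values at the targets
#' @examples
#' idwPredict(c(0, 3), c(0, 0), c(4, 8), 1, 0)  # 4.8
#' @export
idwPredict <- function(x, y, z, xt, yt, params = IDWParams()) {
    stopifnot(is(params, "IDWParams"))
    if (!length(x)) stop("no observations")
    stopifnot(length(x) == length(y), length(x) == length(z))
    .idwCore(x, y, z, xt, yt, params@power, params@k)
}

.okObs <- function(obs, frame = NULL) {
    o <- obs[obs$qc_flag == "ok" & !is.na(obs$ph), ]
    if (!is.null(frame)) o <- o[o$frame == frame, ]
    o
}

#' Interpolate one frame's observations onto a regular grid
#'
#' IDW prediction at every node centre of an r x r um grid spanning the
#' observations' bounding box (origin at the box's top-left corner, node
#' (i, j) centred at origin + (j - 0.5, i - 0.5) r).
#'
#' @param obs observation data.frame with ph filled (only ok-flagged rows
#'   are used); needs >= 2 such rows
#' @param resolutionUm grid resolution r (um)
#' @param params an \code{\link{IDWParams}}
#' @param frame frame to map (default: the single frame present)
#' @return an \code{\linkS4class{InterpolatedMap}}
#' @export
buildMap <- function(obs, resolutionUm, params = IDWParams(), frame = NULL) {
    if (is.null(frame)) {
        fr <- unique(obs$frame)
        if (length(fr) != 1L)
            stop("obs spans several frames; pass `frame`")
        frame <- fr
    }
    o <- .okObs(obs, frame)
    if (nrow(o) < 2L) stop("need >= 2 ok-flagged observations to map")
    r <- resolutionUm
    x0 <- min(o$x_um); y0 <- min(o$y_um)
    nc <- max(1L, ceiling((max(o$x_um) - x0) / r))
    nr <- max(1L, ceiling((max(o$y_um) - y0) / r))
    xt <- x0 + (rep(seq_len(nc), each = nr) - 0.5) * r
    yt <- y0 + (rep(seq_len(nr), times = nc) - 0.5) * r
    v <- idwPredict(o$x_um, o$y_um, o$ph, xt, yt, params)
    new("InterpolatedMap", values = matrix(v, nr, nc),
        originUm = c(x0, y0), resolutionUm = r, frame = as.integer(frame),
        nObservations = nrow(o))
}

#' Leave-one-out cross-validation of IDW at a grid resolution
#'
#' For each observation i, the pH is predicted at the centre of the r-grid
#' cell containing its position (grid anchored at the origin, cell centre
#' (floor(x/r) + 0.5) r), using all observations except i. This makes the
#' score genuinely resolution-dependent: coarser grids displace the
#' prediction point further from the cell. Reports
#' CV R^2 = 1 - SS_res / SS_tot and the mean absolute prediction error as
#' a percentage of the observed pH.
#'
#' @param obs observation data.frame (ok-flagged, ph filled); or a
#'   data.frame with x_um, y_um, ph columns. Needs >= 3 rows.
#' @param resolutionUm grid resolution r (um)
#' @param params an \code{\link{IDWParams}}
#' @return list(cv_r_squared, prediction_error_pct, n); R^2 is NA when the
#'   observed pH has zero variance
#' @export
looCv <- function(obs, resolutionUm, params = IDWParams()) {
    o <- if ("qc_flag" %in% names(obs)) .okObs(obs) else obs
    n <- nrow(o)
    if (n < 3L) stop("need >= 3 observations for cross-validation")
    r <- resolutionUm
    xt <- (floor(o$x_um / r) + 0.5) * r
    yt <- (floor(o$y_um / r) + 0.5) * r
    pred <- numeric(n)
    for (i in seq_len(n))
        pred[i] <- .idwCore(o$x_um[-i], o$y_um[-i], o$ph[-i],
                            xt[i], yt[i], params@power, params@k)
    ssTot <- sum((o$ph - mean(o$ph))^2)
    ssRes <- sum((o$ph - pred)^2)
    r2 <- if (ssTot < .Machine$double.eps) NA_real_ else 1 - ssRes / ssTot
    errPct <- 100 * mean(abs(o$ph - pred) / o$ph)
    list(cv_r_squared = r2, prediction_error_pct = errPct, n = n)
}

#' Cross-validate candidate resolutions and select the finest reliable one
#'
#' Runs \code{\link{looCv}} at each candidate resolution and selects the
#' smallest r with CV R^2 >= \code{r2Min} and prediction error <
#' \code{errMaxPct} (the accuracy regime within which interpolation is
#' trusted).
#'
#' @param obs observations (see \code{\link{looCv}})
#' @param resolutions candidate grid resolutions, um (default 1:5)
#' @param params an \code{\link{IDWParams}}
#' @param r2Min minimum CV R^2 (default 0.79)
#' @param errMaxPct maximum prediction error percent (default 4.5)
#' @return a \code{\linkS4class{CVReport}}
#' @export
crossValidateResolutions <- function(obs, resolutions = 1:5,
                                     params = IDWParams(), r2Min = 0.79,
                                     errMaxPct = 4.5) {
    rows <- lapply(resolutions, function(r) {
        cv <- looCv(obs, r, params)
        data.frame(resolution_um = r, cv_r_squared = cv$cv_r_squared,
                   prediction_error_pct = cv$prediction_error_pct,
                   n = cv$n)
    })
    tab <- do.call(rbind, rows)
    sel <- selectResolutionFromTable(tab, r2Min, errMaxPct)
    new("CVReport", table = tab, selectedResolution = sel,
        r2Min = r2Min, errMaxPct = errMaxPct)
}

#' Apply the resolution-selection rule to a CV table
#'
#' @param tab data.frame with resolution_um, cv_r_squared,
#'   prediction_error_pct
#' @param r2Min,errMaxPct thresholds
#' @return the smallest passing resolution, or NA (with a diagnostic
#'   message) if none passes
#' @export
selectResolutionFromTable <- function(tab, r2Min = 0.79, errMaxPct = 4.5) {
    pass <- !is.na(tab$cv_r_squared) & tab$cv_r_squared >= r2Min &
        tab$prediction_error_pct < errMaxPct
    if (!any(pass)) {
        message(sprintf(
            "no resolution meets CV R^2 >= %g and error < %g%% (best R^2 %.3f)",
            r2Min, errMaxPct, suppressWarnings(max(tab$cv_r_squared,
                                                   na.rm = TRUE))))
        return(NA_real_)
    }
    min(tab$resolution_um[pass])
}

## ---- map I/O ------------------------------------------------------------

#' Write an interpolated map (CSV matrix + JSON sidecar, optional PNG)
#'
#' The CSV holds the node matrix; the sidecar records origin, resolution,
#' frame and n. \code{writeMapPng} renders a heatmap with the package's
#' fixed colormap (blue = alkaline to red = acidic) and explicit colour
#' limits.
#'
#' @param map an \code{\linkS4class{InterpolatedMap}}
#' @param path output CSV path
#' @return (invisibly) the path written
#' @export
writeMapCsv <- function(map, path) {
    utils::write.table(map@values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    side <- sub("\\.csv$", ".json", path)
    jsonlite::write_json(list(origin_um = map@originUm,
                              resolution_um = map@resolutionUm,
                              frame = map@frame,
                              n_observations = map@nObservations),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeMapCsv
#' @param zlim colour limits in pH units (default c(4, 7.5))
#' @export
writeMapPng <- function(map, path, zlim = c(4, 7.5)) {
    pal <- grDevices::hcl.colors(64, "RdYlBu")  # red = acidic end first
    v <- pmin(pmax(map@values, zlim[1]), zlim[2])
    grDevices::png(path, width = 640,
                   height = max(120, round(640 * nrow(v) / ncol(v))))
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(2, 2, 1, 1))
    ## image() draws x along rows; transpose and flip so y runs downward
    graphics::image(t(v)[, rev(seq_len(nrow(v))), drop = FALSE],
                    col = rev(pal), zlim = zlim, axes = FALSE,
                    main = sprintf("frame %d", map@frame))
    invisible(path)
}

#' @rdname writeMapCsv
#' @param report a \code{\linkS4class{CVReport}}
#' @export
writeCvReportCsv <- function(report, path) {
    utils::write.csv(report@table, path, row.names = FALSE)
    invisible(path)
}
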