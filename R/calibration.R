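## Linear ratio-vs-pH calibration: fit, inversion, precision propagation.

#' Fit the linear ratio-vs-pH standard curve
#'
#' Ordinary least squares of the per-level mean ratio on pH, each level
#' weighted equally (the calibration experiment reports a mean and sd over
#' hundreds of cells per level); set \code{pooled = TRUE} to regress all
#' individual cells instead. The fit is rejected if the slope is
#' non-negative: the 475/395 excitation ratio of the sensor must fall with
#' increasing pH.
#'
#' @param points data.frame with columns \code{ph_true} and \code{ratio}
#'   (one row per cell measurement), optionally \code{medium}
#' @param medium curve label; taken from \code{points$medium} when present
#' @param pooled regress per-cell ratios instead of level means
#' @return a \code{\linkS4class{CalibrationCurve}}
#' @examples
#' pts <- data.frame(ph_true = c(7.4, 5.0), ratio = c(0.45, 1.59))
#' fitCalibration(pts)   # slope -0.475, intercept 3.965
#' @export
fitCalibration <- function(points, medium = NULL, pooled = FALSE) {
    stopifnot(all(c("ph_true", "ratio") %in% names(points)))
    if (any(points$ratio <= 0)) stop("ratios must be > 0")
    levels <- sort(unique(points$ph_true))
    if (length(levels) < 2L)
        stop("calibration needs >= 2 distinct pH levels")
    if (is.null(medium))
        medium <- if ("medium" %in% names(points))
            as.character(points$medium[1]) else "unbuffered"
    meanR <- tapply(points$ratio, points$ph_true, mean)
    sdR <- tapply(points$ratio, points$ph_true, function(x)
        if (length(x) > 1L) stats::sd(x) else 0)
    if (pooled) {
        fit <- stats::lm(ratio ~ ph_true, data = points)
        yv <- points$ratio
    } else {
        df <- data.frame(ph = as.numeric(names(meanR)),
                         ratio = as.numeric(meanR))
        fit <- stats::lm(ratio ~ ph, data = df)
        yv <- df$ratio
    }
    ## direct R^2 (summary.lm warns on exact fits)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((yv - mean(yv))^2)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    if (slope >= 0)
        stop("non-responsive sensor: fitted slope >= 0")
    sdByLevel <- as.numeric(sdR)
    names(sdByLevel) <- names(sdR)
    new("CalibrationCurve", slope = slope, intercept = intercept,
        rSquared = r2, phRange = range(levels), sdByLevel = sdByLevel,
        medium = medium)
}

#' Convert ratios to pH with a calibration curve
#'
#' pH = (ratio - intercept) / slope. Values falling more than 0.2 pH units
#' outside the calibrated range are flagged
#' \code{out_of_calibration_range}; they are reported but excluded from
#' mapping by default (extrapolating a sensor past its calibrated range is
#' not defensible).
#'
#' @param curve a \code{\linkS4class{CalibrationCurve}}
#' @param ratio positive ratio(s)
#' @param graceMargin extension of the valid range before flagging
#'   (default 0.2 pH units)
#' @return data.frame with columns \code{ph} and \code{flag} ("ok" or
#'   "out_of_calibration_range")
#' @examples
#' crv <- fitCalibration(data.frame(ph_true = c(7.4, 5), ratio = c(0.45, 1.59)))
#' ratioToPh(crv, 1.22)  # pH 5.78
#' @export
ratioToPh <- function(curve, ratio, graceMargin = 0.2) {
    stopifnot(is(curve, "CalibrationCurve"))
    if (any(ratio <= 0)) stop("ratio must be > 0")
    ph <- (ratio - curve@intercept) / curve@slope
    lo <- curve@phRange[1] - graceMargin
    hi <- curve@phRange[2] + graceMargin
    flag <- ifelse(ph < lo | ph > hi, "out_of_calibration_range", "ok")
    data.frame(ph = ph, flag = flag)
}

#' Propagate ratio precision to pH precision
#'
#' For a linear curve, sd_pH = sd_ratio / |slope|.
#'
#' @param curve a \code{\linkS4class{CalibrationCurve}}
#' @param sdRatio standard deviation(s) of the ratio (>= 0)
#' @return standard deviation in pH units
#' @export
propagateSd <- function(curve, sdRatio) {
    stopifnot(is(curve, "CalibrationCurve"), all(sdRatio >= 0))
    sdRatio / abs(curve@slope)
}

#' Calibrate an observation table
#'
#' Fills the \code{ph} column of ok-flagged observations and downgrades
#' those outside the calibrated range (plus grace margin) to
#' \code{out_of_calibration_range}.
#'
#' @param obs observation data.frame (from \code{\link{quantifyStack}})
#' @param curve a \code{\linkS4class{CalibrationCurve}}
#' @param graceMargin see \code{\link{ratioToPh}}
#' @return \code{obs} with \code{ph} filled and \code{qc_flag} updated
#' @export
applyCalibration <- function(obs, curve, graceMargin = 0.2) {
    ok <- which(obs$qc_flag == "ok")
    if (length(ok)) {
        conv <- ratioToPh(curve, obs$ratio[ok], graceMargin)
        obs$ph[ok] <- conv$ph
        obs$qc_flag[ok][conv$flag != "ok"] <- "out_of_calibration_range"
    }
    obs
}

#' Calibration table I/O
#'
#' \code{readCalibrationCsv} reads a per-cell calibration table
#' (ph_true,medium,cell_id,ratio); \code{writeCurveJson} serializes a
#' fitted curve (slope, intercept, r_squared, ph_range, sd_by_level,
#' medium); \code{readCurveJson} restores it.
#'
#' @param path file path
#' @return see details
#' @export
readCalibrationCsv <- function(path) {
    df <- utils::read.csv(path)
    stopifnot(all(c("ph_true", "ratio") %in% names(df)))
    df
}

#' @rdname readCalibrationCsv
#' @param curve a \code{CalibrationCurve}
#' @export
writeCurveJson <- function(curve, path) {
    jsonlite::write_json(list(
        slope = curve@slope, intercept = curve@intercept,
        r_squared = curve@rSquared, ph_range = curve@phRange,
        sd_by_level = as.list(curve@sdByLevel), medium = curve@medium),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname readCalibrationCsv
#' @export
readCurveJson <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("CalibrationCurve", slope = x$slope, intercept = x$intercept,
        rSquared = x$r_squared, phRange = as.numeric(x$ph_range),
        sdByLevel = unlist(x$sd_by_level), medium = x$medium)
}
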