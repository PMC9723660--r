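#' @import methods
NULL

## Coordinate convention used throughout: origin at the top-left corner of
## the field, x increasing rightward, y increasing downward, all lengths in
## micrometres. Pixel (i, j) (1-based row/column) covers the half-open
## square [(j-1)*s, j*s) x [(i-1)*s, i*s) where s is the pixel size, so its
## centre sits at ((j-0.5)*s, (i-0.5)*s).

#' SceneConfig: geometry and sampling of a synthetic microcosm scene
#'
#' Holds the observation-field geometry and temporal sampling used by the
#' synthetic-scene generator: a 0.8 x 0.4 mm field imaged hourly for 48 h
#' with immobilized biosensor cells scattered at ~2200 cells/mm^2.
#'
#' @slot fieldWidthUm,fieldHeightUm field extent in micrometres
#' @slot pixelSizeUm rendered pixel size (um/px)
#' @slot nFrames number of frames (49 = hourly from 0 to 48 h)
#' @slot frameIntervalH time between frames, hours
#' @slot cellDensityPerMm2 areal cell density (cells per mm^2)
#' @slot cellRadiusUm biosensor cell radius, micrometres
#' @slot seed integer seed controlling all stochastic stages
#' @export
setClass("SceneConfig", representation(
    fieldWidthUm = "numeric", fieldHeightUm = "numeric",
    pixelSizeUm = "numeric", nFrames = "integer", frameIntervalH = "numeric",
    cellDensityPerMm2 = "numeric", cellRadiusUm = "numeric", seed = "integer"))

setValidity("SceneConfig", function(object) {
    msg <- character()
    if (object@fieldWidthUm <= 0 || object@fieldHeightUm <= 0)
        msg <- c(msg, "field dimensions must be > 0")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
    if (object@frameIntervalH <= 0) msg <- c(msg, "frameIntervalH must be > 0")
    if (object@cellDensityPerMm2 < 0) msg <- c(msg, "density must be >= 0")
    if (object@cellRadiusUm <= 0) msg <- c(msg, "cellRadiusUm must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a SceneConfig
#'
#' Defaults reproduce the study geometry: a 0.4 x 0.8 mm observation area,
#' ~2200 cells/mm^2 (~704 cells in expectation), hourly frames over 48 h,
#' ~2 um cells rendered at 0.5 um/px.
#'
#' @param fieldWidthUm,fieldHeightUm field extent (um)
#' @param pixelSizeUm pixel size (um)
#' @param nFrames number of frames
#' @param frameIntervalH frame interval (h)
#' @param cellDensityPerMm2 cell density (mm^-2)
#' @param cellRadiusUm cell radius (um)
#' @param seed integer seed
#' @return a \code{SceneConfig}
#' @examples
#' cfg <- SceneConfig(nFrames = 3L)
#' @export
SceneConfig <- function(fieldWidthUm = 800, fieldHeightUm = 400,
                        pixelSizeUm = 0.5, nFrames = 49L, frameIntervalH = 1,
                        cellDensityPerMm2 = 2200, cellRadiusUm = 1.0,
                        seed = 1L) {
    new("SceneConfig", fieldWidthUm = fieldWidthUm,
        fieldHeightUm = fieldHeightUm, pixelSizeUm = pixelSizeUm,
        nFrames = as.integer(nFrames), frameIntervalH = frameIntervalH,
        cellDensityPerMm2 = cellDensityPerMm2, cellRadiusUm = cellRadiusUm,
        seed = as.integer(seed))
}

#' Photophysics: ratiometric sensor response and camera model
#'
#' The sensor response is linear in pH: R(pH) = slope * pH + intercept with
#' slope < 0 (the 475/395 excitation ratio increases as pH drops). The two
#' channel amplitudes split a pH-independent total signal A so that
#' I475 = A R/(1+R) and I395 = A/(1+R); imaging noise is Poisson shot noise
#' on signal plus background followed by Gaussian read noise.
#'
#' @slot slope ratio change per pH unit (negative)
#' @slot intercept ratio at pH 0 (extrapolated)
#' @slot totalSignal A, pH-independent per-pixel cell amplitude (counts)
#' @slot background475,background395 per-channel background level (counts)
#' @slot readNoiseSd Gaussian read noise sd (counts)
#' @slot bleachPerFrame fractional loss of A per frame, in [0, 1)
#' @slot psfSigmaUm Gaussian point-spread sd (um)
#' @export
setClass("Photophysics", representation(
    slope = "numeric", intercept = "numeric", totalSignal = "numeric",
    background475 = "numeric", background395 = "numeric",
    readNoiseSd = "numeric", bleachPerFrame = "numeric",
    psfSigmaUm = "numeric"))

setValidity("Photophysics", function(object) {
    msg <- character()
    if (object@slope >= 0) msg <- c(msg, "slope must be negative")
    if (object@totalSignal <= 0) msg <- c(msg, "totalSignal must be > 0")
    if (object@background475 < 0 || object@background395 < 0)
        msg <- c(msg, "backgrounds must be >= 0")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (object@bleachPerFrame < 0 || object@bleachPerFrame >= 1)
        msg <- c(msg, "bleachPerFrame must be in [0, 1)")
    if (object@psfSigmaUm <= 0) msg <- c(msg, "psfSigmaUm must be > 0")
    if (length(msg)) msg else TRUE
})

#' Construct a Photophysics model
#'
#' Default slope/intercept are the two-point unbuffered standard curve
#' through (pH 7.4, R 0.45) and (pH 5.0, R 1.59): slope -0.475,
#' intercept 3.965. Signal and background defaults give a per-pixel SNR of
#' roughly 20-30 for a cell at neutral pH; absolute camera counts are free
#' parameters of the emulation.
#'
#' @param slope,intercept linear ratio-vs-pH response
#' @param totalSignal per-pixel cell amplitude A (counts)
#' @param background475,background395 background levels (counts)
#' @param readNoiseSd read noise sd (counts)
#' @param bleachPerFrame per-frame fractional bleaching of A
#' @param psfSigmaUm point-spread Gaussian sd (um)
#' @return a \code{Photophysics}
#' @export
Photophysics <- function(slope = -0.475, intercept = 3.965,
                         totalSignal = 1000, background475 = 100,
                         background395 = 100, readNoiseSd = 3,
                         bleachPerFrame = 0, psfSigmaUm = 0.5) {
    new("Photophysics", slope = slope, intercept = intercept,
        totalSignal = totalSignal, background475 = background475,
        background395 = background395, readNoiseSd = readNoiseSd,
        bleachPerFrame = bleachPerFrame, psfSigmaUm = psfSigmaUm)
}

#' GroundTruthField: the simulator's latent pH raster
#'
#' A time-indexed 2D raster of true pH values on a regular grid; the latent
#' truth against which pipeline recovery is scored.
#'
#' @slot values numeric array (frame, row, col) of pH values
#' @slot spacingUm node spacing in micrometres
#' @slot fieldKind one of uniform, ramp, gradient_patch, grf, hyphal_front
#' @slot params the generator parameters used
#' @export
setClass("GroundTruthField", representation(
    values = "array", spacingUm = "numeric", fieldKind = "character",
    params = "list"))

setValidity("GroundTruthField", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a (frame, row, col) array")
    if (any(object@values < 3 - 1e-9) || any(object@values > 9 + 1e-9))
        msg <- c(msg, "pH values must lie within [3, 9]")
    if (object@spacingUm <= 0) msg <- c(msg, "spacingUm must be > 0")
    if (length(msg)) msg else TRUE
})

#' CellLayout: immobilized cell positions
#'
#' @slot cells data.frame with columns cell_id, x_um, y_um
#' @slot fieldWidthUm,fieldHeightUm bounds the coordinates must respect
#' @export
setClass("CellLayout", representation(
    cells = "data.frame", fieldWidthUm = "numeric", fieldHeightUm = "numeric"))

setValidity("CellLayout", function(object) {
    msg <- character()
    need <- c("cell_id", "x_um", "y_um")
    if (!all(need %in% names(object@cells)))
        msg <- c(msg, "cells must have columns cell_id, x_um, y_um")
    else {
        if (anyDuplicated(object@cells$cell_id))
            msg <- c(msg, "cell_ids must be unique")
        if (nrow(object@cells) &&
            (any(object@cells$x_um < 0) ||
             any(object@cells$x_um >= object@fieldWidthUm) ||
             any(object@cells$y_um < 0) ||
             any(object@cells$y_um >= object@fieldHeightUm)))
            msg <- c(msg, "cell coordinates must lie inside the field")
    }
    if (length(msg)) msg else TRUE
})

#' ImagePair: one two-channel 16-bit frame
#'
#' Emission at 510 nm under 475 nm excitation (ch475) and 395 nm excitation
#' (ch395), as integer count matrices of identical shape.
#'
#' @slot ch475,ch395 count matrices (row = y, col = x)
#' @slot frame 0-based frame index
#' @slot pixelSizeUm pixel size (um)
#' @export
setClass("ImagePair", representation(
    ch475 = "matrix", ch395 = "matrix", frame = "integer",
    pixelSizeUm = "numeric"))

setValidity("ImagePair", function(object) {
    msg <- character()
    if (!identical(dim(object@ch475), dim(object@ch395)))
        msg <- c(msg, "channel shapes must match")
    if (min(object@ch475, object@ch395) < 0)
        msg <- c(msg, "counts must be >= 0")
    if (max(object@ch475, object@ch395) > 65535)
        msg <- c(msg, "counts must fit in 16 bits")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (length(msg)) msg else TRUE
})

#' CalibrationCurve: linear ratio-to-pH standard curve
#'
#' @slot slope,intercept R(pH) = slope * pH + intercept, slope < 0
#' @slot rSquared coefficient of determination of the fit
#' @slot phRange pH range spanned by the calibration levels
#' @slot sdByLevel named numeric: per-level sd of the ratio
#' @slot medium "buffered" or "unbuffered"
#' @export
setClass("CalibrationCurve", representation(
    slope = "numeric", intercept = "numeric", rSquared = "numeric",
    phRange = "numeric", sdByLevel = "numeric", medium = "character"))

setValidity("CalibrationCurve", function(object) {
    msg <- character()
    if (object@slope >= 0) msg <- c(msg, "slope must be negative")
    if (length(object@phRange) != 2L || object@phRange[1] >= object@phRange[2])
        msg <- c(msg, "phRange must be increasing length-2")
    if (!is.na(object@rSquared) &&
        (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9))
        msg <- c(msg, "rSquared must lie in [0, 1]")
    if (!object@medium %in% c("buffered", "unbuffered"))
        msg <- c(msg, "medium must be 'buffered' or 'unbuffered'")
    if (length(msg)) msg else TRUE
})

#' IDWParams: inverse-distance-weighting settings
#'
#' @slot power distance exponent p (> 0), default 2
#' @slot k neighbourhood size (k nearest observations); \code{Inf} uses all
#'   observations
#' @export
setClass("IDWParams", representation(power = "numeric", k = "numeric"))

setValidity("IDWParams", function(object) {
    msg <- character()
    if (object@power <= 0) msg <- c(msg, "power must be > 0")
    if (!is.infinite(object@k) && (object@k < 1 || object@k != round(object@k)))
        msg <- c(msg, "k must be a positive integer or Inf")
    if (length(msg)) msg else TRUE
})

#' Construct IDW parameters
#'
#' @param power distance exponent (default 2)
#' @param k number of nearest observations used per prediction; \code{Inf}
#'   for all observations. Default 25.
#' @return an \code{IDWParams}
#' @export
IDWParams <- function(power = 2, k = 25) new("IDWParams", power = power, k = k)

#' InterpolatedMap: pH on a regular r x r um grid for one frame
#'
#' @slot values pH matrix (row = y, col = x)
#' @slot originUm (x0, y0) of the grid's top-left corner
#' @slot resolutionUm node spacing r (um); node (i, j) centre at
#'   (x0 + (j - 0.5) r, y0 + (i - 0.5) r)
#' @slot frame frame index
#' @slot nObservations number of observations interpolated
#' @export
setClass("InterpolatedMap", representation(
    values = "matrix", originUm = "numeric", resolutionUm = "numeric",
    frame = "integer", nObservations = "integer"))

setValidity("InterpolatedMap", function(object) {
    msg <- character()
    if (length(object@originUm) != 2L) msg <- c(msg, "originUm must be (x0, y0)")
    if (object@resolutionUm <= 0) msg <- c(msg, "resolutionUm must be > 0")
    if (anyNA(object@values)) msg <- c(msg, "map must have no missing nodes")
    if (length(msg)) msg else TRUE
})

#' CVReport: leave-one-out accuracy per candidate resolution
#'
#' @slot table data.frame with columns resolution_um, cv_r_squared,
#'   prediction_error_pct, n
#' @slot selectedResolution finest resolution passing both thresholds
#'   (NA if none)
#' @slot r2Min,errMaxPct the thresholds applied
#' @export
setClass("CVReport", representation(
    table = "data.frame", selectedResolution = "numeric",
    r2Min = "numeric", errMaxPct = "numeric"))

setValidity("CVReport", function(object) {
    msg <- character()
    need <- c("resolution_um", "cv_r_squared", "prediction_error_pct", "n")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, "table missing required columns")
    else if (any(object@table$prediction_error_pct < 0, na.rm = TRUE))
        msg <- c(msg, "prediction_error_pct must be >= 0")
    if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SceneConfig", function(object) {
    cat(sprintf(
        "SceneConfig: %.0f x %.0f um field, %.2f um/px, %d frames @ %g h\n",
        object@fieldWidthUm, object@fieldHeightUm, object@pixelSizeUm,
        object@nFrames, object@frameIntervalH))
    cat(sprintf("  %g cells/mm^2, cell radius %g um, seed %d\n",
        object@cellDensityPerMm2, object@cellRadiusUm, object@seed))
})

setMethod("show", "Photophysics", function(object) {
    cat(sprintf("Photophysics: R(pH) = %.4g pH + %.4g; A = %g counts\n",
        object@slope, object@intercept, object@totalSignal))
    cat(sprintf("  bg (475/395) %g/%g, read noise %g, bleach %g/frame, PSF %g um\n",
        object@background475, object@background395, object@readNoiseSd,
        object@bleachPerFrame, object@psfSigmaUm))
})

setMethod("show", "GroundTruthField", function(object) {
    d <- dim(object@values)
    cat(sprintf(
        "GroundTruthField '%s': %d frame(s) of %d x %d nodes @ %g um\n",
        object@fieldKind, d[1], d[2], d[3], object@spacingUm))
    cat(sprintf("  pH range [%.3f, %.3f]\n",
        min(object@values), max(object@values)))
})

setMethod("show", "CellLayout", function(object) {
    cat(sprintf("CellLayout: %d cells in %g x %g um\n",
        nrow(object@cells), object@fieldWidthUm, object@fieldHeightUm))
})

setMethod("show", "ImagePair", function(object) {
    cat(sprintf(
        "ImagePair frame %d: %d x %d px @ %g um/px (ch475, ch395)\n",
        object@frame, nrow(object@ch475), ncol(object@ch475),
        object@pixelSizeUm))
})

setMethod("show", "CalibrationCurve", function(object) {
    cat(sprintf(
        "CalibrationCurve (%s): R = %.4g pH + %.4g, R^2 = %.4g, pH %g-%g\n",
        object@medium, object@slope, object@intercept, object@rSquared,
        object@phRange[1], object@phRange[2]))
})

setMethod("show", "InterpolatedMap", function(object) {
    cat(sprintf(
        "InterpolatedMap frame %d: %d x %d nodes @ %g um from (%g, %g), n = %d\n",
        object@frame, nrow(object@values), ncol(object@values),
        object@resolutionUm, object@originUm[1], object@originUm[2],
        object@nObservations))
    cat(sprintf("  pH range [%.3f, %.3f]\n",
        min(object@values), max(object@values)))
})

setMethod("show", "CVReport", function(object) {
    cat("CVReport (leave-one-out):\n")
    print(object@table, row.names = FALSE)
    if (is.na(object@selectedResolution))
        cat(sprintf("  no resolution meets R^2 >= %g and error < %g%%\n",
            object@r2Min, object@errMaxPct))
    else
        cat(sprintf("  selected: %g um (R^2 >= %g, error < %g%%)\n",
            object@selectedResolution, object@r2Min, object@errMaxPct))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for micropHmap objects
#'
#' \code{phValues} returns the pH raster of a \code{GroundTruthField}
#' (frame, row, col array) or an \code{InterpolatedMap} (matrix);
#' \code{spacingUm} / \code{resolutionUm} return node spacings;
#' \code{cellPositions} the layout's data.frame; \code{curveCoef} the
#' (slope, intercept) of a calibration curve; \code{cvTable} and
#' \code{selectedResolution} the cross-validation results.
#'
#' @param object a micropHmap S4 object
#' @return see details
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("phValues", function(object) standardGeneric("phValues"))
#' @rdname accessors
#' @export
setMethod("phValues", "GroundTruthField", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("phValues", "InterpolatedMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("spacingUm", function(object) standardGeneric("spacingUm"))
#' @rdname accessors
#' @export
setMethod("spacingUm", "GroundTruthField", function(object) object@spacingUm)

#' @rdname accessors
#' @export
setGeneric("resolutionUm", function(object) standardGeneric("resolutionUm"))
#' @rdname accessors
#' @export
setMethod("resolutionUm", "InterpolatedMap", function(object)
    object@resolutionUm)

#' @rdname accessors
#' @export
setGeneric("cellPositions", function(object) standardGeneric("cellPositions"))
#' @rdname accessors
#' @export
setMethod("cellPositions", "CellLayout", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("curveCoef", function(object) standardGeneric("curveCoef"))
#' @rdname accessors
#' @export
setMethod("curveCoef", "CalibrationCurve", function(object)
    c(slope = object@slope, intercept = object@intercept))

#' @rdname accessors
#' @export
setGeneric("cvTable", function(object) standardGeneric("cvTable"))
#' @rdname accessors
#' @export
setMethod("cvTable", "CVReport", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("selectedResolution", function(object)
    standardGeneric("selectedResolution"))
#' @rdname accessors
#' @export
setMethod("selectedResolution", "CVReport", function(object)
    object@selectedResolution)
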