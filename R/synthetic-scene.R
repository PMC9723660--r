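## Synthetic microcosm scenes: latent pH fields, Poisson cell layouts, and
## noisy two-channel renders. The generator is the source of known truth for
## every recovery test downstream.

.PH_MIN <- 3
.PH_MAX <- 9

.clipField <- function(v, warn = TRUE) {
    if (any(v < .PH_MIN) || any(v > .PH_MAX)) {
        if (warn) warning("field pH outside [3, 9]; clipping", call. = FALSE)
        v <- pmin(pmax(v, .PH_MIN), .PH_MAX)
    }
    v
}

.fieldGridDims <- function(config, spacingUm) {
    c(rows = max(1L, ceiling(config@fieldHeightUm / spacingUm)),
      cols = max(1L, ceiling(config@fieldWidthUm / spacingUm)))
}

#' Generate a ground-truth pH field
#'
#' Builds the latent pH landscape a synthetic scene renders and against
#' which recovery is scored. Available kinds:
#' \describe{
#'   \item{uniform}{constant pH; \code{params$ph}.}
#'   \item{ramp}{spatially constant, mean drifting linearly from
#'     \code{ph_start} at frame 0 to \code{ph_end} at the last frame —
#'     the whole-field acidification trajectory (6.9 to ~5.0 over 48 h).}
#'   \item{gradient_patch}{baseline pH minus sigmoidal acidic depressions of
#'     \code{amplitude} pH units around \code{anchors} (data.frame x_um,
#'     y_um), each a disk of radius \code{patch_radius_um}.
#'     \code{length_scale_um} is the separation over which the full
#'     plateau-to-plateau contrast is observed: the sigmoidal transition is
#'     concentrated in the central half of that distance, so two points
#'     \code{length_scale_um} apart straddling the edge see ~99.9\% of the
#'     amplitude. Static from \code{onset_frame} (default 0), baseline
#'     before. Emulates temporally stable microscale gradients (~1.4 units
#'     over ~20 um).}
#'   \item{grf}{stationary Gaussian random field with smoothing-kernel sd
#'     \code{correlation_length_um}, marginal sd \code{sd} and mean
#'     \code{mean}, clipped to [3, 9]; same realization at every frame when
#'     \code{static = TRUE} (default).}
#'   \item{hyphal_front}{an acidification front entering from the x = 0
#'     edge and travelling at \code{extension_rate_um_per_h}, with
#'     acidification leading the (virtual) hyphal tip by \code{lead_time_h}:
#'     the acidified edge sits at rate * (t + lead_time). Behind the edge pH
#'     relaxes from \code{ph_far} toward \code{ph_near} with exponential
#'     shoulder width \code{front_width_um} (default 50).}
#' }
#'
#' @param config a \code{\link{SceneConfig}}
#' @param kind field kind (see above)
#' @param params named list of kind-specific parameters
#' @param spacingUm node spacing of the truth raster (default 2 um)
#' @return a \code{\linkS4class{GroundTruthField}}
#' @examples
#' cfg <- SceneConfig(nFrames = 3L)
#' f <- generateField(cfg, "uniform", list(ph = 6.9))
#' @export
generateField <- function(config, kind, params = list(), spacingUm = 2) {
    stopifnot(is(config, "SceneConfig"))
    kinds <- c("uniform", "ramp", "gradient_patch", "grf", "hyphal_front")
    if (!kind %in% kinds)
        stop("unknown field kind '", kind, "'; must be one of ",
             paste(kinds, collapse = ", "))
    d <- .fieldGridDims(config, spacingUm)
    nf <- config@nFrames
    ## node centres
    xs <- (seq_len(d["cols"]) - 0.5) * spacingUm
    ys <- (seq_len(d["rows"]) - 0.5) * spacingUm
    vals <- array(NA_real_, dim = c(nf, d["rows"], d["cols"]))

    if (kind == "uniform") {
        stopifnot(!is.null(params$ph))
        vals[] <- params$ph
    } else if (kind == "ramp") {
        stopifnot(!is.null(params$ph_start), !is.null(params$ph_end))
        phs <- if (nf == 1L) params$ph_start else
            seq(params$ph_start, params$ph_end, length.out = nf)
        for (f in seq_len(nf)) vals[f, , ] <- phs[f]
    } else if (kind == "gradient_patch") {
        stopifnot(!is.null(params$baseline), !is.null(params$amplitude),
                  !is.null(params$length_scale_um), !is.null(params$anchors))
        a <- params$anchors
        rad <- if (is.null(params$patch_radius_um)) 50 else
            params$patch_radius_um
        onset <- if (is.null(params$onset_frame)) 0L else params$onset_frame
        L <- params$length_scale_um
        ## steepness 16/L: ~96% of the amplitude within L/2, so the full
        ## contrast is expressed between points L apart across the edge
        depth <- matrix(0, d["rows"], d["cols"])
        for (i in seq_len(nrow(a))) {
            dist <- sqrt(outer((ys - a$y_um[i])^2, (xs - a$x_um[i])^2, "+"))
            s <- params$amplitude / (1 + exp(-16 * (rad - dist) / L))
            depth <- pmax(depth, s)
        }
        patch <- params$baseline - depth
        for (f in seq_len(nf))
            vals[f, , ] <- if ((f - 1L) >= onset) patch else params$baseline
    } else if (kind == "grf") {
        stopifnot(!is.null(params$correlation_length_um), !is.null(params$sd),
                  !is.null(params$mean))
        static <- if (is.null(params$static)) TRUE else params$static
        seed <- if (is.null(params$seed)) config@seed else params$seed
        set.seed(seed)
        mkfield <- function() {
            w <- matrix(stats::rnorm(d["rows"] * d["cols"]),
                        d["rows"], d["cols"])
            g <- EBImage::gblur(w, sigma = params$correlation_length_um /
                                    spacingUm)
            (g - mean(g)) / stats::sd(as.vector(g)) * params$sd + params$mean
        }
        if (static) {
            f0 <- mkfield()
            for (f in seq_len(nf)) vals[f, , ] <- f0
        } else for (f in seq_len(nf)) vals[f, , ] <- mkfield()
    } else { # hyphal_front
        stopifnot(!is.null(params$extension_rate_um_per_h),
                  !is.null(params$lead_time_h))
        phFar <- if (is.null(params$ph_far)) 6.9 else params$ph_far
        phNear <- if (is.null(params$ph_near)) 5.0 else params$ph_near
        W <- if (is.null(params$front_width_um)) 50 else params$front_width_um
        amp <- phFar - phNear
        for (f in seq_len(nf)) {
            t <- (f - 1L) * config@frameIntervalH
            xEdge <- params$extension_rate_um_per_h *
                (t + params$lead_time_h)
            delta <- ifelse(xs < xEdge,
                            amp * (1 - exp(-(xEdge - xs) / W)), 0)
            vals[f, , ] <- matrix(phFar - delta, d["rows"], d["cols"],
                                  byrow = TRUE)
        }
    }
    vals[] <- .clipField(vals)
    new("GroundTruthField", values = vals, spacingUm = spacingUm,
        fieldKind = kind, params = params)
}

#' Sample a ground-truth field at scene coordinates
#'
#' Nearest-node lookup under the half-open pixel convention: position
#' (x, y) falls in node (floor(y/s)+1, floor(x/s)+1).
#'
#' @param field a \code{GroundTruthField}
#' @param frame 0-based frame index
#' @param x,y coordinates (um)
#' @return pH values at the queried positions
#' @export
sampleField <- function(field, frame, x, y) {
    stopifnot(is(field, "GroundTruthField"))
    d <- dim(field@values)
    if (frame < 0 || frame >= d[1]) stop("frame out of range")
    i <- pmin(pmax(floor(y / field@spacingUm) + 1, 1), d[2])
    j <- pmin(pmax(floor(x / field@spacingUm) + 1, 1), d[3])
    field@values[cbind(frame + 1L, i, j)]
}

#' Place cells by homogeneous Poisson sampling
#'
#' Cell count ~ Poisson(density x area); positions uniform over the field.
#' At the defaults (2200 cells/mm^2 on 0.32 mm^2) the expected count is
#' 704, matching the >700 cells tracked in the emulated experiment.
#'
#' @param config a \code{\link{SceneConfig}}
#' @param seed integer seed (defaults to \code{config@seed})
#' @return a \code{\linkS4class{CellLayout}}
#' @export
placeCells <- function(config, seed = config@seed) {
    stopifnot(is(config, "SceneConfig"))
    set.seed(seed)
    areaMm2 <- config@fieldWidthUm * config@fieldHeightUm / 1e6
    n <- stats::rpois(1, config@cellDensityPerMm2 * areaMm2)
    cells <- data.frame(
        cell_id = seq_len(n),
        x_um = stats::runif(n, 0, config@fieldWidthUm),
        y_um = stats::runif(n, 0, config@fieldHeightUm))
    new("CellLayout", cells = cells, fieldWidthUm = config@fieldWidthUm,
        fieldHeightUm = config@fieldHeightUm)
}

## Rasterize disks of per-cell amplitude onto a pixel grid. amp475/amp395
## are per-cell scalar amplitudes; overlapping disks add.
.rasterizeCells <- function(layout, ampByCell, config) {
    s <- config@pixelSizeUm
    nr <- ceiling(config@fieldHeightUm / s)
    nc <- ceiling(config@fieldWidthUm / s)
    img <- matrix(0, nr, nc)
    cells <- layout@cells
    r <- config@cellRadiusUm
    for (k in seq_len(nrow(cells))) {
        jc <- (cells$x_um[k]) / s
        ic <- (cells$y_um[k]) / s
        j0 <- max(1L, floor(jc - r / s)); j1 <- min(nc, ceiling(jc + r / s) + 1L)
        i0 <- max(1L, floor(ic - r / s)); i1 <- min(nr, ceiling(ic + r / s) + 1L)
        jj <- j0:j1; ii <- i0:i1
        ## pixel centres at (j - 0.5, i - 0.5) in pixel units
        inside <- outer((ii - 0.5 - ic)^2, (jj - 0.5 - jc)^2, "+") <= (r / s)^2
        img[ii, jj] <- img[ii, jj] + inside * ampByCell[k]
    }
    img
}

#' Render one synthetic two-channel frame
#'
#' Each cell is drawn as a disk of the configured radius whose noise-free
#' channel amplitudes split the total signal A according to the local true
#' pH: with R = slope * pH + intercept, I475 = A R/(1+R) and
#' I395 = A/(1+R), so the per-cell ratio is exactly R and total brightness
#' is pH-independent. The amplitude images are blurred by a Gaussian
#' point-spread, backgrounds are added, and (unless \code{noise = FALSE})
#' Poisson shot noise then Gaussian read noise are applied before clipping
#' to the 16-bit range. Bleaching scales A by (1 - bleach)^frame; the ratio
#' is invariant to it by construction.
#'
#' @param field a \code{GroundTruthField} covering the layout
#' @param layout a \code{CellLayout}
#' @param phys a \code{\link{Photophysics}}
#' @param config the \code{\link{SceneConfig}}
#' @param frame 0-based frame index
#' @param seed integer seed for the noise draws
#' @param noise apply the camera noise model? (default TRUE)
#' @return an \code{\linkS4class{ImagePair}}
#' @export
renderFrame <- function(field, layout, phys, config, frame = 0L,
                        seed = config@seed, noise = TRUE) {
    stopifnot(is(field, "GroundTruthField"), is(layout, "CellLayout"),
              is(phys, "Photophysics"), is(config, "SceneConfig"))
    fr <- field@values[frame + 1L, , ]
    rng <- range(fr)
    if (phys@slope * rng[2] + phys@intercept <= 0)
        stop("configuration error: R(pH) <= 0 within the field's pH range")
    cells <- layout@cells
    A <- phys@totalSignal * (1 - phys@bleachPerFrame)^frame
    if (nrow(cells)) {
        phCell <- sampleField(field, frame, cells$x_um, cells$y_um)
        R <- phys@slope * phCell + phys@intercept
        amp475 <- A * R / (1 + R)
        amp395 <- A / (1 + R)
    } else amp475 <- amp395 <- numeric(0)
    im475 <- .rasterizeCells(layout, amp475, config)
    im395 <- .rasterizeCells(layout, amp395, config)
    sigmaPx <- phys@psfSigmaUm / config@pixelSizeUm
    if (nrow(cells)) {
        im475 <- EBImage::gblur(im475, sigma = sigmaPx)
        im395 <- EBImage::gblur(im395, sigma = sigmaPx)
    }
    im475 <- pmax(im475, 0) + phys@background475
    im395 <- pmax(im395, 0) + phys@background395
    if (noise) {
        set.seed(seed)
        n <- length(im475)
        im475[] <- stats::rpois(n, im475) +
            stats::rnorm(n, 0, phys@readNoiseSd)
        im395[] <- stats::rpois(n, im395) +
            stats::rnorm(n, 0, phys@readNoiseSd)
    }
    im475[] <- pmin(pmax(round(im475), 0), 65535)
    im395[] <- pmin(pmax(round(im395), 0), 65535)
    new("ImagePair", ch475 = im475, ch395 = im395, frame = as.integer(frame),
        pixelSizeUm = config@pixelSizeUm)
}

#' Render a full synthetic scene
#'
#' Renders every frame of the field with per-frame derived seeds
#' (seed + frame), so a scene is reproducible as a whole and per frame.
#'
#' @inheritParams renderFrame
#' @return list of \code{ImagePair}, one per frame
#' @export
renderScene <- function(field, layout, phys, config, seed = config@seed,
                        noise = TRUE) {
    lapply(seq_len(config@nFrames) - 1L, function(f)
        renderFrame(field, layout, phys, config, frame = f,
                    seed = seed + f, noise = noise))
}

#' Simulate single-cell calibration measurements
#'
#' Renders isolated cells at each requested pH level through the full
#' imaging model and re-measures them with the quantification module,
#' yielding per-cell ratios as a calibration experiment would: the
#' round-trip includes segmentation, background correction and noise.
#' Default levels span pH 4.0-8.2 in 0.6-unit steps, the span of the
#' emulated calibration experiment; a calibration that stops at the lowest
#' pH the maps are expected to report would censor the acid tail through
#' the out-of-range exclusion policy.
#'
#' @param phys a \code{\link{Photophysics}}
#' @param levels pH levels to calibrate at
#' @param nCells cells per level
#' @param seed integer seed
#' @param noise apply camera noise (default TRUE)
#' @param medium label stored with the points
#' @return data.frame ph_true, medium, cell_id, ratio (one row per cell)
#' @export
simulateCalibration <- function(phys, levels = seq(4.0, 8.2, by = 0.6),
                                nCells = 50, seed = 1L, noise = TRUE,
                                medium = "unbuffered") {
    out <- list()
    for (li in seq_along(levels)) {
        ## small field with a grid of well-separated cells
        side <- ceiling(sqrt(nCells))
        pitch <- 10
        cfg <- SceneConfig(fieldWidthUm = side * pitch,
                           fieldHeightUm = side * pitch, nFrames = 1L,
                           seed = seed + li)
        xy <- expand.grid(ix = seq_len(side), iy = seq_len(side))[
            seq_len(nCells), ]
        layout <- new("CellLayout", cells = data.frame(
            cell_id = seq_len(nCells),
            x_um = (xy$ix - 0.5) * pitch, y_um = (xy$iy - 0.5) * pitch),
            fieldWidthUm = cfg@fieldWidthUm, fieldHeightUm = cfg@fieldHeightUm)
        fld <- generateField(cfg, "uniform", list(ph = levels[li]))
        pair <- renderFrame(fld, layout, phys, cfg, frame = 0L,
                            seed = seed + li, noise = noise)
        seg <- segmentCells(pair)
        obs <- measureCells(seg, pair, readNoiseSd = phys@readNoiseSd)
        ok <- obs[obs$qc_flag == "ok", ]
        if (nrow(ok))
            out[[li]] <- data.frame(ph_true = levels[li], medium = medium,
                                    cell_id = ok$cell_id, ratio = ok$ratio)
    }
    do.call(rbind, out)
}

## ---- scene I/O ----------------------------------------------------------

#' Write / read the synthetic-scene artifact set
#'
#' \code{writeScene} writes per-frame two-page 16-bit TIFFs
#' (frame_%03d.tif; page 1 = ch475, page 2 = ch395), the ground-truth field
#' as CSV (frame,row,col,ph) with a JSON sidecar (spacing, kind, params),
#' and the layout CSV (cell_id,x_um,y_um). \code{readImagePair} reads one
#' such TIFF back.
#'
#' @param pairs list of \code{ImagePair}
#' @param field the \code{GroundTruthField} (or NULL to skip)
#' @param layout the \code{CellLayout} (or NULL to skip)
#' @param dir output directory (created if needed)
#' @return (invisibly) the vector of files written
#' @export
writeScene <- function(pairs, field = NULL, layout = NULL, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (p in pairs) {
        fn <- file.path(dir, sprintf("frame_%03d.tif", p@frame))
        writeImagePair(p, fn)
        files <- c(files, fn)
    }
    if (!is.null(field)) {
        d <- dim(field@values)
        df <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]),
                          frame = seq_len(d[1]) - 1L)
        df$ph <- as.vector(aperm(field@values, c(2, 3, 1)))
        fn <- file.path(dir, "ground_truth.csv")
        utils::write.csv(df[, c("frame", "row", "col", "ph")], fn,
                         row.names = FALSE)
        sc <- file.path(dir, "ground_truth.json")
        jsonlite::write_json(list(spacing_um = field@spacingUm,
                                  field_kind = field@fieldKind,
                                  params = field@params),
                             sc, auto_unbox = TRUE, digits = NA)
        files <- c(files, fn, sc)
    }
    if (!is.null(layout)) {
        fn <- file.path(dir, "layout.csv")
        utils::write.csv(layout@cells, fn, row.names = FALSE)
        files <- c(files, fn)
    }
    invisible(files)
}

#' @rdname writeScene
#' @param pair an \code{ImagePair}
#' @param path TIFF file path
#' @export
writeImagePair <- function(pair, path) {
    tiff::writeTIFF(list(pair@ch475 / 65535, pair@ch395 / 65535), path,
                    bits.per.sample = 16L, compression = "none")
    ## pixel-size sidecar so foreign stacks carry their scale
    side <- sub("\\.tiff?$", ".json", path)
    jsonlite::write_json(list(pixel_size_um = pair@pixelSizeUm,
                              frame = pair@frame),
                         side, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeScene
#' @param path TIFF file path
#' @param pixelSizeUm pixel size; if NULL, read from the JSON sidecar
#' @param frame frame index; if NULL, from sidecar (else 0)
#' @export
readImagePair <- function(path, pixelSizeUm = NULL, frame = NULL) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) < 2L) stop("expected a two-page TIFF (ch475, ch395)")
    side <- sub("\\.tiff?$", ".json", path)
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side)
        if (is.null(pixelSizeUm)) pixelSizeUm <- meta$pixel_size_um
        if (is.null(frame)) frame <- meta$frame
    }
    if (is.null(pixelSizeUm))
        stop("pixelSizeUm not given and no sidecar found")
    if (is.null(frame)) frame <- 0L
    new("ImagePair", ch475 = round(pages[[1]] * 65535),
        ch395 = round(pages[[2]] * 65535),
        frame = as.integer(frame), pixelSizeUm = pixelSizeUm)
}
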