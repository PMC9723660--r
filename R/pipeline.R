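## Orchestration: simulate -> quantify -> calibrate -> map -> analyze as
## one reproducible, manifest-logged run.

#' Default run configuration
#'
#' A nested list mirroring the pipeline stages; any element can be
#' overridden via \code{modifyList} semantics in \code{\link{runPipeline}}
#' or a YAML file. Scene, photophysics and thresholds default to the study
#' conditions (0.4 x 0.8 mm, 2200 cells/mm^2, hourly frames over 48 h,
#' ramp 6.9 -> 5.0, CV thresholds R^2 >= 0.79 and error < 4.5%).
#'
#' @return named list of defaults
#' @export
defaultRunConfig <- function() {
    list(
        seed = 1L,
        scene = list(field_width_um = 800, field_height_um = 400,
                     pixel_size_um = 0.5, n_frames = 49, frame_interval_h = 1,
                     cell_density_per_mm2 = 2200, cell_radius_um = 1.0),
        ## a late-colonisation snapshot: static acidic patch with a 1.4-unit
        ## edge. The whole-field ramp (6.9 -> 5.0) is spatially flat, so it
        ## cannot support per-frame CV resolution selection; select it
        ## explicitly for trajectory studies.
        field = list(kind = "gradient_patch",
                     params = list(baseline = 5.8, amplitude = 1.4,
                                   length_scale_um = 20,
                                   patch_radius_um = 100,
                                   anchors = data.frame(x_um = 400,
                                                        y_um = 200))),
        photophysics = list(slope = -0.475, intercept = 3.965,
                            total_signal = 1000, background475 = 100,
                            background395 = 100, read_noise_sd = 3,
                            bleach_per_frame = 0, psf_sigma_um = 0.5),
        images_dir = NULL,        # set to skip simulation and read TIFFs
        segmentation = list(min_area_um2 = 1, max_area_um2 = 20),
        tracking = list(link_radius_um = 2, max_gap = 2),
        calibration = list(csv = NULL,          # path, or NULL = synthetic
                           levels = seq(4.0, 8.2, by = 0.6),
                           n_cells = 50, medium = "unbuffered"),
        idw = list(power = 2, k = 25),
        resolutions = c(1, 2, 3, 4, 5),
        cv = list(r2_min = 0.79, err_max_pct = 4.5, frame = NULL),
        analysis = list(gradient_window_um = 20, top_fraction = 0.1,
                        lead_time_h = 18, extension_rate_um_per_h = 100,
                        diffusion_distance_um = 20,
                        d_cm2_per_s = 9.3e-5, geometry_factor = 2),
        write_png = FALSE,
        map_frames = NULL)        # NULL = all frames; or integer vector
}

.deepMerge <- function(base, override) {
    for (nm in names(override)) {
        if (is.list(override[[nm]]) && is.list(base[[nm]]))
            base[[nm]] <- .deepMerge(base[[nm]], override[[nm]])
        else base[[nm]] <- override[[nm]]
    }
    base
}

#' Read a run configuration from YAML
#'
#' Values absent from the file keep their defaults.
#'
#' @param path YAML file
#' @return full configuration list
#' @export
readRunConfig <- function(path) {
    .deepMerge(defaultRunConfig(), yaml::read_yaml(path))
}

.sceneFromConfig <- function(cfg) {
    SceneConfig(fieldWidthUm = cfg$scene$field_width_um,
                fieldHeightUm = cfg$scene$field_height_um,
                pixelSizeUm = cfg$scene$pixel_size_um,
                nFrames = cfg$scene$n_frames,
                frameIntervalH = cfg$scene$frame_interval_h,
                cellDensityPerMm2 = cfg$scene$cell_density_per_mm2,
                cellRadiusUm = cfg$scene$cell_radius_um,
                seed = cfg$seed)
}

.physFromConfig <- function(cfg) {
    Photophysics(slope = cfg$photophysics$slope,
                 intercept = cfg$photophysics$intercept,
                 totalSignal = cfg$photophysics$total_signal,
                 background475 = cfg$photophysics$background475,
                 background395 = cfg$photophysics$background395,
                 readNoiseSd = cfg$photophysics$read_noise_sd,
                 bleachPerFrame = cfg$photophysics$bleach_per_frame,
                 psfSigmaUm = cfg$photophysics$psf_sigma_um)
}

#' Run the full mapping pipeline
#'
#' Executes simulate (skipped when \code{config$images_dir} points at an
#' existing TIFF stack), quantify, calibrate, map (cross-validated
#' resolution selection, then per-frame maps at the selected resolution)
#' and analyze, writing every artifact plus a manifest with config hash,
#' seed and per-file checksums. Deterministic given (config, seed). If no
#' candidate resolution passes cross-validation the run stops with a
#' diagnostic and no heatmaps, preserving earlier artifacts.
#'
#' @param config configuration list (see \code{\link{defaultRunConfig}});
#'   partial lists are merged over the defaults
#' @param outDir output directory
#' @param seed overrides \code{config$seed} when given
#' @param quiet suppress progress messages
#' @return (invisibly) list with observations, curve, cvReport, maps,
#'   summary, gradients, report, manifest
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL,
                        quiet = FALSE) {
    cfg <- .deepMerge(defaultRunConfig(), config)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    say <- function(...) if (!quiet) message(sprintf(...))
    manifest <- list(seed = cfg$seed, stages = list(), warnings = list())
    cfgPath <- file.path(outDir, "config.yaml")
    yaml::write_yaml(cfg, cfgPath)
    manifest$config_md5 <- unname(tools::md5sum(cfgPath))

    scene <- .sceneFromConfig(cfg)
    phys <- .physFromConfig(cfg)

    ## -- simulate ---------------------------------------------------------
    field <- NULL
    if (is.null(cfg$images_dir)) {
        say("simulate: %d frame(s), %s field", scene@nFrames,
            cfg$field$kind)
        field <- generateField(scene, cfg$field$kind, cfg$field$params)
        layout <- placeCells(scene)
        pairs <- renderScene(field, layout, phys, scene)
        imgDir <- file.path(outDir, "images")
        writeScene(pairs, field, layout, imgDir)
        manifest$stages$simulate <- list(n_frames = length(pairs),
                                         n_cells = nrow(layout@cells))
    } else {
        tifs <- sort(list.files(cfg$images_dir, pattern = "\\.tiff?$",
                                full.names = TRUE))
        if (!length(tifs)) stop("no TIFF frames in ", cfg$images_dir)
        say("reading %d frame(s) from %s", length(tifs), cfg$images_dir)
        pairs <- lapply(tifs, readImagePair,
                        pixelSizeUm = cfg$scene$pixel_size_um)
        manifest$stages$simulate <- list(skipped = TRUE,
                                         n_frames = length(pairs))
    }

    ## -- quantify ---------------------------------------------------------
    say("quantify: segmenting %d frame(s)", length(pairs))
    obs <- quantifyStack(pairs, frameIntervalH = cfg$scene$frame_interval_h,
                         readNoiseSd = cfg$photophysics$read_noise_sd,
                         minAreaUm2 = cfg$segmentation$min_area_um2,
                         maxAreaUm2 = cfg$segmentation$max_area_um2)
    obs <- linkTracks(obs, linkRadiusUm = cfg$tracking$link_radius_um,
                      maxGap = cfg$tracking$max_gap)
    manifest$stages$quantify <- list(
        n_observations = nrow(obs), n_tracks = length(unique(obs$track_id)),
        qc = as.list(table(obs$qc_flag)))

    ## -- calibrate --------------------------------------------------------
    if (!is.null(cfg$calibration$csv)) {
        pts <- readCalibrationCsv(cfg$calibration$csv)
    } else {
        say("calibrate: simulating %d cells x %d levels",
            cfg$calibration$n_cells, length(cfg$calibration$levels))
        pts <- simulateCalibration(phys, levels = cfg$calibration$levels,
                                   nCells = cfg$calibration$n_cells,
                                   seed = cfg$seed + 1000L,
                                   medium = cfg$calibration$medium)
    }
    curve <- fitCalibration(pts, medium = cfg$calibration$medium)
    writeCurveJson(curve, file.path(outDir, "calibration_curve.json"))
    obs <- applyCalibration(obs, curve)
    writeObservations(obs, file.path(outDir, "observations.csv"))
    manifest$stages$calibrate <- list(slope = curve@slope,
                                      intercept = curve@intercept,
                                      r_squared = curve@rSquared)

    ## -- map --------------------------------------------------------------
    idw <- IDWParams(power = cfg$idw$power,
                     k = if (is.null(cfg$idw$k) ||
                             identical(cfg$idw$k, "all")) Inf else cfg$idw$k)
    cvFrame <- if (is.null(cfg$cv$frame)) max(obs$frame) else cfg$cv$frame
    cvObs <- obs[obs$frame == cvFrame, ]
    say("map: cross-validating resolutions {%s} on frame %d",
        paste(cfg$resolutions, collapse = ","), cvFrame)
    cvRep <- crossValidateResolutions(cvObs, cfg$resolutions, idw,
                                      r2Min = cfg$cv$r2_min,
                                      errMaxPct = cfg$cv$err_max_pct)
    writeCvReportCsv(cvRep, file.path(outDir, "cv_report.csv"))
    manifest$stages$map <- list(cv_frame = cvFrame,
                                selected_resolution =
                                    cvRep@selectedResolution)
    if (is.na(cvRep@selectedResolution)) {
        manifest$failed_stage <- "map"
        .writeManifest(manifest, outDir)
        stop("no resolution passed cross-validation; see cv_report.csv")
    }
    rSel <- cvRep@selectedResolution
    mapFrames <- if (is.null(cfg$map_frames)) sort(unique(obs$frame)) else
        cfg$map_frames
    mapDir <- file.path(outDir, "maps")
    dir.create(mapDir, showWarnings = FALSE)
    maps <- list()
    for (f in mapFrames) {
        m <- buildMap(obs, rSel, idw, frame = f)
        maps[[as.character(f)]] <- m
        writeMapCsv(m, file.path(mapDir, sprintf("map_%03d.csv", f)))
        if (isTRUE(cfg$write_png))
            writeMapPng(m, file.path(mapDir, sprintf("map_%03d.png", f)))
    }

    ## -- analyze ----------------------------------------------------------
    say("analyze: %d frame(s)", length(mapFrames))
    summary <- frameStats(obs)
    win <- cfg$analysis$gradient_window_um
    grads <- lapply(seq_along(maps), function(i) {
        g <- gradientMetric(maps[[i]], win)
        jac <- if (i > 1L &&
                   identical(dim(maps[[i]]@values),
                             dim(maps[[i - 1L]]@values)))
            gradientStability(maps[[i - 1L]], maps[[i]],
                              cfg$analysis$top_fraction) else NA_real_
        data.frame(frame = maps[[i]]@frame, max_delta_ph = g$max_delta_ph,
                   window_um = win, jaccard_vs_prev = jac)
    })
    grads <- do.call(rbind, grads)
    report <- list(
        seed = cfg$seed,
        selected_resolution_um = rSel,
        final_mean_ph = summary$mean_ph[nrow(summary)],
        max_gradient_ph = max(grads$max_delta_ph),
        influence_zone_um = influenceZoneWidth(
            cfg$analysis$lead_time_h, cfg$analysis$extension_rate_um_per_h),
        diffusion_time_s = diffusionTime(
            cfg$analysis$diffusion_distance_um, cfg$analysis$d_cm2_per_s,
            cfg$analysis$geometry_factor))
    writeAnalysis(summary, grads, report, outDir)
    manifest$stages$analyze <- list(final_mean_ph = report$final_mean_ph,
                                    max_gradient_ph = report$max_gradient_ph)
    .writeManifest(manifest, outDir)
    invisible(list(observations = obs, curve = curve, cvReport = cvRep,
                   maps = maps, summary = summary, gradients = grads,
                   report = report, manifest = manifest))
}

.writeManifest <- function(manifest, outDir) {
    files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    sums <- tools::md5sum(files)
    manifest$files <- lapply(seq_along(sums), function(i)
        list(path = sub(paste0("^", outDir, "/?"), "", files[i]),
             md5 = unname(sums[i])))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(manifest)
}

#' Verify a run directory against its manifest
#'
#' @param outDir a directory written by \code{\link{runPipeline}}
#' @return TRUE if every listed file matches its checksum
#' @export
verifyManifest <- function(outDir) {
    man <- jsonlite::read_json(file.path(outDir, "manifest.json"))
    ok <- vapply(man$files, function(f) {
        p <- file.path(outDir, f$path)
        file.exists(p) && unname(tools::md5sum(p)) == f$md5
    }, logical(1))
    all(ok)
}
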