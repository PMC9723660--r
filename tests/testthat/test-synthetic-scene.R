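test_that("uniform and ramp fields hit their endpoints", {
    cfg <- SceneConfig(nFrames = 49L)
    fu <- generateField(cfg, "uniform", list(ph = 6.9))
    expect_true(all(phValues(fu) == 6.9))

    fr <- generateField(cfg, "ramp", list(ph_start = 6.9, ph_end = 5.0))
    means <- apply(phValues(fr), 1, mean)
    expect_equal(means[1], 6.9)
    expect_equal(means[49], 5.0)
    # linear in between: second differences vanish
    expect_lt(max(abs(diff(diff(means)))), 1e-12)
})

test_that("unknown field kind and out-of-range pH are handled", {
    cfg <- SceneConfig(nFrames = 1L)
    expect_error(generateField(cfg, "vortex", list()), "unknown field kind")
    expect_warning(
        f <- generateField(cfg, "uniform", list(ph = 2.0)),
        "clipping")
    expect_true(all(phValues(f) == 3))
})

test_that("hyphal front's acidified edge advances at rate * (t + lead)", {
    # small-scale instance: rate 10 um/h, lead 2 h -> edge at 10 (t + 2)
    cfg <- SceneConfig(fieldWidthUm = 100, fieldHeightUm = 20,
                       nFrames = 4L)
    f <- generateField(cfg, "hyphal_front",
                       list(extension_rate_um_per_h = 10, lead_time_h = 2,
                            ph_far = 6.9, ph_near = 5.0,
                            front_width_um = 50))
    xs <- (seq_len(dim(phValues(f))[3]) - 0.5) * spacingUm(f)
    for (fr in 0:3) {
        row <- phValues(f)[fr + 1, 1, ]
        acid <- which(6.9 - row > 0.05)
        edge <- if (length(acid)) max(xs[acid]) else -Inf
        expect_lt(abs(edge - 10 * (fr + 2)), 2 * spacingUm(f) + 1.5)
    }

    # at the study's rates the edge (100 t + 1800 um) is capped at the
    # field width from t = 0: the whole field is already acidified
    cfg2 <- SceneConfig(nFrames = 2L)
    f2 <- generateField(cfg2, "hyphal_front",
                        list(extension_rate_um_per_h = 100,
                             lead_time_h = 18, ph_far = 6.9, ph_near = 5.0))
    expect_true(all(6.9 - phValues(f2)[1, , ] > 0.05))
})

test_that("Poisson placement matches density x area and is reproducible", {
    cfg <- SceneConfig()  # 0.32 mm^2 at 2200 cells/mm^2 -> mean 704
    counts <- vapply(1:200, function(s)
        nrow(cellPositions(placeCells(cfg, seed = s))), numeric(1))
    se <- sqrt(704 / 200)
    expect_lt(abs(mean(counts) - 704), 3 * se)

    zero <- SceneConfig(cellDensityPerMm2 = 0)
    expect_identical(nrow(cellPositions(placeCells(zero))), 0L)

    expect_identical(placeCells(cfg, seed = 5L), placeCells(cfg, seed = 5L))
})

test_that("noise-free isolated cells render the calibrated ratio", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    phys <- Photophysics()
    # unbuffered endpoint: pH 5.0 -> R 1.59
    f5 <- generateField(cfg, "uniform", list(ph = 5.0))
    pair <- renderFrame(f5, lay, phys, cfg, noise = FALSE)
    obs <- measureCells(segmentCells(pair), pair)
    expect_true(all(obs$qc_flag == "ok"))
    expect_lt(max(abs(obs$ratio - 1.59)), 0.01)

    # ratio fidelity across the calibrated range: recovered pH within 0.01
    crv <- twoPointCurve()
    for (ph in c(4.6, 5.8, 6.9, 7.6)) {
        fp <- generateField(cfg, "uniform", list(ph = ph))
        pp <- renderFrame(fp, lay, phys, cfg, noise = FALSE)
        oo <- measureCells(segmentCells(pp), pp)
        phs <- ratioToPh(crv, oo$ratio[oo$qc_flag == "ok"])$ph
        expect_lt(max(abs(phs - ph)), 0.01)
    }
})

test_that("empty layout renders pure background; noise model respects A", {
    cfg <- smallScene()
    phys <- Photophysics()
    f <- generateField(cfg, "uniform", list(ph = 6.9))
    empty <- new("CellLayout",
                 cells = data.frame(cell_id = integer(), x_um = numeric(),
                                    y_um = numeric()),
                 fieldWidthUm = cfg@fieldWidthUm,
                 fieldHeightUm = cfg@fieldHeightUm)
    pair <- renderFrame(f, empty, phys, cfg, noise = FALSE)
    expect_true(all(pair@ch475 == phys@background475))
    expect_true(all(pair@ch395 == phys@background395))

    # doubling A leaves every pixelwise background-corrected ratio unchanged
    lay <- gridLayout(cfg)
    p1 <- renderFrame(f, lay, phys, cfg, noise = FALSE)
    phys2 <- Photophysics(totalSignal = 2 * phys@totalSignal)
    p2 <- renderFrame(f, lay, phys2, cfg, noise = FALSE)
    sig <- p1@ch475 - phys@background475 > 50   # on-cell pixels
    r1 <- (p1@ch475[sig] - phys@background475) /
          (p1@ch395[sig] - phys@background395)
    r2 <- (p2@ch475[sig] - phys2@background475) /
          (p2@ch395[sig] - phys2@background395)
    expect_lt(max(abs(r1 - r2)), 0.02)  # integer rounding only
})

test_that("channel response is monotone in pH (475 up, 395 down as pH drops)", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    phys <- Photophysics()
    phs <- c(7.4, 6.6, 5.8, 5.0)
    i475 <- i395 <- numeric(length(phs))
    for (i in seq_along(phs)) {
        f <- generateField(cfg, "uniform", list(ph = phs[i]))
        p <- renderFrame(f, lay, phys, cfg, noise = FALSE)
        o <- measureCells(segmentCells(p), p)
        i475[i] <- mean(o$i475_corr); i395[i] <- mean(o$i395_corr)
    }
    expect_true(all(diff(i475) > 0))  # pH decreasing along phs
    expect_true(all(diff(i395) < 0))
})

test_that("rendering is deterministic and aborts on a non-positive ratio", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    phys <- Photophysics()
    f <- generateField(cfg, "uniform", list(ph = 6.9))
    a <- renderFrame(f, lay, phys, cfg, seed = 3L)
    b <- renderFrame(f, lay, phys, cfg, seed = 3L)
    expect_identical(a@ch475, b@ch475)
    expect_identical(a@ch395, b@ch395)

    f9 <- generateField(cfg, "uniform", list(ph = 8.5))  # R(8.5) < 0
    expect_error(renderFrame(f9, lay, phys, cfg), "R\\(pH\\) <= 0")
})

test_that("scene TIFF round trip preserves counts and metadata", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    phys <- Photophysics()
    f <- generateField(cfg, "uniform", list(ph = 6.0))
    pair <- renderFrame(f, lay, phys, cfg)
    dir <- withr::local_tempdir()
    writeScene(list(pair), f, lay, dir)
    back <- readImagePair(file.path(dir, "frame_000.tif"))
    expect_equal(back@ch475, pair@ch475)
    expect_equal(back@ch395, pair@ch395)
    expect_equal(back@pixelSizeUm, cfg@pixelSizeUm)
    gt <- read.csv(file.path(dir, "ground_truth.csv"))
    expect_setequal(names(gt), c("frame", "row", "col", "ph"))
    expect_true(all(gt$ph == 6.0))
})

test_that("gradient_patch plants a static step of the requested amplitude", {
    cfg <- SceneConfig(fieldWidthUm = 200, fieldHeightUm = 100,
                       nFrames = 3L)
    f <- generateField(cfg, "gradient_patch",
                       list(baseline = 5.8, amplitude = 1.4,
                            length_scale_um = 20, patch_radius_um = 40,
                            anchors = data.frame(x_um = 100, y_um = 50),
                            onset_frame = 1))
    v <- phValues(f)
    expect_true(all(v[1, , ] == 5.8))            # before onset
    expect_identical(v[2, , ], v[3, , ])          # static afterwards
    expect_lt(min(v[2, , ]), 5.8 - 1.4 + 0.05)    # full depth reached
    expect_equal(max(v[2, , ]), 5.8, tolerance = 1e-3)
})
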