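# mask/image constructors for arithmetic-level tests
blankPair <- function(nr = 40, nc = 40, bg475 = 100, bg395 = 100, s = 0.5) {
    new("ImagePair", ch475 = matrix(bg475, nr, nc),
        ch395 = matrix(bg395, nr, nc), frame = 0L, pixelSizeUm = s)
}

test_that("well-separated noise-free disks are all found with true centroids", {
    cfg <- SceneConfig(fieldWidthUm = 100, fieldHeightUm = 50, nFrames = 1L)
    set.seed(4)
    pick <- data.frame(cell_id = 1:10,
                       x_um = seq(8, 92, length.out = 10),
                       y_um = rep(c(15, 35), 5))
    lay <- new("CellLayout", cells = pick, fieldWidthUm = 100,
               fieldHeightUm = 50)
    f <- generateField(cfg, "uniform", list(ph = 6.0))
    pair <- renderFrame(f, lay, Photophysics(), cfg, noise = FALSE)
    seg <- segmentCells(pair)
    expect_identical(nrow(seg$rois), 10L)
    # match each planted cell to nearest ROI
    d <- sqrt(outer(pick$x_um, seg$rois$x_um, "-")^2 +
              outer(pick$y_um, seg$rois$y_um, "-")^2)
    expect_lt(max(apply(d, 1, min)), 0.5)
})

test_that("blank frames and sub-area components give no ROIs", {
    expect_identical(nrow(segmentCells(blankPair())$rois), 0L)

    # a 2-pixel blob = 0.5 um^2 at 0.5 um/px: below the 1 um^2 floor
    p <- blankPair()
    p@ch475[20, 20:21] <- 5000
    expect_identical(nrow(segmentCells(p)$rois), 0L)
    expect_identical(nrow(segmentCells(p, minAreaUm2 = 0.25)$rois), 1L)
})

test_that("segmentation connectivity is 8-connected", {
    p <- blankPair()
    # a diagonal staircase is one component under 8- but not 4-connectivity
    for (k in 0:5) p@ch475[15 + k, 15 + k] <- 8000
    seg <- segmentCells(p, smoothSigmaPx = 0.1, minAreaUm2 = 0.25)
    expect_identical(nrow(seg$rois), 1L)
})

test_that("measureCells applies background correction and QC flags", {
    p <- blankPair()
    mask <- matrix(0L, 40, 40)
    mask[10:12, 10:12] <- 1L
    mask[30:32, 30:32] <- 2L
    p@ch475[10:12, 10:12] <- 300; p@ch395[10:12, 10:12] <- 500
    p@ch475[30:32, 30:32] <- 90                      # below background
    p@ch395[30:32, 30:32] <- 500
    rois <- data.frame(cell_id = 1:2, x_um = c(5.25, 15.25),
                       y_um = c(5.25, 15.25), area_um2 = 2.25)
    obs <- measureCells(list(rois = rois, mask = mask), p,
                        background = c(100, 100))
    expect_equal(obs$i475_corr[1], 200)
    expect_equal(obs$i395_corr[1], 400)
    expect_equal(obs$ratio[1], 0.5)
    expect_identical(obs$qc_flag[1], "ok")
    expect_identical(obs$qc_flag[2], "negative_after_correction")
    expect_true(is.na(obs$ratio[2]))

    # low-signal flag: positive but under k * read noise
    p2 <- blankPair()
    mask2 <- matrix(0L, 40, 40); mask2[5:7, 5:7] <- 1L
    p2@ch475[5:7, 5:7] <- 106; p2@ch395[5:7, 5:7] <- 106
    obs2 <- measureCells(list(rois = rois[1, ], mask = mask2), p2,
                         background = c(100, 100), readNoiseSd = 3, k = 3)
    expect_identical(obs2$qc_flag, "low_signal")

    # ROI outside the image errors
    badMask <- matrix(0L, 10, 10)
    expect_error(measureCells(list(rois = rois, mask = badMask), p),
                 "does not match")
})

test_that("noise-free cell at pH 7.4 measures the published ratio 0.45", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    f <- generateField(cfg, "uniform", list(ph = 7.4))
    pair <- renderFrame(f, lay, Photophysics(), cfg, noise = FALSE)
    obs <- measureCells(segmentCells(pair), pair)
    expect_lt(max(abs(obs$ratio - 0.45)), 0.01)
})

test_that("ratio is invariant to bleaching and to scaling A", {
    cfg <- smallScene()
    lay <- gridLayout(cfg)
    f <- generateField(cfg, "uniform", list(ph = 5.8))
    base <- Photophysics(bleachPerFrame = 0.05)
    p0 <- renderFrame(f, lay, base, cfg, frame = 0L, noise = FALSE)
    # frame 10: A scaled by 0.95^10, same truth
    f10 <- generateField(SceneConfig(fieldWidthUm = 200, fieldHeightUm = 100,
                                     nFrames = 11L), "uniform",
                         list(ph = 5.8))
    p10 <- renderFrame(f10, lay, base, cfg, frame = 10L, noise = FALSE)
    r0 <- measureCells(segmentCells(p0), p0)$ratio
    r10 <- measureCells(segmentCells(p10), p10)$ratio
    expect_lt(max(abs(sort(r0) - sort(r10))), 0.01)
})

test_that("track linking follows identity, jitter, and displacement rules", {
    mkObs <- function(frames, xy) {
        do.call(rbind, lapply(frames, function(f)
            data.frame(cell_id = seq_len(nrow(xy)), frame = f, time_h = f,
                       x_um = xy$x, y_um = xy$y, i475_corr = 200,
                       i395_corr = 400, ratio = 0.5, ph = NA_real_,
                       qc_flag = "ok")))
    }
    xy <- data.frame(x = c(10, 30, 50), y = c(10, 10, 10))
    obs <- linkTracks(mkObs(0:4, xy))
    expect_identical(length(unique(obs$track_id)), 3L)
    expect_true(all(table(obs$track_id) == 5))

    # jitter below the link radius: same tracks
    set.seed(1)
    jit <- do.call(rbind, lapply(0:4, function(f) {
        o <- mkObs(f, xy)
        o$x_um <- o$x_um + runif(3, -0.5, 0.5)
        o$y_um <- o$y_um + runif(3, -0.5, 0.5)
        o
    }))
    expect_identical(length(unique(linkTracks(jit)$track_id)), 3L)

    # a 5 um displacement at frame 3 breaks the track
    disp <- mkObs(0:5, xy[1, , drop = FALSE])
    disp$x_um[disp$frame >= 3] <- disp$x_um[disp$frame >= 3] + 5
    linked <- linkTracks(disp)
    expect_identical(length(unique(linked$track_id)), 2L)
    expect_identical(unique(linked$track_id[linked$frame >= 3]),
                     unique(linked$track_id[linked$frame < 3]) + 1L)

    # gap tolerance: a skipped frame does not split the track
    gap <- mkObs(c(0, 1, 3, 4), xy[1, , drop = FALSE])
    expect_identical(length(unique(linkTracks(gap)$track_id)), 1L)
    farGap <- mkObs(c(0, 4), xy[1, , drop = FALSE])  # gap 3 > maxGap 2
    expect_identical(length(unique(linkTracks(farGap)$track_id)), 2L)
})

test_that("planted cells are recovered and tracked at default SNR", {
    # full study geometry: the per-seed recovery fraction concentrates at
    # ~700 cells, while small cutouts are dominated by Poisson clustering
    cfg <- SceneConfig(nFrames = 3L, seed = 21L)
    phys <- Photophysics()
    f <- generateField(cfg, "uniform", list(ph = 6.2))
    lay <- placeCells(cfg)
    pairs <- renderScene(f, lay, phys, cfg)
    obs <- linkTracks(quantifyStack(pairs))
    full <- table(obs$track_id[obs$qc_flag == "ok"])
    nFull <- sum(full == cfg@nFrames)
    expect_gte(nFull / nrow(cellPositions(lay)), 0.95)

    # conservation: every ok observation belongs to exactly one track
    expect_false(any(is.na(obs$track_id[obs$qc_flag == "ok"])))
    perFrame <- table(obs$track_id, obs$frame)
    expect_true(all(perFrame <= 1))

    # per-cell ratio error within the Monte-Carlo noise bound:
    # repeated noisy renders of one isolated cell give the expected sd
    one <- new("CellLayout",
               cells = data.frame(cell_id = 1L, x_um = 20, y_um = 20),
               fieldWidthUm = 40, fieldHeightUm = 40)
    cfg1 <- SceneConfig(fieldWidthUm = 40, fieldHeightUm = 40, nFrames = 1L)
    f1 <- generateField(cfg1, "uniform", list(ph = 6.2))
    ratios <- vapply(1:40, function(s) {
        p <- renderFrame(f1, one, phys, cfg1, seed = s)
        o <- measureCells(segmentCells(p), p,
                          readNoiseSd = phys@readNoiseSd)
        o$ratio[1]
    }, numeric(1))
    bound <- 4 * stats::sd(ratios)
    p0 <- renderFrame(f, lay, phys, cfg, noise = FALSE)
    truth <- measureCells(segmentCells(p0), p0)
    o1 <- obs[obs$frame == 0 & obs$qc_flag == "ok", ]
    d <- sqrt(outer(truth$x_um, o1$x_um, "-")^2 +
              outer(truth$y_um, o1$y_um, "-")^2)
    match <- apply(d, 1, which.min)
    close <- apply(d, 1, min) < 1
    err <- abs(truth$ratio[close] - o1$ratio[match[close]])
    expect_lt(stats::quantile(err, 0.95), bound)
})
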