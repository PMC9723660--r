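## Per-cell quantification: segmentation of the two-channel frames,
## background-corrected intensity extraction, ratio computation and
## track linking across frames.

## EBImage::bwlabel is 4-connected; merge labels that touch diagonally so
## components follow 8-connectivity.
.bwlabel8 <- function(mask) {
    lab <- EBImage::bwlabel(mask)
    nlab <- max(lab)
    if (nlab < 2L) return(lab)
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
        cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
        cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
        pairs <- unique(pairs)
        for (k in seq_len(nrow(pairs))) {
            ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
            if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
        root <- vapply(seq_len(nlab), find, integer(1))
        relab <- match(root, sort(unique(root)))
        lab[] <- c(0L, relab)[lab + 1L]
    }
    lab
}

#' Segment biosensor cells in a two-channel frame
#'
#' Automated stand-in for interactive per-cell ROI drawing: the channel sum
#' is Gaussian-smoothed (sd 1 px), thresholded globally by Otsu's method,
#' labelled with 8-connectivity, and components outside the area band are
#' dropped. Because foreground covers ~1\% of these frames, a single Otsu
#' pass lands near the background mode and fattens cells until near
#' neighbours merge; by default a second Otsu pass over the above-threshold
#' pixels refines the cut to the cell-core level (recursive Otsu, the
#' standard unbalanced-class correction — still one global threshold, not a
#' shape-based split). A frame with more than 1\% saturated pixels triggers
#' a warning; an empty result (e.g. a blank frame) is valid.
#'
#' @param pair an \code{\linkS4class{ImagePair}}
#' @param minAreaUm2,maxAreaUm2 component area band (default 1-20 um^2)
#' @param smoothSigmaPx smoothing sd in pixels (default 1)
#' @param refineThreshold apply the second Otsu pass (default TRUE)
#' @return list with \code{rois} (data.frame cell_id, x_um, y_um, area_um2)
#'   and \code{mask} (label matrix, 0 = background)
#' @export
segmentCells <- function(pair, minAreaUm2 = 1, maxAreaUm2 = 20,
                         smoothSigmaPx = 1, refineThreshold = TRUE) {
    stopifnot(is(pair, "ImagePair"))
    s <- pair@pixelSizeUm
    total <- pair@ch475 + pair@ch395
    if (mean(pair@ch475 == 65535 | pair@ch395 == 65535) > 0.01)
        warning("frame has >1% saturated pixels", call. = FALSE)
    rng <- range(total)
    empty <- list(rois = data.frame(cell_id = integer(), x_um = numeric(),
                                    y_um = numeric(), area_um2 = numeric()),
                  mask = matrix(0L, nrow(total), ncol(total)))
    if (rng[1] == rng[2]) return(empty)  # constant frame: nothing to find
    sm <- EBImage::gblur(total, sigma = smoothSigmaPx)
    norm <- (sm - min(sm)) / (max(sm) - min(sm))
    thr <- EBImage::otsu(norm, range = c(0, 1))
    if (refineThreshold) {
        above <- norm[norm > thr]
        if (length(above) > 1L && diff(range(above)) > 0)
            thr <- EBImage::otsu(matrix(above, 1L), range = c(0, 1))
    }
    mask <- norm > thr
    lab <- .bwlabel8(mask)
    n <- max(lab)
    if (n == 0L) return(empty)
    pxArea <- s^2
    idx <- which(lab > 0)
    l <- lab[idx]
    areaPx <- tabulate(l, nbins = n)
    ## centroids from pixel centres
    ii <- (idx - 1L) %% nrow(lab) + 1L
    jj <- (idx - 1L) %/% nrow(lab) + 1L
    cx <- tapply((jj - 0.5) * s, l, mean)
    cy <- tapply((ii - 0.5) * s, l, mean)
    keep <- which(areaPx * pxArea >= minAreaUm2 &
                  areaPx * pxArea <= maxAreaUm2)
    if (!length(keep)) return(empty)
    ## drop rejected components from the mask, renumber survivors
    relab <- integer(n)
    relab[keep] <- seq_along(keep)
    lab[] <- c(0L, relab)[lab + 1L]
    list(rois = data.frame(cell_id = seq_along(keep),
                           x_um = as.numeric(cx[as.character(keep)]),
                           y_um = as.numeric(cy[as.character(keep)]),
                           area_um2 = areaPx[keep] * pxArea),
         mask = lab)
}

#' Measure background-corrected per-cell intensities and ratios
#'
#' Per channel, the background is the median over non-ROI pixels of the
#' frame (robust at these cell densities) unless given explicitly. Each
#' cell's corrected intensity is its ROI mean minus background, and the
#' ratio is i475_corr / i395_corr. QC flags:
#' \code{negative_after_correction} when either corrected intensity is
#' <= 0, \code{low_signal} when i395_corr < k * readNoiseSd. pH is left NA
#' for \code{\link{applyCalibration}} to fill.
#'
#' @param seg result of \code{\link{segmentCells}}
#' @param pair the \code{ImagePair} measured
#' @param background optional c(b475, b395) overriding the median estimate
#' @param readNoiseSd camera read noise (counts) for the low-signal test
#' @param k low-signal multiplier (default 3)
#' @param timeH acquisition time of the frame in hours (default frame index)
#' @return data.frame: cell_id, frame, time_h, x_um, y_um, i475_corr,
#'   i395_corr, ratio, ph, qc_flag
#' @export
measureCells <- function(seg, pair, background = NULL, readNoiseSd = 3,
                         k = 3, timeH = NULL) {
    stopifnot(is(pair, "ImagePair"))
    rois <- seg$rois; mask <- seg$mask
    if (!identical(dim(mask), dim(pair@ch475)))
        stop("ROI mask does not match the image")
    if (is.null(timeH)) timeH <- as.numeric(pair@frame)
    if (!nrow(rois))
        return(data.frame(cell_id = integer(), frame = integer(),
                          time_h = numeric(), x_um = numeric(),
                          y_um = numeric(), i475_corr = numeric(),
                          i395_corr = numeric(), ratio = numeric(),
                          ph = numeric(), qc_flag = character()))
    if (is.null(background)) {
        bgpx <- mask == 0L
        background <- c(stats::median(pair@ch475[bgpx]),
                        stats::median(pair@ch395[bgpx]))
    }
    idx <- which(mask > 0L)
    l <- mask[idx]
    m475 <- tapply(pair@ch475[idx], l, mean)
    m395 <- tapply(pair@ch395[idx], l, mean)
    ord <- as.character(rois$cell_id)
    i475 <- as.numeric(m475[ord]) - background[1]
    i395 <- as.numeric(m395[ord]) - background[2]
    qc <- rep("ok", nrow(rois))
    qc[i395 < k * readNoiseSd] <- "low_signal"
    qc[i475 <= 0 | i395 <= 0] <- "negative_after_correction"
    ratio <- i475 / i395
    ratio[qc == "negative_after_correction"] <- NA_real_
    data.frame(cell_id = rois$cell_id, frame = pair@frame, time_h = timeH,
               x_um = rois$x_um, y_um = rois$y_um,
               i475_corr = i475, i395_corr = i395, ratio = ratio,
               ph = NA_real_, qc_flag = qc)
}

#' Quantify a full image stack
#'
#' Runs segmentation and measurement over every frame.
#'
#' @param pairs list of \code{ImagePair}
#' @param frameIntervalH hours between frames (for time_h)
#' @param ... passed to \code{\link{segmentCells}} and
#'   \code{\link{measureCells}}
#' @param readNoiseSd camera read noise for the low-signal flag
#' @return row-bound observation data.frame (see \code{measureCells})
#' @export
quantifyStack <- function(pairs, frameIntervalH = 1, readNoiseSd = 3, ...) {
    out <- lapply(pairs, function(p) {
        seg <- segmentCells(p, ...)
        measureCells(seg, p, readNoiseSd = readNoiseSd,
                     timeH = p@frame * frameIntervalH)
    })
    do.call(rbind, out)
}

#' Link per-frame observations into tracks
#'
#' Greedy nearest-neighbour linking for immobilized cells: candidate pairs
#' between active tracks and current-frame cells closer than
#' \code{linkRadiusUm} are assigned in order of increasing distance (ties:
#' smaller cell_id), each side at most once. Tracks tolerate up to
#' \code{maxGap} missed frames before they are closed; unmatched cells
#' start new tracks.
#'
#' @param obs observation data.frame from \code{\link{quantifyStack}}
#' @param linkRadiusUm maximum link distance (default 2 um)
#' @param maxGap tolerated missing frames within a track (default 2)
#' @return \code{obs} with a \code{track_id} column
#' @export
linkTracks <- function(obs, linkRadiusUm = 2, maxGap = 2) {
    if (!nrow(obs)) { obs$track_id <- integer(); return(obs) }
    obs <- obs[order(obs$frame, obs$cell_id), ]
    obs$track_id <- NA_integer_
    frames <- sort(unique(obs$frame))
    ## active track state
    tx <- numeric(0); ty <- numeric(0); tlast <- integer(0)
    nextId <- 1L
    for (f in frames) {
        sel <- which(obs$frame == f)
        cx <- obs$x_um[sel]; cy <- obs$y_um[sel]
        alive <- which(tlast >= f - 1L - maxGap)
        assigned <- rep(NA_integer_, length(sel))
        if (length(alive) && length(sel)) {
            d <- sqrt(outer(tx[alive], cx, "-")^2 +
                      outer(ty[alive], cy, "-")^2)
            cand <- which(d <= linkRadiusUm, arr.ind = TRUE)
            if (nrow(cand)) {
                ordc <- order(d[cand], obs$cell_id[sel][cand[, 2]])
                usedT <- logical(length(alive))
                usedC <- logical(length(sel))
                for (k in ordc) {
                    ti <- cand[k, 1]; ci <- cand[k, 2]
                    if (!usedT[ti] && !usedC[ci]) {
                        usedT[ti] <- TRUE; usedC[ci] <- TRUE
                        assigned[ci] <- alive[ti]
                    }
                }
            }
        }
        newc <- which(is.na(assigned))
        if (length(newc)) {
            ids <- seq.int(nextId, length.out = length(newc))
            nextId <- nextId + length(newc)
            tx <- c(tx, rep(NA_real_, length(newc)))
            ty <- c(ty, rep(NA_real_, length(newc)))
            tlast <- c(tlast, rep(NA_integer_, length(newc)))
            assigned[newc] <- ids
        }
        obs$track_id[sel] <- assigned
        tx[assigned] <- cx; ty[assigned] <- cy; tlast[assigned] <- f
    }
    rownames(obs) <- NULL
    obs
}

#' Write an observation table as CSV
#'
#' @param obs observation data.frame (optionally with track_id)
#' @param path output CSV
#' @export
writeObservations <- function(obs, path) {
    utils::write.csv(obs, path, row.names = FALSE)
    invisible(path)
}
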