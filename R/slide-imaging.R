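#' Adaptive-threshold segmentation of one channel
#'
#' A pixel is foreground iff its intensity exceeds the local arithmetic mean
#' over a `blockSize` x `blockSize` window by more than `offset`. The binary
#' mask is then cleaned by morphological opening with a disk structuring
#' element and removal of components smaller than `minArea`.
#'
#' @param img numeric intensity matrix (one channel).
#' @param blockSize odd window width in pixels (>= 3).
#' @param offset intensity offset above the local mean.
#' @param minArea minimum component area kept, px^2.
#' @param openRadius radius of the opening disk, px (0 disables opening).
#' @return binary (0/1) matrix of the same shape, with attributes
#'   `channel`-provenance parameters.
#' @examples
#' m <- matrix(0, 60, 60); m[20:40, 20:40] <- 100
#' mask <- segmentChannel(m, blockSize = 31, offset = 10)
#' sum(mask) > 0
#' @export
segmentChannel <- function(img, blockSize = 51, offset = 10, minArea = 50,
                           openRadius = 2) {
    stopifnot(is.matrix(img))
    if (blockSize %% 2 == 0) stop("blockSize must be odd")
    if (blockSize < 3) stop("blockSize must be >= 3")
    w <- (blockSize - 1) / 2
    mask <- EBImage::thresh(EBImage::Image(img), w = w, h = w, offset = offset)
    if (openRadius > 0) {
        brush <- EBImage::makeBrush(2 * openRadius + 1, shape = "disc")
        mask <- EBImage::opening(mask, brush)
    }
    m <- EBImage::imageData(mask)
    if (minArea > 0 && any(m > 0)) {
        lab <- EBImage::imageData(EBImage::bwlabel(mask))
        areas <- tabulate(lab[lab > 0])
        small <- which(areas < minArea)
        if (length(small)) m[lab %in% small] <- 0
    }
    m <- matrix(as.numeric(m > 0), nrow(img), ncol(img))
    attr(m, "provenance") <- list(blockSize = blockSize, offset = offset,
                                  minArea = minArea, openRadius = openRadius)
    m
}

#' Merge per-channel masks into one cell mask
#'
#' Pixel-wise union of one or more binary masks of identical shape.
#'
#' @param masks list of binary matrices.
#' @return binary matrix.
#' @export
mergeMasks <- function(masks) {
    stopifnot(is.list(masks), length(masks) >= 1)
    d <- dim(masks[[1]])
    out <- matrix(0, d[1], d[2])
    for (m in masks) {
        if (!identical(dim(m), d)) stop("mask shape mismatch")
        out <- pmax(out, as.numeric(m > 0))
    }
    out
}

#' Equivalent diameter of a region
#'
#' Diameter of the circle with the same area as the region, converted to
#' micrometres: `pixelSize * sqrt(4 * area / pi)`.
#'
#' @param area region area in px^2 (>= 0; vectorized).
#' @param pixelSize micrometres per pixel.
#' @return diameter(s) in micrometres.
#' @export
equivalentDiameter <- function(area, pixelSize = 1) {
    if (any(area < 0)) stop("area must be non-negative")
    pixelSize * sqrt(4 * area / pi)
}

## per-component summary of intensities: mean/max/total over labelled pixels
.intensityStats <- function(vals, lab, ncomp) {
    keep <- lab > 0
    v <- vals[keep]; l <- lab[keep]
    tot <- rep(0, ncomp); cnt <- rep(0, ncomp); mx <- rep(0, ncomp)
    if (length(v)) {
        s <- rowsum(v, l)
        tot[as.integer(rownames(s))] <- s[, 1]
        tb <- tabulate(l, nbins = ncomp)
        cnt <- tb
        mxv <- vapply(split(v, l), max, numeric(1))
        mx[as.integer(names(mxv))] <- mxv
    }
    list(mean = ifelse(cnt > 0, tot / cnt, 0), max = mx, total = tot)
}

#' Extract per-cell morphometric and intensity features
#'
#' Connected components of the merged cell mask define cells; each cell's
#' nuclear region is the intersection of its component with the DAPI mask.
#' Per cell, reports centroid, areas, equivalent diameters (micrometres) and
#' mean/max/total intensity per channel over the cell and nuclear masks.
#' Cells without any nuclear pixel are kept with `d_nuc_um = 0` and flagged
#' `anucleate`; components touching the image border are flagged `border`.
#'
#' @param cellMask binary cell mask (e.g. from [mergeMasks()]).
#' @param dapiMask binary nuclear mask from the DAPI channel.
#' @param image a [SlideImage-class].
#' @return data.frame of cell records, one row per cell; columns
#'   `cell_id, x, y, area_cell_px, area_nuc_px, d_cell_um, d_nuc_um,
#'   anucleate, border` then `<channel>_{mean,max,total}_{cell,nuc}`.
#' @export
extractCells <- function(cellMask, dapiMask, image) {
    stopifnot(is(image, "SlideImage"),
              identical(dim(cellMask), dim(image)),
              identical(dim(dapiMask), dim(image)))
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cellMask)))
    ncomp <- max(lab)
    cols <- c("cell_id", "x", "y", "area_cell_px", "area_nuc_px",
              "d_cell_um", "d_nuc_um", "anucleate", "border")
    if (ncomp == 0) {
        out <- data.frame(matrix(nrow = 0, ncol = length(cols)))
        names(out) <- cols
        return(out)
    }
    ps <- pixelSize(image)
    keep <- lab > 0
    l <- lab[keep]
    idx <- which(keep, arr.ind = TRUE)
    areaCell <- tabulate(l, nbins = ncomp)
    cx <- rowsum(as.numeric(idx[, 1]), l)[, 1] / areaCell
    cy <- rowsum(as.numeric(idx[, 2]), l)[, 1] / areaCell
    nucLab <- lab * (dapiMask > 0)
    areaNuc <- tabulate(nucLab[nucLab > 0], nbins = ncomp)
    border <- rep(FALSE, ncomp)
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    border[edge[edge > 0]] <- TRUE
    out <- data.frame(cell_id = seq_len(ncomp), x = cx, y = cy,
                      area_cell_px = areaCell, area_nuc_px = areaNuc,
                      d_cell_um = equivalentDiameter(areaCell, ps),
                      d_nuc_um = equivalentDiameter(areaNuc, ps),
                      anucleate = areaNuc == 0, border = border)
    for (ch in channelNames(image)) {
        vals <- channel(image, ch)
        sc <- .intensityStats(vals, lab, ncomp)
        sn <- .intensityStats(vals, nucLab, ncomp)
        out[[paste0(ch, "_mean_cell")]] <- sc$mean
        out[[paste0(ch, "_max_cell")]] <- sc$max
        out[[paste0(ch, "_total_cell")]] <- sc$total
        out[[paste0(ch, "_mean_nuc")]] <- sn$mean
        out[[paste0(ch, "_max_nuc")]] <- sn$max
        out[[paste0(ch, "_total_nuc")]] <- sn$total
    }
    out
}

#' Segment a whole slide and extract cell records
#'
#' Convenience wrapper: segments every channel with [segmentChannel()],
#' merges the channel masks into a cell mask, and extracts features with
#' the DAPI mask as the nuclear mask.
#'
#' @inheritParams segmentChannel
#' @param image a [SlideImage-class].
#' @return list with `records` (data.frame), `cellMask`, `dapiMask`.
#' @export
segmentSlide <- function(image, blockSize = 51, offset = 10, minArea = 50,
                         openRadius = 2) {
    stopifnot(is(image, "SlideImage"))
    masks <- lapply(channelNames(image), function(ch)
        segmentChannel(channel(image, ch), blockSize, offset, minArea,
                       openRadius))
    names(masks) <- channelNames(image)
    cellMask <- mergeMasks(masks)
    dapiMask <- if ("DAPI" %in% names(masks)) masks$DAPI else
        stop("missing channel: DAPI")
    list(records = extractCells(cellMask, dapiMask, image),
         cellMask = cellMask, dapiMask = dapiMask, channelMasks = masks)
}

#' Write a slide as a multi-page TIFF
#'
#' One 16-bit page per channel, stored as `value / 65535`. The page-order
#' channel names are written to a `<path>.channels.txt` sidecar (the TIFF
#' writer exposes no per-page description tag).
#'
#' @param image a [SlideImage-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSlideTIFF <- function(image, path) {
    stopifnot(is(image, "SlideImage"))
    pages <- lapply(channelNames(image), function(ch)
        pmin(channel(image, ch), 65535) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
    writeLines(channelNames(image), paste0(path, ".channels.txt"))
    invisible(path)
}

#' Read a multi-page TIFF slide
#'
#' @param path TIFF written by [writeSlideTIFF()]; channel names are read
#'   from the `<path>.channels.txt` sidecar, with fallback names `ch<i>`
#'   when it is absent.
#' @param pixelSize micrometres per pixel of the stored image.
#' @return A [SlideImage-class].
#' @export
readSlideTIFF <- function(path, pixelSize = 1) {
    pages <- tiff::readTIFF(path, all = TRUE)
    channels <- lapply(pages, function(p) {
        m <- p * 65535
        attributes(m) <- list(dim = dim(p))
        m
    })
    sidecar <- paste0(path, ".channels.txt")
    nms <- if (file.exists(sidecar)) readLines(sidecar)
           else paste0("ch", seq_along(pages))
    names(channels) <- nms
    SlideImage(channels, pixelSize = pixelSize)
}

#' Write cell records as CSV (stable column order)
#'
#' @param records data.frame from [extractCells()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeCellRecords <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}

#' Read a cell-record CSV
#' @param path CSV written by [writeCellRecords()].
#' @return data.frame.
#' @export
readCellRecords <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
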