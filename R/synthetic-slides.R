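#' @importFrom stats rnorm runif rpois rbinom median quantile rmultinom rexp
#'   rnbinom setNames
NULL

## deterministic seed derivation for sub-streams; stays below 2^31
.deriveSeed <- function(base, i) {
    as.integer((as.numeric(base) * 48271 + i * 7919) %% 2147483629)
}

#' Specification of one planted cell class
#'
#' Describes a population of cells to plant on a synthetic slide: how many,
#' their nuclear and whole-cell diameters (Gaussian, in micrometres) and the
#' mean fluorescence intensity in each channel. White blood cells (WBC) carry
#' CD45 and no epithelial signal; CTCs carry the epithelial (EPI) cocktail and
#' no CD45; CTC_IGC are CTCs with at least doubled nuclear diameter;
#' EPI_NEG_IGC are large EPI-negative, variable-channel-positive cells.
#'
#' @param label one of `"WBC"`, `"CTC"`, `"CTC_IGC"`, `"EPI_NEG_IGC"`.
#' @param count number of cells to plant (>= 0).
#' @param nucDiamMean,nucDiamSd nuclear diameter mean/sd, micrometres.
#' @param cellDiamMean,cellDiamSd whole-cell diameter mean/sd, micrometres.
#' @param intensity named numeric vector of per-channel mean intensities
#'   (names are channel names, e.g. DAPI/EPI/CD45/VAR).
#' @return A `CellClassSpec` list.
#' @export
cellClassSpec <- function(label, count, nucDiamMean, nucDiamSd,
                          cellDiamMean, cellDiamSd, intensity) {
    stopifnot(label %in% c("WBC", "CTC", "CTC_IGC", "EPI_NEG_IGC"),
              count >= 0, nucDiamMean > 0, cellDiamMean >= nucDiamMean,
              nucDiamSd >= 0, cellDiamSd >= 0,
              is.numeric(intensity), !is.null(names(intensity)))
    structure(list(label = label, count = as.integer(count),
                   nucDiamMean = nucDiamMean, nucDiamSd = nucDiamSd,
                   cellDiamMean = cellDiamMean, cellDiamSd = cellDiamSd,
                   intensity = intensity),
              class = "CellClassSpec")
}

#' Specification of one synthetic slide
#'
#' @param width,height slide dimensions in pixels.
#' @param pixelSize micrometres per pixel.
#' @param backgroundLevel constant background intensity added to all channels.
#' @param noiseSd standard deviation of additive Gaussian pixel noise.
#' @param cellClasses list of [cellClassSpec()] objects.
#' @param seed integer; fully determines the rendered slide.
#' @return A `SlideSpec` list.
#' @export
slideSpec <- function(width, height, pixelSize = 1, backgroundLevel = 500,
                      noiseSd = 50, cellClasses = list(), seed = 1L) {
    stopifnot(width > 0, height > 0, pixelSize > 0, noiseSd >= 0,
              backgroundLevel >= 0)
    ctc <- Filter(function(s) s$label == "CTC", cellClasses)
    igc <- Filter(function(s) s$label == "CTC_IGC", cellClasses)
    if (length(ctc) && length(igc)) {
        if (any(vapply(igc, `[[`, 0, "nucDiamMean") <
                2 * max(vapply(ctc, `[[`, 0, "nucDiamMean"))))
            stop("CTC_IGC nuclear diameter mean must be >= 2x the CTC mean")
    }
    structure(list(width = as.integer(width), height = as.integer(height),
                   pixelSize = pixelSize, backgroundLevel = backgroundLevel,
                   noiseSd = noiseSd, cellClasses = cellClasses,
                   seed = as.integer(seed)),
              class = "SlideSpec")
}

## linear indices of the disk (cx, cy, radius) within a W x H matrix
.diskIndices <- function(cx, cy, radius, W, H) {
    x0 <- max(1L, floor(cx - radius)); x1 <- min(W, ceiling(cx + radius))
    y0 <- max(1L, floor(cy - radius)); y1 <- min(H, ceiling(cy + radius))
    if (x0 > x1 || y0 > y1) return(integer(0))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
    sel <- which(d2 <= radius^2, arr.ind = TRUE)
    xs[sel[, 1]] + (ys[sel[, 2]] - 1L) * W
}

#' Render a synthetic fluorescence slide
#'
#' Plants the requested cell populations as hard disks (whole cell in the
#' cytoplasmic channels, a concentric nuclear disk in DAPI), applies a
#' sigma = 1 px Gaussian blur, and adds Gaussian pixel noise. Cell centres are
#' placed by rejection sampling so that no two cells overlap (3 px margin) and
#' every cell lies fully inside the slide; placement failure after 10,000
#' attempts for any cell is an error (infeasible packing).
#'
#' @param spec a [slideSpec()].
#' @return list with `image` (a [SlideImage-class]) and `truth` (data.frame of
#'   per-cell ground truth: `cell_id`, `label`, `x`, `y`, nuclear and cell
#'   diameters in micrometres).
#' @examples
#' sp <- slideSpec(120, 120, cellClasses = list(
#'   cellClassSpec("CTC", 2, 12, 0.3, 18, 0.5,
#'                 c(DAPI = 8000, EPI = 9000, CD45 = 0, VAR = 0))), seed = 3)
#' out <- renderSlide(sp)
#' out$truth
#' @export
renderSlide <- function(spec) {
    stopifnot(inherits(spec, "SlideSpec"))
    set.seed(spec$seed)
    chn <- c("DAPI", "EPI", "CD45", "VAR")
    W <- spec$width; H <- spec$height; ps <- spec$pixelSize
    channels <- lapply(chn, function(ch) matrix(0, W, H))
    names(channels) <- chn

    labels <- character(0); nucd <- celld <- numeric(0)
    inten <- list()
    for (cls in spec$cellClasses) {
        if (cls$count == 0) next
        labels <- c(labels, rep(cls$label, cls$count))
        nucd <- c(nucd, pmax(1 * ps, rnorm(cls$count, cls$nucDiamMean, cls$nucDiamSd)))
        celld2 <- pmax(1 * ps, rnorm(cls$count, cls$cellDiamMean, cls$cellDiamSd))
        celld <- c(celld, celld2)
        inten <- c(inten, rep(list(cls$intensity), cls$count))
    }
    ncell <- length(labels)
    celld <- pmax(celld, nucd)                    # nucleus within cell
    rcell <- celld / 2 / ps; rnuc <- nucd / 2 / ps  # radii in px
    ## place largest first: improves packing and keeps it deterministic
    ord <- order(rcell, decreasing = TRUE)
    xs <- ys <- numeric(ncell)
    margin <- 3
    for (k in seq_len(ncell)) {
        i <- ord[k]; placed <- FALSE
        for (a in seq_len(10000L)) {
            x <- runif(1, rcell[i] + 2, W - rcell[i] - 2)
            y <- runif(1, rcell[i] + 2, H - rcell[i] - 2)
            prev <- ord[seq_len(k - 1L)]
            if (k == 1L ||
                all((xs[prev] - x)^2 + (ys[prev] - y)^2 >
                    (rcell[prev] + rcell[i] + margin)^2)) {
                xs[i] <- x; ys[i] <- y; placed <- TRUE; break
            }
        }
        if (!placed)
            stop("infeasible packing: could not place cell after 10000 attempts")
    }
    idxAcc <- valAcc <- stats::setNames(vector("list", length(chn)), chn)
    for (i in seq_len(ncell)) {
        ints <- inten[[i]]
        for (ch in chn) {
            v <- if (ch %in% names(ints)) ints[[ch]] else 0
            if (v <= 0) next
            r <- if (ch == "DAPI") rnuc[i] else rcell[i]
            idx <- .diskIndices(xs[i], ys[i], r, W, H)
            idxAcc[[ch]] <- c(idxAcc[[ch]], idx)
            valAcc[[ch]] <- c(valAcc[[ch]], rep(v, length(idx)))
        }
    }
    for (ch in chn) {
        if (!length(idxAcc[[ch]])) next
        m <- channels[[ch]]
        m[idxAcc[[ch]]] <- m[idxAcc[[ch]]] + valAcc[[ch]]
        channels[[ch]] <- m
    }
    for (ch in chn) {
        m <- channels[[ch]]
        if (ncell > 0) m <- EBImage::gblur(m, sigma = 1)
        m <- m + spec$backgroundLevel
        if (spec$noiseSd > 0) m <- m + matrix(rnorm(W * H, 0, spec$noiseSd), W, H)
        channels[[ch]] <- pmax(m, 0)
    }
    truth <- data.frame(cell_id = seq_len(ncell),
                        label = labels, x = xs, y = ys,
                        nuc_diam_um = nucd, cell_diam_um = celld,
                        stringsAsFactors = FALSE)
    list(image = SlideImage(channels, pixelSize = ps), truth = truth)
}
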