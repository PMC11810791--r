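#' @import methods
#' @importFrom GenomicRanges GRanges seqnames width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

#' Multi-channel fluorescence slide image
#'
#' In-memory representation of one scanned slide: a named list of 2D intensity
#' matrices (one per fluorescence channel, identical dimensions, arbitrary
#' 16-bit-style units) plus the physical pixel size in micrometres.
#'
#' @slot channels named list of numeric matrices, one per channel
#'   (conventionally \code{DAPI}, \code{EPI}, \code{CD45}, \code{VAR}).
#' @slot pixelSize micrometres per pixel (scalar, > 0).
#'
#' @seealso [SlideImage()], [segmentChannel()], [extractCells()]
#' @export
setClass("SlideImage",
         representation(channels = "list", pixelSize = "numeric"))

setValidity("SlideImage", function(object) {
    ch <- object@channels
    if (length(ch) == 0L)
        return("at least one channel required")
    if (is.null(names(ch)) || any(!nzchar(names(ch))))
        return("channels must be named")
    if (!all(vapply(ch, is.matrix, logical(1))))
        return("every channel must be a matrix")
    d <- dim(ch[[1]])
    for (i in seq_along(ch)) {
        if (!identical(dim(ch[[i]]), d))
            return("all channels must share dimensions")
        if (any(ch[[i]] < 0))
            return(sprintf("channel '%s' has negative intensities", names(ch)[i]))
    }
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        return("pixelSize must be a single positive number")
    TRUE
})

#' Construct a SlideImage
#'
#' @param channels named list of non-negative numeric matrices with identical
#'   dimensions.
#' @param pixelSize micrometres per pixel.
#' @return A [SlideImage-class] object.
#' @examples
#' img <- SlideImage(list(DAPI = matrix(0, 20, 20)), pixelSize = 1)
#' channelNames(img)
#' @export
SlideImage <- function(channels, pixelSize = 1) {
    new("SlideImage", channels = channels, pixelSize = pixelSize)
}

#' @describeIn SlideImage names of the fluorescence channels.
#' @param x a \code{SlideImage}.
#' @export
channelNames <- function(x) names(x@channels)

#' @describeIn SlideImage extract one channel's intensity matrix.
#' @param name channel name.
#' @export
channel <- function(x, name) {
    if (!name %in% names(x@channels))
        stop("missing channel: ", name)
    x@channels[[name]]
}

#' @describeIn SlideImage micrometres per pixel.
#' @export
pixelSize <- function(x) x@pixelSize

setMethod("dim", "SlideImage", function(x) dim(x@channels[[1]]))

setMethod("show", "SlideImage", function(object) {
    d <- dim(object)
    cat("SlideImage:", d[1], "x", d[2], "px @", object@pixelSize, "um/px\n")
    cat("channels:", paste(names(object@channels), collapse = ", "), "\n")
})

#' Single-cell copy-number ratio profile
#'
#' Per-bin read counts, genome-median-normalized copy-number ratios, and
#' (after segmentation) a segment assignment with per-segment mean ratios for
#' one cell. A ratio of 1 is copy-number neutral relative to the cell's own
#' genome-wide median, which makes profiles invariant under whole-genome
#' doubling and sequencing depth.
#'
#' @slot cellId character scalar.
#' @slot grid `GRanges` of ordered, non-overlapping bins with a `gc` metadata
#'   column (0-based half-open origin; stored 1-based as usual for `GRanges`).
#' @slot counts raw per-bin read counts.
#' @slot ratio normalized per-bin ratio (median 1).
#' @slot segment integer segment id per bin (0 = unsegmented).
#' @slot segmentRatio per-bin mean ratio of the bin's segment (NA when
#'   unsegmented).
#' @export
setClass("CNProfile",
         representation(cellId = "character", grid = "GRanges",
                        counts = "numeric", ratio = "numeric",
                        segment = "integer", segmentRatio = "numeric"))

setValidity("CNProfile", function(object) {
    n <- length(object@grid)
    if (length(object@counts) != n) return("counts length != number of bins")
    if (length(object@ratio) != n) return("ratio length != number of bins")
    if (length(object@segment) != n) return("segment length != number of bins")
    if (length(object@segmentRatio) != n)
        return("segmentRatio length != number of bins")
    if (any(object@counts < 0)) return("counts must be non-negative")
    if (any(object@ratio < 0, na.rm = TRUE)) return("ratios must be non-negative")
    TRUE
})

setMethod("show", "CNProfile", function(object) {
    cat("CNProfile for cell", object@cellId, "-", length(object@grid), "bins,",
        length(unique(object@segment[object@segment > 0])), "segments\n")
    cat("median ratio:", stats::median(object@ratio), "\n")
})

#' @describeIn CNProfile normalized per-bin copy-number ratios.
#' @param x a \code{CNProfile}.
#' @export
cnRatio <- function(x) x@ratio

#' @describeIn CNProfile per-bin segment mean ratios (NA before segmentation).
#' @export
segmentRatio <- function(x) x@segmentRatio

#' @describeIn CNProfile the bin grid as a `GRanges`.
#' @export
binGrid <- function(x) x@grid
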