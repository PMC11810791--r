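#' @importFrom GenomeInfoDb Seqinfo
NULL

#' Build a genome-wide bin grid
#'
#' Tiles a human-like genome (22 autosomes with lengths proportional to hg38)
#' into approximately `nBins` equal-width bins, 0-based half-open in the
#' on-disk representation. GC fraction per bin follows a smooth deterministic
#' profile in \[0.35, 0.55\] so GC-bias handling can be exercised
#' reproducibly.
#'
#' @param nBins approximate total number of bins (default 5000).
#' @return A `GRanges` with a `gc` metadata column.
#' @export
makeBinGrid <- function(nBins = 5000) {
    stopifnot(nBins >= 22)
    ## hg38 autosome lengths, Mb (rounded)
    lens <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
              114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6
    chroms <- paste0("chr", 1:22)
    binSize <- floor(sum(lens) / nBins)
    perChrom <- pmax(1L, floor(lens / binSize))
    starts <- unlist(lapply(perChrom, function(nb) (seq_len(nb) - 1L) * binSize))
    gr <- GenomicRanges::GRanges(
        rep(chroms, perChrom),
        IRanges::IRanges(start = starts + 1L, width = binSize),
        seqinfo = GenomeInfoDb::Seqinfo(seqnames = chroms))
    idx <- seq_along(gr)
    S4Vectors::mcols(gr)$gc <- 0.45 + 0.10 * sin(idx / 37) * cos(idx / 11) / 2 +
        0.05 * sin(idx / 5) / 2
    gr
}

#' Planted copy-number ground truth
#'
#' @param grid bin grid (`GRanges` with `gc` column), see [makeBinGrid()].
#' @param cnStates integer copy number per bin (>= 0, not all zero).
#' @param wgdFactor integer >= 1; uniform whole-genome multiplication applied
#'   to every bin's state. Ratio profiles are invariant to it.
#' @param readsPerCell expected total reads per cell.
#' @return A `CNGroundTruth` list.
#' @export
cnGroundTruth <- function(grid, cnStates, wgdFactor = 1L, readsPerCell = 5e5) {
    stopifnot(length(cnStates) == length(grid), all(cnStates >= 0),
              any(cnStates > 0), wgdFactor >= 1, readsPerCell > 0)
    structure(list(grid = grid, cnStates = as.integer(cnStates),
                   wgdFactor = as.integer(wgdFactor),
                   readsPerCell = readsPerCell),
              class = "CNGroundTruth")
}

#' PC3-like copy-number preset
#'
#' Copy-number state 3 on chromosome 1 and 1 on chromosome 10 (matching the
#' FISH ploidy of the PC3 line at those centromeres), baseline 2 elsewhere,
#' on a ~5,000-bin genome grid.
#'
#' @param nBins grid resolution.
#' @param wgdFactor uniform whole-genome-doubling multiplier.
#' @param readsPerCell expected reads per cell.
#' @return A `CNGroundTruth`.
#' @export
pc3CNPreset <- function(nBins = 5000, wgdFactor = 1L, readsPerCell = 5e5) {
    grid <- makeBinGrid(nBins)
    st <- rep(2L, length(grid))
    chr <- as.character(GenomicRanges::seqnames(grid))
    st[chr == "chr1"] <- 3L
    st[chr == "chr10"] <- 1L
    cnGroundTruth(grid, st, wgdFactor = wgdFactor, readsPerCell = readsPerCell)
}

## monotone quadratic GC bias curve (increasing on [0.3, 0.6])
.gcBiasCurve <- function(gc) 0.2 + 2 * gc^2

#' Simulate per-cell bin counts from planted copy-number states
#'
#' Each cell's total read count is Poisson around `readsPerCell`; reads fall
#' into bins multinomially with probability proportional to
#' copy-number state x bin width (x an optional monotone quadratic GC bias).
#' The whole-genome-doubling factor multiplies every state uniformly and so
#' cancels from the bin probabilities.
#'
#' @param truth a [cnGroundTruth()].
#' @param nCells number of cells (>= 1).
#' @param seed integer seed; fully determines output.
#' @param gcBias logical; apply the GC bias curve (default FALSE).
#' @return integer matrix of counts, cells in rows, bins in columns.
#' @export
simulateCNCells <- function(truth, nCells, seed = 1L, gcBias = FALSE) {
    stopifnot(inherits(truth, "CNGroundTruth"), nCells >= 1)
    set.seed(seed)
    st <- truth$cnStates * truth$wgdFactor
    w <- GenomicRanges::width(truth$grid)
    p <- st * w
    if (gcBias) p <- p * .gcBiasCurve(S4Vectors::mcols(truth$grid)$gc)
    p <- p / sum(p)
    tot <- rpois(nCells, truth$readsPerCell)
    counts <- t(vapply(tot, function(n) rmultinom(1, n, p)[, 1],
                       numeric(length(p))))
    dimnames(counts) <- list(paste0("cell", seq_len(nCells)),
                             paste0("bin", seq_along(p)))
    counts
}
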