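#' Write a bin grid as BED-like TSV
#'
#' Columns `chrom`, `start`, `end`, `gc`; 0-based half-open coordinates.
#'
#' @param grid `GRanges` with a `gc` column.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeBinGrid <- function(grid, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(grid)),
                     start = GenomicRanges::start(grid) - 1L,
                     end = GenomicRanges::end(grid),
                     gc = S4Vectors::mcols(grid)$gc)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a BED-like bin grid TSV
#'
#' @param path TSV written by [writeBinGrid()].
#' @return `GRanges` with a `gc` column.
#' @export
readBinGrid <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(start = df$start + 1L,
                                                  end = df$end))
    S4Vectors::mcols(gr)$gc <- df$gc
    gr
}

#' Write per-cell bin counts as TSV
#'
#' Cells in rows, bins in columns; row names are cell ids.
#'
#' @param counts cells x bins matrix.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeBinCounts <- function(counts, path) {
    utils::write.table(counts, path, sep = "\t", quote = FALSE,
                       col.names = NA)
    invisible(path)
}

#' Read per-cell bin counts TSV
#' @param path TSV from [writeBinCounts()].
#' @return cells x bins matrix.
#' @export
readBinCounts <- function(path) {
    as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                row.names = 1, check.names = FALSE))
}

#' Write a count matrix as MatrixMarket with gene/cell sidecars
#'
#' Writes `<prefix>.mtx`, `<prefix>.genes.tsv` (gene id + biotype when
#' available) and `<prefix>.cells.tsv` (cell id + metadata).
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param prefix output path prefix.
#' @return the `.mtx` path, invisibly.
#' @export
writeCountsMTX <- function(sce, prefix) {
    m <- Matrix::Matrix(SummarizedExperiment::assay(sce, "counts"),
                        sparse = TRUE)
    Matrix::writeMM(m, paste0(prefix, ".mtx"))
    utils::write.table(
        as.data.frame(SummarizedExperiment::rowData(sce)),
        paste0(prefix, ".genes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    cd <- cbind(cell = colnames(sce), cd)
    utils::write.table(cd, paste0(prefix, ".cells.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(paste0(prefix, ".mtx"))
}

#' Read a MatrixMarket count matrix with sidecars
#'
#' @param prefix prefix used by [writeCountsMTX()].
#' @return a `SingleCellExperiment`.
#' @export
readCountsMTX <- function(prefix) {
    m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
    genes <- utils::read.table(paste0(prefix, ".genes.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    cells <- utils::read.table(paste0(prefix, ".cells.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    rownames(m) <- genes$gene_id
    colnames(m) <- cells$cell
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(cells[, -1, drop = FALSE],
                                       row.names = cells$cell),
        rowData = S4Vectors::DataFrame(genes, row.names = genes$gene_id))
}

#' Write a cohort table as CSV
#' @param cohort data.frame from [simulateCohort()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeCohortCSV <- function(cohort, path) {
    utils::write.csv(cohort, path, row.names = FALSE)
    invisible(path)
}

#' Read a cohort CSV
#' @param path CSV from [writeCohortCSV()].
#' @return data.frame.
#' @export
readCohortCSV <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Render a copy-number ratio heatmap to PNG
#'
#' Cells in rows, bins in columns; white is ratio 1 (copy-number neutral),
#' blue below, red above.
#'
#' @param profiles list of segmented [CNProfile-class] objects.
#' @param path output PNG.
#' @param zlim ratio limits for the color scale.
#' @return `path`, invisibly.
#' @export
plotCNHeatmap <- function(profiles, path, zlim = c(0, 2)) {
    m <- do.call(rbind, lapply(profiles, function(p) .segOrRatio(p)))
    m <- pmin(pmax(m, zlim[1]), zlim[2])
    pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
    grDevices::png(path, width = 900, height = 80 + 24 * nrow(m))
    graphics::image(t(m), col = pal, zlim = zlim, axes = FALSE,
                    main = "segmented copy-number ratio")
    grDevices::dev.off()
    invisible(path)
}

#' Plot Kaplan-Meier step curves to PNG
#'
#' @param curves named list from [kmByGroup()].
#' @param path output PNG.
#' @return `path`, invisibly.
#' @export
plotKM <- function(curves, path) {
    grDevices::png(path, width = 640, height = 480)
    maxT <- max(c(1, unlist(lapply(curves, function(k) k$time))))
    graphics::plot(NULL, xlim = c(0, maxT), ylim = c(0, 1),
                   xlab = "months", ylab = "survival",
                   main = "progression-free survival")
    cols <- c("firebrick", "darkcyan", "gray40", "orange")
    for (i in seq_along(curves)) {
        k <- curves[[i]]
        graphics::lines(stats::stepfun(k$time, c(1, k$surv)),
                        col = cols[(i - 1) %% 4 + 1], do.points = FALSE)
    }
    graphics::legend("topright", legend = names(curves),
                     col = cols[seq_along(curves)], lty = 1)
    grDevices::dev.off()
    invisible(path)
}
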