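#' Single-cell RNA simulation preset
#'
#' Defines a negative-binomial single-cell counts simulation with planted
#' gene programs: sets of genes shifted by a fixed log2 fold change in the
#' conditions they affect. Planted |LFC| must be at least 3 (an 8-fold shift)
#' so downstream threshold recovery has no borderline cases, and every
#' condition must have at least 20 cells.
#'
#' @param nGenes gene universe size.
#' @param conditions data.frame with columns `condition`, `line`, `treated`
#'   (logical) and `n` (cells per condition, >= 20).
#' @param programs list of programs, each `list(genes = <integer indices>,
#'   lfc = <planted log2 fold change>, conditions = <affected condition
#'   labels>)`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsizeMean,libsizeSd library-size distribution (counts).
#' @param biotype character vector of length `nGenes`: one of
#'   `protein_coding`, `lncRNA`, `pseudogene`, `TEC`.
#' @return An `RNAPreset` list.
#' @export
rnaPreset <- function(nGenes, conditions, programs = list(), dispersion = 0.1,
                      libsizeMean = 1e5, libsizeSd = 2e4, biotype = NULL) {
    stopifnot(nGenes >= 1, is.data.frame(conditions),
              all(c("condition", "line", "treated", "n") %in% names(conditions)),
              all(conditions$n >= 20), dispersion > 0, libsizeMean > 0)
    for (p in programs) {
        stopifnot(all(p$genes >= 1), all(p$genes <= nGenes),
                  abs(p$lfc) >= 3.0,
                  all(p$conditions %in% conditions$condition))
    }
    if (is.null(biotype))
        biotype <- rep("protein_coding", nGenes)
    stopifnot(length(biotype) == nGenes,
              all(biotype %in% c("protein_coding", "lncRNA", "pseudogene", "TEC")))
    structure(list(nGenes = as.integer(nGenes), conditions = conditions,
                   programs = programs, dispersion = dispersion,
                   libsizeMean = libsizeMean, libsizeSd = libsizeSd,
                   biotype = biotype),
              class = "RNAPreset")
}

#' The shared-survivor signature preset
#'
#' Two cell lines (MDA, PC3), each with a DMSO control and two drug conditions
#' (cisplatin, docetaxel) at 10 days post treatment release, with cell counts
#' matching the profiled 10-DPT populations (MDA 43/62/62; PC3 129/68/118).
#' Three upregulated survivor programs are planted at log2 fold change 3:
#' a 309-gene program shared by all four treated conditions, a 1282-gene
#' MDA-only program and an 869-gene PC3-only program, so the per-line
#' drug-shared up-gene sets have sizes 1591 and 1178 and their cross-line
#' intersection has size 309. Of the 309 shared genes, 238 are annotated
#' protein_coding and 53 lncRNA (77% and 17%).
#'
#' @param nGenes gene universe size (default 20000, a realistic
#'   transcriptome scale that keeps the planted programs a small share of
#'   each cell's library; must hold the 2460 program genes).
#' @return An `RNAPreset`.
#' @export
signaturePresetA <- function(nGenes = 20000) {
    stopifnot(nGenes >= 2460 + 100)
    conditions <- data.frame(
        condition = c("MDA_ctrl", "MDA_cis", "MDA_doc",
                      "PC3_ctrl", "PC3_cis", "PC3_doc"),
        line = rep(c("MDA", "PC3"), each = 3),
        treated = rep(c(FALSE, TRUE, TRUE), 2),
        n = c(43L, 62L, 62L, 129L, 68L, 118L),
        stringsAsFactors = FALSE)
    shared <- 1:309
    mdaOnly <- 310:(309 + 1282)
    pc3Only <- (309 + 1282 + 1):(309 + 1282 + 869)
    programs <- list(
        list(genes = shared, lfc = 3.0,
             conditions = c("MDA_cis", "MDA_doc", "PC3_cis", "PC3_doc")),
        list(genes = mdaOnly, lfc = 3.0, conditions = c("MDA_cis", "MDA_doc")),
        list(genes = pc3Only, lfc = 3.0, conditions = c("PC3_cis", "PC3_doc")))
    biotype <- rep_len(c(rep("protein_coding", 40), rep("lncRNA", 6),
                         rep("pseudogene", 3), "TEC"), nGenes)
    biotype[shared] <- c(rep("protein_coding", 238), rep("lncRNA", 53),
                         rep("pseudogene", 12), rep("TEC", 6))
    rnaPreset(nGenes, conditions, programs, dispersion = 0.1,
              libsizeMean = 1e5, libsizeSd = 2e4, biotype = biotype)
}

#' Simulate single-cell RNA counts from a preset
#'
#' Gene baseline means are log-normal; program genes get moderate uniform
#' baselines (mean count 1-2) so planted shifts are never sub-detection and
#' the programs stay a small share of each cell's library; counts are
#' negative binomial
#' with per-cell library-size factors; program genes are multiplied by
#' `2^lfc` in the conditions their program affects. Cells within each
#' condition are split over two sequencing batches.
#'
#' @param preset an [rnaPreset()].
#' @param seed integer seed; fully determines the counts.
#' @return A `SingleCellExperiment` with a `counts` assay, `colData` columns
#'   `condition`, `line`, `treated`, `batch`, and `rowData` columns
#'   `biotype` and `program`.
#' @export
simulateRNACounts <- function(preset, seed = 1L) {
    stopifnot(inherits(preset, "RNAPreset"))
    set.seed(seed)
    G <- preset$nGenes
    conds <- preset$conditions
    nc <- sum(conds$n)
    baseMean <- stats::rlnorm(G, meanlog = log(1.5), sdlog = 1)
    inProgram <- rep(FALSE, G)
    for (p in preset$programs) inProgram[p$genes] <- TRUE
    baseMean[inProgram] <- runif(sum(inProgram), 1, 2)

    condition <- rep(conds$condition, conds$n)
    line <- rep(conds$line, conds$n)
    treated <- rep(conds$treated, conds$n)
    batch <- unlist(lapply(conds$n, function(n) rep_len(c("b1", "b2"), n)),
                    use.names = FALSE)
    libsize <- pmax(stats::rnorm(nc, preset$libsizeMean, preset$libsizeSd),
                    0.2 * preset$libsizeMean)
    sf <- libsize / preset$libsizeMean

    lfcMat <- matrix(0, nrow = G, ncol = nrow(conds),
                     dimnames = list(NULL, conds$condition))
    for (p in preset$programs) lfcMat[p$genes, p$conditions] <- p$lfc

    counts <- matrix(0L, nrow = G, ncol = nc)
    size <- 1 / preset$dispersion
    for (j in seq_len(nrow(conds))) {
        cells <- which(condition == conds$condition[j])
        mu <- outer(baseMean * 2^lfcMat[, j], sf[cells])
        counts[, cells] <- matrix(
            rnbinom(length(mu), mu = mu, size = size), nrow = G)
    }
    geneId <- sprintf("gene%05d", seq_len(G))
    rownames(counts) <- geneId
    colnames(counts) <- sprintf("cell%04d", seq_len(nc))
    prog <- rep("none", G)
    for (i in seq_along(preset$programs))
        prog[preset$programs[[i]]$genes] <- paste0("program", i)
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(condition = condition, line = line,
                                       treated = treated, batch = batch,
                                       row.names = colnames(counts)),
        rowData = S4Vectors::DataFrame(gene_id = geneId,
                                       biotype = preset$biotype,
                                       program = prog,
                                       row.names = geneId))
}
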