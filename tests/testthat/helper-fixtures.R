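## small fixtures shared across test files; everything built in code

tinyCTCSpec <- function(seed = 3, nCTC = 2, nIGC = 0, noiseSd = 25,
                        size = 220) {
    classes <- list(
        cellClassSpec("CTC", nCTC, 12, 0.3, 18, 0.5,
                      c(DAPI = 8000, EPI = 9000, CD45 = 0, VAR = 0)))
    if (nIGC > 0)
        classes <- c(classes, list(
            cellClassSpec("CTC_IGC", nIGC, 28, 0.8, 36, 1,
                          c(DAPI = 8000, EPI = 9000, CD45 = 0, VAR = 0))))
    slideSpec(size, size, pixelSize = 1, backgroundLevel = 500,
              noiseSd = noiseSd, cellClasses = classes, seed = seed)
}

## a hand-built record table for classification tests (no imaging involved)
recordsFromIntensity <- function(dapi, epi, cd45, var = rep(0, length(dapi)),
                                 dnuc = rep(10, length(dapi))) {
    data.frame(cell_id = seq_along(dapi), d_nuc_um = dnuc,
               d_cell_um = dnuc * 1.5,
               DAPI_mean_cell = dapi, EPI_mean_cell = epi,
               CD45_mean_cell = cd45, VAR_mean_cell = var)
}

fixedThresholds <- c(DAPI = 1000, EPI = 1000, CD45 = 1000, VAR = 1000)

## tiny RNA preset: 2 conditions (one line), optional planted program
tinyRNAPreset <- function(nGenes = 300, n = 30, programGenes = integer(0),
                          lfc = 3) {
    conds <- data.frame(condition = c("ctrl", "treat"), line = "L",
                        treated = c(FALSE, TRUE), n = c(n, n),
                        stringsAsFactors = FALSE)
    progs <- if (length(programGenes))
        list(list(genes = programGenes, lfc = lfc, conditions = "treat"))
    else list()
    rnaPreset(nGenes, conds, progs, dispersion = 0.1,
              libsizeMean = 5e4, libsizeSd = 5e3)
}

## flat two-chromosome grid with unit-length bins for hand CN examples
flatGrid <- function(nPerChrom = c(400)) {
    chroms <- paste0("chr", seq_along(nPerChrom))
    starts <- unlist(lapply(nPerChrom, function(n) seq_len(n) * 100 - 99))
    suppressWarnings(GenomicRanges::GRanges(
        rep(chroms, nPerChrom),
        IRanges::IRanges(start = starts, width = 100),
        gc = 0.45))
}
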