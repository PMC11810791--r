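test_that("log2 CPM follows the closed formula and is depth-invariant", {
    m <- matrix(c(10, 0, 90, 5, 5, 0), nrow = 3,
                dimnames = list(paste0("g", 1:3), c("c1", "c2")))
    cpm <- normalizeCPM(m)
    expect_equal(cpm[1, 1], log2(1 + 1e6 * 10 / 100))
    expect_equal(cpm[2, 2], log2(1 + 1e6 * 5 / 10))
    expect_equal(cpm[2, 1], 0)
    ## doubling all counts of a cell leaves its CPM unchanged
    m2 <- m; m2[, 1] <- m2[, 1] * 2
    expect_equal(normalizeCPM(m2)[, 1], cpm[, 1])
    ## one gene carrying the whole library
    single <- matrix(c(7), dimnames = list("g", "c"))
    expect_equal(normalizeCPM(single)[1, 1], log2(1 + 1e6))
    bad <- m; bad[, 2] <- 0
    expect_error(normalizeCPM(bad), "c2")
})

test_that("identical groups produce a null DE result", {
    preset <- tinyRNAPreset(nGenes = 400, n = 30)
    sce <- simulateRNACounts(preset, seed = 41)
    cond <- SummarizedExperiment::colData(sce)$condition
    ## split the control condition into two arbitrary halves
    ia <- which(cond == "ctrl")[1:15]; ib <- which(cond == "ctrl")[16:30]
    de <- deTest(sce, ia, ib)
    expect_equal(length(upregulatedSet(de)), 0)
    expect_true(all(de$q >= de$p - 1e-12))
})

test_that("a planted LFC-3 gene passes both DE thresholds", {
    preset <- tinyRNAPreset(nGenes = 400, n = 40, programGenes = c(7L, 8L))
    sce <- simulateRNACounts(preset, seed = 43)
    cond <- SummarizedExperiment::colData(sce)$condition
    de <- deTest(sce, which(cond == "ctrl"), which(cond == "treat"),
                 batch = SummarizedExperiment::colData(sce)$batch)
    up <- upregulatedSet(de, 1.5, 0.01)
    expect_true(all(c("gene00007", "gene00008") %in% up))
})

test_that("DE false discoveries stay within the nominal FDR over replicates", {
    fdp <- vapply(1:20, function(s) {
        preset <- tinyRNAPreset(nGenes = 2000, n = 30)
        sce <- simulateRNACounts(preset, seed = 1000 + s)
        cond <- SummarizedExperiment::colData(sce)$condition
        de <- deTest(sce, which(cond == "ctrl"), which(cond == "treat"))
        ## all cells are exchangeable: every q < 0.01 discovery is false
        as.numeric(sum(de$q < 0.01) > 0)
    }, numeric(1))
    ## FDR control implies P(any false discovery) <= 0.01 under the global
    ## null; allow two-sigma binomial slack over the 20 replicates
    expect_lte(mean(fdp), 0.01 + 2 * sqrt(0.01 * 0.99 / 20))
})

test_that("Benjamini-Hochberg matches the hand-computed step-up values", {
    p <- c(0.001, 0.01, 0.02, 0.8)
    expect_equal(stats::p.adjust(p, method = "BH"),
                 c(0.004, 0.02, 4 * 0.02 / 3, 0.8))
})

test_that("set intersection logic and monotonicity hold", {
    mkDE <- function(genes, lfc, q) data.frame(gene = genes, lfc = lfc, q = q)
    de <- list(
        A1 = mkDE(c("a", "b", "c", "d"), c(2, 2, 2, 0.2), c(0, 0, 0, 0)),
        A2 = mkDE(c("a", "b", "c", "d"), c(2, 2, 0.3, 2), c(0, 0, 0, 0)),
        B1 = mkDE(c("a", "b", "c", "d"), c(2, 2, 2, 2), c(0, 0.5, 0, 0)),
        B2 = mkDE(c("a", "b", "c", "d"), c(2, 2, 2, 2), c(0, 0, 0, 0)))
    lines <- list(A = c("A1", "A2"), B = c("B1", "B2"))
    res <- sharedUpregulated(de, lines)
    expect_equal(sort(res$lineSets$A), c("a", "b"))
    expect_equal(sort(res$lineSets$B), c("a", "c", "d"))
    expect_equal(res$survivorSet, "a")
    ## relaxing thresholds never shrinks a set
    res2 <- sharedUpregulated(de, lines, lfcThresh = 0.1, fdrThresh = 0.6)
    expect_true(all(res$survivorSet %in% res2$survivorSet))
    expect_true(all(res$lineSets$A %in% res2$lineSets$A))
    ## disjoint drug sets give an empty survivor set
    deD <- list(A1 = mkDE("x", 2, 0), A2 = mkDE("y", 2, 0),
                B1 = mkDE("x", 2, 0), B2 = mkDE("x", 2, 0))
    expect_equal(length(sharedUpregulated(deD, lines)$survivorSet), 0)
    expect_error(sharedUpregulated(de[1:3], lines), "missing comparison")
})

test_that("linear-scale LFC dialect relaxes the cutoff", {
    de <- data.frame(gene = c("a", "b"), lfc = c(0.8, 2), q = c(0, 0))
    expect_equal(upregulatedSet(de, 1.5, 0.01, lfcScale = "log2"), "b")
    expect_equal(sort(upregulatedSet(de, 1.5, 0.01, lfcScale = "linear")),
                 c("a", "b"))
})

test_that("biotype breakdown rounds percentages for reporting", {
    bt <- c(a = "protein_coding", b = "protein_coding", c = "lncRNA",
            d = "pseudogene")
    res <- biotypeBreakdown(c("a", "b", "c"), bt)
    expect_equal(res$percent[res$biotype == "protein_coding"], 67)
    expect_equal(res$percent[res$biotype == "lncRNA"], 33)
    ## unannotated genes fall into TEC; empty set gives an empty table
    res2 <- biotypeBreakdown(c("a", "zz"), bt)
    expect_equal(res2$count[res2$biotype == "TEC"], 1)
    expect_equal(nrow(biotypeBreakdown(character(0), bt)), 0)
    all_pc <- biotypeBreakdown(c("a", "b"), bt)
    expect_equal(all_pc$percent, 100)
})

test_that("Fisher over-representation matches a brute-force tail sum", {
    universe <- paste0("g", 1:1000)
    query <- universe[1:100]
    lib <- list(hit = universe[c(1:10, 101:140)],   # a=10, set size 50
                miss = universe[900:950])
    res <- overrepresentation(query, universe, lib)
    ## independent oracle: hypergeometric upper tail, a = 10..50
    a <- 10; K <- 50; n <- 100; N <- 1000
    pOracle <- sum(stats::dhyper(a:K, K, N - K, n))
    expect_equal(res$p[res$set == "hit"], pOracle, tolerance = 1e-12)
    ## library set equal to the query: minimal p among sets
    lib2 <- c(lib, list(self = query))
    res2 <- overrepresentation(query, universe, lib2)
    expect_equal(res2$set[1], "self")
    ## disjoint set: odds ratio 0, p = 1
    dis <- res[res$set == "miss", ]
    expect_equal(dis$oddsRatio, 0)
    expect_equal(dis$p, 1)
    expect_error(overrepresentation(query, character(0), lib), "universe")
})

test_that("GMT libraries round-trip through the reader", {
    path <- tempfile(fileext = ".gmt")
    writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg9"), path)
    lib <- readGeneSetLibrary(path)
    expect_equal(lib$setA, c("g1", "g2", "g3"))
    expect_equal(lib$setB, c("g2", "g9"))
    unlink(path)
})

test_that("signature scores separate cells with the program on vs off", {
    preset <- tinyRNAPreset(nGenes = 300, n = 40, programGenes = 1:25)
    sce <- simulateRNACounts(preset, seed = 47)
    cond <- SummarizedExperiment::colData(sce)$condition
    sc <- signatureScore(normalizeCPM(sce),
                         sprintf("gene%05d", 1:25))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_gt(mean(sc[cond == "treat"]), mean(sc[cond == "ctrl"]))
})

test_that("degenerate signature scoring cases are defined", {
    m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("g1", "g2"), c("c1", "c2")))
    ## signature = all genes: both components constant, flagged degenerate
    ws <- testthat::capture_warnings(sc <- signatureScore(m, c("g1", "g2")))
    expect_true(any(grepl("degenerate", ws)))
    expect_equal(unname(sc), c(0.5, 0.5))
    ## single cell: min-max scaling degenerate by convention -> 0.5
    m1 <- m[, 1, drop = FALSE]
    ws1 <- testthat::capture_warnings(sc1 <- signatureScore(m1, "g1"))
    expect_true(any(grepl("degenerate", ws1)))
    expect_equal(unname(sc1), 0.5)
    expect_error(signatureScore(m, "nope"), "no signature gene")
})

test_that("MTX round trip preserves counts and metadata", {
    preset <- tinyRNAPreset(nGenes = 50, n = 20)
    sce <- simulateRNACounts(preset, seed = 53)
    prefix <- tempfile()
    writeCountsMTX(sce, prefix)
    back <- readCountsMTX(prefix)
    expect_equal(unname(SummarizedExperiment::assay(back, "counts")),
                 unname(SummarizedExperiment::assay(sce, "counts")))
    expect_equal(SummarizedExperiment::colData(back)$condition,
                 as.character(SummarizedExperiment::colData(sce)$condition))
    unlink(paste0(prefix, c(".mtx", ".genes.tsv", ".cells.tsv")))
})
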