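#' @importFrom matrixStats rowRanks
NULL

.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts")
    else as.matrix(x)
}

#' Log2 counts-per-million normalization
#'
#' `log2(1 + 1e6 * count / libsize)` per cell, with library size the cell's
#' total count.
#'
#' @param counts genes x cells count matrix (or a SummarizedExperiment with
#'   a `counts` assay).
#' @return matrix of log2 CPM values, same dimnames.
#' @export
normalizeCPM <- function(counts) {
    m <- .countsOf(counts)
    lib <- colSums(m)
    if (any(lib == 0))
        stop("zero library size for cells: ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    log2(1 + sweep(m, 2, lib, "/") * 1e6)
}

## vectorized per-gene rank-sum z (group B vs A), tie-corrected
.rankSumZ <- function(logcpm, idxA, idxB) {
    sub <- logcpm[, c(idxA, idxB), drop = FALSE]
    nA <- length(idxA); nB <- length(idxB); n <- nA + nB
    r <- matrixStats::rowRanks(sub, ties.method = "average")
    W <- rowSums(r[, (nA + 1):n, drop = FALSE])
    mu <- nB * (n + 1) / 2
    tieTerm <- apply(r, 1, function(rr) {
        tb <- table(rr); sum(tb^3 - tb)
    })
    sig2 <- nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- (W - mu) / sqrt(pmax(sig2, 1e-300))
    z[sig2 == 0] <- 0
    z
}

#' Two-group differential expression on single-cell counts
#'
#' Stratified Wilcoxon rank-sum on log2 CPM: within each sequencing batch
#' that contains both groups, a tie-corrected rank-sum z is computed per
#' gene, and the strata are combined by Stouffer weighting with sqrt(n).
#' The log2 fold change is the difference in group means of `log2(CPM + 1)`
#' (B minus A; treat B as the treated group). Genes expressed in fewer than
#' `minDetect` of cells in both groups are excluded before testing; q-values
#' are Benjamini-Hochberg over the tested genes.
#'
#' @param counts genes x cells counts (matrix or SummarizedExperiment).
#' @param groupA,groupB cell indices or names for the two groups (>= 3
#'   each).
#' @param batch optional per-cell batch labels (length = total cells of
#'   `counts`); `NULL` for a single stratum.
#' @param minDetect detection-rate filter (default 0.1).
#' @return data.frame: `gene`, `lfc`, `p`, `q`, `meanA`, `meanB`, `detA`,
#'   `detB`.
#' @export
deTest <- function(counts, groupA, groupB, batch = NULL, minDetect = 0.1) {
    m <- .countsOf(counts)
    toIdx <- function(g) if (is.character(g)) match(g, colnames(m)) else g
    idxA <- toIdx(groupA); idxB <- toIdx(groupB)
    if (length(idxA) < 3 || length(idxB) < 3)
        stop("each group needs at least 3 cells")
    logcpm <- normalizeCPM(m[, c(idxA, idxB), drop = FALSE])
    a <- seq_along(idxA); b <- length(idxA) + seq_along(idxB)
    detA <- rowMeans(m[, idxA, drop = FALSE] > 0)
    detB <- rowMeans(m[, idxB, drop = FALSE] > 0)
    keep <- detA >= minDetect | detB >= minDetect
    lg <- logcpm[keep, , drop = FALSE]
    meanA <- rowMeans(lg[, a, drop = FALSE])
    meanB <- rowMeans(lg[, b, drop = FALSE])
    lfc <- meanB - meanA
    if (is.null(batch)) batch <- rep("all", ncol(m))
    bt <- batch[c(idxA, idxB)]
    zs <- NULL; ws <- NULL
    for (s in unique(bt)) {
        sa <- a[bt[a] == s]; sb <- b[bt[b] == s]
        if (length(sa) < 2 || length(sb) < 2) next
        zs <- cbind(zs, .rankSumZ(lg, sa, sb))
        ws <- c(ws, sqrt(length(sa) + length(sb)))
    }
    if (is.null(zs))
        stop("no batch stratum contains both groups")
    z <- as.numeric(zs %*% ws) / sqrt(sum(ws^2))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(gene = rownames(lg), lfc = lfc, p = p,
               q = stats::p.adjust(p, method = "BH"),
               meanA = meanA, meanB = meanB,
               detA = detA[keep], detB = detB[keep],
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Up-regulated gene set of one comparison
#'
#' @param de a [deTest()] result.
#' @param lfcThresh LFC threshold; interpreted on the log2 scale by default
#'   (`lfcScale = "log2"`, i.e. LFC > 1.5 is ~2.8-fold) or as a linear fold
#'   change (`"linear"`, i.e. LFC > log2(1.5)).
#' @param fdrThresh BH q-value threshold.
#' @param lfcScale `"log2"` or `"linear"`.
#' @return character vector of gene ids.
#' @export
upregulatedSet <- function(de, lfcThresh = 1.5, fdrThresh = 0.01,
                           lfcScale = c("log2", "linear")) {
    lfcScale <- match.arg(lfcScale)
    th <- if (lfcScale == "log2") lfcThresh else log2(lfcThresh)
    de$gene[de$lfc > th & de$lfc > 0 & de$q < fdrThresh]
}

#' Shared-survivor gene-set intersection
#'
#' For each cell line, intersects the up-regulated gene sets of its two drug
#' comparisons; the cross-line intersection of those per-line shared sets is
#' the survivor set. Monotone in the thresholds: relaxing them never shrinks
#' any reported set.
#'
#' @param deResults named list of [deTest()] results, one per
#'   treated-vs-control comparison.
#' @param lines named list mapping each line to the names of its comparisons
#'   in `deResults` (e.g. `list(MDA = c("MDA_cis","MDA_doc"), ...)`).
#' @inheritParams upregulatedSet
#' @return list with `lineSets` (named list of per-line shared up-gene
#'   vectors), `survivorSet`, `upSets` (per comparison) and `sizes`.
#' @export
sharedUpregulated <- function(deResults, lines, lfcThresh = 1.5,
                              fdrThresh = 0.01, lfcScale = "log2") {
    missing <- setdiff(unlist(lines), names(deResults))
    if (length(missing))
        stop("missing comparison(s): ", paste(missing, collapse = ", "))
    upSets <- lapply(deResults, upregulatedSet, lfcThresh = lfcThresh,
                     fdrThresh = fdrThresh, lfcScale = lfcScale)
    lineSets <- lapply(lines, function(cmp) Reduce(intersect, upSets[cmp]))
    survivorSet <- Reduce(intersect, lineSets)
    list(lineSets = lineSets, survivorSet = survivorSet, upSets = upSets,
         sizes = c(vapply(lineSets, length, integer(1)),
                   survivor = length(survivorSet)))
}

#' Biotype breakdown of a gene set
#'
#' @param genes character vector of gene ids.
#' @param biotype named character vector (gene -> biotype); genes without an
#'   annotation are counted as `TEC`.
#' @return data.frame `biotype`, `count`, `percent` (percent rounded to
#'   integers for reporting); zero rows for an empty set.
#' @export
biotypeBreakdown <- function(genes, biotype) {
    if (length(genes) == 0)
        return(data.frame(biotype = character(0), count = integer(0),
                          percent = numeric(0)))
    bt <- biotype[genes]
    bt[is.na(bt)] <- "TEC"
    tb <- sort(table(bt), decreasing = TRUE)
    data.frame(biotype = names(tb), count = as.integer(tb),
               percent = round(100 * as.integer(tb) / length(genes)),
               stringsAsFactors = FALSE)
}

#' Read a GMT gene-set library
#'
#' @param path GMT file (one set per line: name, description, genes).
#' @return named list of gene-id vectors.
#' @export
readGeneSetLibrary <- function(path) {
    fgsea::gmtPathways(path)
}

#' Gene-set over-representation (one-sided Fisher)
#'
#' For each library set, a one-sided Fisher exact test of the query set
#' against the universe, BH-corrected across library sets.
#'
#' @param geneSet query genes (must be a subset of `universe`).
#' @param universe background gene ids (non-empty).
#' @param library named list of gene sets (e.g. from
#'   [readGeneSetLibrary()]); sets are intersected with the universe.
#' @return data.frame: `set`, `overlap`, `setSize`, `oddsRatio`, `p`, `q`,
#'   ordered by p.
#' @export
overrepresentation <- function(geneSet, universe, library) {
    if (length(universe) == 0) stop("empty universe")
    stopifnot(all(geneSet %in% universe))
    res <- lapply(names(library), function(nm) {
        lib <- intersect(library[[nm]], universe)
        a <- length(intersect(geneSet, lib))
        b <- length(geneSet) - a
        cc <- length(lib) - a
        d <- length(universe) - a - b - cc
        ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2),
                                 alternative = "greater")
        data.frame(set = nm, overlap = a, setSize = length(lib),
                   oddsRatio = unname(ft$estimate), p = ft$p.value,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out[order(out$p), , drop = FALSE]
}

#' Rank-based single-cell signature score
#'
#' JASMINE-style scoring. Per cell, among its expressed genes (value > 0):
#' the mean rank of expressed signature genes divided by the number of
#' expressed genes (rank component), and the odds ratio of expression of
#' signature vs non-signature genes (a Haldane 0.5 correction is applied
#' when a margin is zero). Each component is min-max scaled across cells and
#' the two are averaged, giving a score in \[0, 1\]. When a component is
#' constant across cells (including the single-cell case) its scaled value
#' is defined as 0.5 and a warning is emitted.
#'
#' @param logcpm genes x cells expression matrix (e.g. [normalizeCPM()]).
#' @param geneSet signature gene ids (at least one must be expressed in some
#'   cell).
#' @return numeric vector of per-cell scores in \[0, 1\].
#' @export
signatureScore <- function(logcpm, geneSet) {
    stopifnot(is.matrix(logcpm))
    sig <- rownames(logcpm) %in% geneSet
    if (!any(sig)) stop("no signature gene present in the matrix")
    expressed <- logcpm > 0
    if (!any(expressed[sig, , drop = FALSE]))
        stop("no signature gene expressed in any cell")
    nCells <- ncol(logcpm)
    rankComp <- orComp <- numeric(nCells)
    for (j in seq_len(nCells)) {
        e <- expressed[, j]
        nE <- sum(e)
        if (nE == 0) { rankComp[j] <- 0; orComp[j] <- 0; next }
        r <- rank(logcpm[e, j])
        sigE <- sig[e]
        rankComp[j] <- if (any(sigE)) mean(r[sigE]) / nE else 0
        a <- sum(sig & e); b <- sum(sig & !e)
        cc <- sum(!sig & e); d <- sum(!sig & !e)
        orComp[j] <- if (b == 0 || cc == 0)
            ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
        else (a * d) / (b * cc)
    }
    minmax <- function(v) {
        rng <- range(v)
        if (diff(rng) < 1e-12) {
            warning("degenerate component: constant across cells; set to 0.5")
            return(rep(0.5, length(v)))
        }
        (v - rng[1]) / diff(rng)
    }
    (minmax(rankComp) + minmax(orComp)) / 2
}
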