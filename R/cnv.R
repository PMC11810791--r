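#' Normalize bin counts to copy-number ratios
#'
#' Counts are divided by bin width (read density), optionally corrected for
#' GC content by dividing by a median-per-GC-decile curve, then scaled so the
#' genome-wide median ratio equals 1. A ratio of 1 is copy-number neutral
#' relative to the cell's own genome; the normalization is invariant to
#' global count scaling, so sequencing depth and whole-genome doubling cancel.
#'
#' @param counts per-bin counts for one cell (not all zero).
#' @param grid bin grid `GRanges` with a `gc` metadata column.
#' @param gcCorrect apply GC-decile median correction.
#' @param cellId cell identifier.
#' @return A [CNProfile-class] with ratios filled, not yet segmented.
#' @export
normalizeRatios <- function(counts, grid, gcCorrect = FALSE, cellId = "cell") {
    stopifnot(length(counts) == length(grid), all(counts >= 0))
    if (all(counts == 0)) stop("all-zero counts: cannot normalize")
    dens <- counts / GenomicRanges::width(grid)
    if (gcCorrect) {
        gc <- S4Vectors::mcols(grid)$gc
        dec <- cut(gc, breaks = stats::quantile(gc, probs = seq(0, 1, 0.1)),
                   include.lowest = TRUE)
        med <- tapply(dens, dec, stats::median)
        med[med == 0 | is.na(med)] <- stats::median(dens[dens > 0])
        dens <- dens / as.numeric(med[dec])
    }
    r <- dens / stats::median(dens)
    new("CNProfile", cellId = cellId, grid = grid,
        counts = as.numeric(counts), ratio = r,
        segment = rep(0L, length(grid)), segmentRatio = rep(NA_real_,
                                                            length(grid)))
}

## max two-sample t statistic over candidate splits of x; returns list(stat, split)
.maxSplitT <- function(x, minBins) {
    n <- length(x)
    ks <- seq(minBins, n - minBins)
    if (!length(ks)) return(list(stat = -Inf, split = NA_integer_))
    cs <- cumsum(x); cs2 <- cumsum(x^2); tot <- cs[n]; tot2 <- cs2[n]
    nl <- ks; nr <- n - ks
    ml <- cs[ks] / nl; mr <- (tot - cs[ks]) / nr
    ssl <- cs2[ks] - nl * ml^2
    ssr <- (tot2 - cs2[ks]) - nr * mr^2
    s2 <- (ssl + ssr) / pmax(n - 2, 1)
    tstat <- abs(ml - mr) / sqrt(pmax(s2, 1e-12) * (1 / nl + 1 / nr))
    i <- which.max(tstat)
    list(stat = tstat[i], split = ks[i])
}

.segmentVector <- function(x, alpha, minBins, nPerm) {
    n <- length(x)
    if (n < 2 * minBins) return(integer(0))
    obs <- .maxSplitT(x, minBins)
    if (!is.finite(obs$stat)) return(integer(0))
    permMax <- vapply(seq_len(nPerm), function(i)
        .maxSplitT(sample(x), minBins)$stat, numeric(1))
    p <- (1 + sum(permMax >= obs$stat)) / (nPerm + 1)
    if (p >= alpha) return(integer(0))
    s <- obs$split
    left <- .segmentVector(x[seq_len(s)], alpha, minBins, nPerm)
    right <- .segmentVector(x[(s + 1):n], alpha, minBins, nPerm)
    c(left, s, s + right)
}

#' Segment a copy-number ratio profile
#'
#' Recursive binary segmentation per chromosome on log2 ratios (CBS-style):
#' the candidate breakpoint maximizes the two-sample t statistic and is
#' accepted when its within-chromosome permutation p-value is below `alpha`
#' and both sides keep at least `minBins` bins; accepted splits recurse.
#' Segment ratios are the mean (un-logged) ratio per segment. A pseudo-ratio
#' of 0.01 is added before taking log2 so zero-count bins stay finite.
#'
#' @param profile a [CNProfile-class] from [normalizeRatios()].
#' @param alpha permutation significance level for accepting a split.
#' @param minBins minimum bins per segment.
#' @param nPerm permutations per tested split.
#' @return the profile with `segment` and `segmentRatio` filled. Uses the
#'   current RNG stream (set a seed for reproducibility).
#' @export
segmentProfile <- function(profile, alpha = 0.01, minBins = 5, nPerm = 1000) {
    stopifnot(is(profile, "CNProfile"))
    lr <- log2(profile@ratio + 0.01)
    chr <- as.character(GenomicRanges::seqnames(profile@grid))
    seg <- integer(length(lr)); segRatio <- numeric(length(lr))
    nextId <- 1L
    for (ch in unique(chr)) {
        idx <- which(chr == ch)
        bks <- if (stats::var(lr[idx]) < 1e-12) integer(0) else
            sort(.segmentVector(lr[idx], alpha, minBins, nPerm))
        bounds <- c(0L, bks, length(idx))
        for (j in seq_len(length(bounds) - 1L)) {
            sel <- idx[(bounds[j] + 1L):bounds[j + 1L]]
            seg[sel] <- nextId
            segRatio[sel] <- mean(profile@ratio[sel])
            nextId <- nextId + 1L
        }
    }
    profile@segment <- seg
    profile@segmentRatio <- segRatio
    profile
}

#' Pairwise copy-number concordance
#'
#' Correlation of two cells' per-bin log2 segmented ratios (Pearson by
#' default, Spearman as a dialect). Profiles must share the bin grid.
#' Invariant to per-profile uniform scaling by construction of the ratios.
#'
#' @param profileA,profileB segmented [CNProfile-class] objects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in \[-1, 1\], or `NA` (with a warning) when either
#'   profile has zero variance.
#' @export
concordance <- function(profileA, profileB,
                        method = c("pearson", "spearman")) {
    method <- match.arg(method)
    stopifnot(is(profileA, "CNProfile"), is(profileB, "CNProfile"),
              length(profileA@grid) == length(profileB@grid))
    a <- log2(.segOrRatio(profileA) + 0.01)
    b <- log2(.segOrRatio(profileB) + 0.01)
    if (stats::var(a) < 1e-15 || stats::var(b) < 1e-15) {
        warning("zero-variance profile: concordance undefined")
        return(NA_real_)
    }
    stats::cor(a, b, method = method)
}

.segOrRatio <- function(p) {
    if (all(is.na(p@segmentRatio))) p@ratio else p@segmentRatio
}

#' Concordance matrix over a set of cells
#'
#' @param profiles list of segmented [CNProfile-class] objects on one grid.
#' @param method correlation dialect, see [concordance()].
#' @return symmetric matrix with unit diagonal, dimnames from cell ids.
#' @export
concordanceMatrix <- function(profiles, method = "pearson") {
    n <- length(profiles)
    m <- diag(1, n)
    ids <- vapply(profiles, function(p) p@cellId, character(1))
    dimnames(m) <- list(ids, ids)
    if (n < 2) return(m)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        m[i, j] <- m[j, i] <- concordance(profiles[[i]], profiles[[j]],
                                          method = method)
    }
    m
}

#' Compare concordance within and between cell groups
#'
#' Splits the off-diagonal concordance entries into within-group-A,
#' within-group-B and cross-group sets, reports their medians, and tests the
#' three pairwise distribution differences by Wilcoxon rank-sum with Holm
#' correction. Degenerate comparisons (all values tied) are reported with
#' p = 1.
#'
#' @param mat concordance matrix from [concordanceMatrix()].
#' @param labels group label per cell (two levels; each group needs >= 2
#'   cells for its within-group set, otherwise that comparison is omitted
#'   with a warning).
#' @return data.frame of comparisons with medians and Holm-adjusted
#'   p-values, plus attribute `medians`.
#' @export
groupConcordanceTest <- function(mat, labels) {
    stopifnot(nrow(mat) == length(labels))
    lv <- unique(labels)
    stopifnot(length(lv) == 2)
    iA <- which(labels == lv[1]); iB <- which(labels == lv[2])
    up <- upper.tri(mat)
    pick <- function(rows, cols) {
        sel <- matrix(FALSE, nrow(mat), ncol(mat))
        sel[rows, cols] <- TRUE; sel[cols, rows] <- TRUE
        mat[sel & up]
    }
    withinA <- if (length(iA) >= 2) pick(iA, iA) else NULL
    withinB <- if (length(iB) >= 2) pick(iB, iB) else NULL
    cross <- pick(iA, iB)
    if (is.null(withinA) || is.null(withinB))
        warning("group with < 2 cells: within-group comparison omitted")
    sets <- list(withinA = withinA, withinB = withinB, cross = cross)
    names(sets) <- c(paste0("within_", lv[1]), paste0("within_", lv[2]),
                     "cross")
    sets <- Filter(Negate(is.null), sets)
    meds <- vapply(sets, stats::median, numeric(1))
    cmps <- utils::combn(names(sets), 2)
    pv <- apply(cmps, 2, function(nm) {
        x <- sets[[nm[1]]]; y <- sets[[nm[2]]]
        if (length(unique(c(x, y))) == 1) return(1)
        stats::wilcox.test(x, y, exact = FALSE)$p.value
    })
    out <- data.frame(comparison = apply(cmps, 2, paste, collapse = " vs "),
                      p.value = pv,
                      p.holm = stats::p.adjust(pv, method = "holm"),
                      stringsAsFactors = FALSE)
    attr(out, "medians") <- meds
    out
}
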