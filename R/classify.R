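#' Background-relative channel positivity thresholds
#'
#' Estimates per-channel background mean and SD from pixels outside the
#' (dilated) cell mask and sets the positivity cutoff on a cell's mean
#' intensity at `background mean + k * background SD`.
#'
#' @param image a [SlideImage-class].
#' @param cellMask binary cell mask; its 3 px dilation is excluded from the
#'   background estimate.
#' @param k number of background SDs above the mean (default 5).
#' @return named numeric vector of per-channel cutoffs.
#' @export
positivityThresholds <- function(image, cellMask, k = 5) {
    stopifnot(is(image, "SlideImage"), k > 0)
    dil <- EBImage::dilate(EBImage::Image(cellMask),
                           EBImage::makeBrush(7, shape = "disc"))
    bg <- EBImage::imageData(dil) == 0
    vapply(channelNames(image), function(ch) {
        v <- channel(image, ch)[bg]
        mean(v) + k * stats::sd(v)
    }, numeric(1))
}

#' Call cell classes from records
#'
#' Exhaustive, mutually exclusive rules on mean cell-mask intensity
#' positivity: DAPI-negative cells are `OTHER`; CD45-positive cells are
#' `WBC` (the exclusion marker dominates); EPI-positive CD45-negative cells
#' are `CTC`; EPI-negative CD45-negative VAR-positive cells are
#' `MARKER_ONLY` (tumor origin cannot be concluded from the variable marker
#' alone); everything else is `OTHER`.
#'
#' @param records cell records from [extractCells()].
#' @param thresholds named per-channel cutoffs (needs `DAPI`, `EPI`, `CD45`;
#'   `VAR` is used when present).
#' @return data.frame of calls: `cell_id`, `class`, `igc` (initialized
#'   FALSE; see [flagIGC()]), and `<channel>_pos` logicals.
#' @export
callCells <- function(records, thresholds) {
    for (ch in c("DAPI", "EPI", "CD45")) {
        if (!ch %in% names(thresholds) ||
            !paste0(ch, "_mean_cell") %in% names(records))
            stop("missing channel: ", ch)
    }
    pos <- function(ch) records[[paste0(ch, "_mean_cell")]] > thresholds[[ch]]
    dapi <- pos("DAPI"); epi <- pos("EPI"); cd45 <- pos("CD45")
    var <- if ("VAR" %in% names(thresholds) &&
               "VAR_mean_cell" %in% names(records)) pos("VAR")
           else rep(FALSE, nrow(records))
    cls <- rep("OTHER", nrow(records))
    cls[dapi & cd45] <- "WBC"
    cls[dapi & !cd45 & epi] <- "CTC"
    cls[dapi & !cd45 & !epi & var] <- "MARKER_ONLY"
    out <- data.frame(cell_id = records$cell_id, class = cls,
                      igc = logical(nrow(records)),
                      DAPI_pos = dapi, EPI_pos = epi, CD45_pos = cd45,
                      VAR_pos = var, stringsAsFactors = FALSE)
    out
}

#' Flag CTC-IGC by the nuclear-diameter doubling rule
#'
#' Within one sample, the reference nuclear diameter is the average over the
#' sample's CTC-class cells (median by default; the mean would be inflated by
#' the very IGC cells being detected). A CTC whose nuclear equivalent
#' diameter is at least `2 * reference` is flagged `igc`; MARKER_ONLY cells
#' meeting the same rule are flagged too but reported separately and never
#' count toward sample positivity. The flag is invariant to uniform scaling
#' of all diameters.
#'
#' @param calls calls from [callCells()].
#' @param records matching records (for `d_nuc_um`).
#' @param reference `"median"` (default) or `"trimmed_mean"` (20% trimmed).
#' @return `calls` with `igc` set and an attribute `d_ref` (reference
#'   diameter, micrometres). With no CTC in the sample a warning is emitted
#'   and no flag is set.
#' @export
flagIGC <- function(calls, records, reference = c("median", "trimmed_mean")) {
    reference <- match.arg(reference)
    stopifnot(nrow(calls) == nrow(records),
              all(calls$cell_id == records$cell_id))
    d <- records$d_nuc_um
    ctc <- calls$class == "CTC"
    if (!any(ctc)) {
        warning("no CTC-class cell in sample; no IGC flag set")
        attr(calls, "d_ref") <- NA_real_
        return(calls)
    }
    dRef <- if (reference == "median") median(d[ctc])
            else mean(d[ctc], trim = 0.2)
    calls$igc <- calls$class %in% c("CTC", "MARKER_ONLY") & d >= 2 * dRef
    attr(calls, "d_ref") <- dRef
    calls
}

#' Sample-level CTC-IGC positivity
#'
#' TRUE iff the sample contains at least one CTC-class cell flagged `igc`.
#' MARKER_ONLY IGC cells do not count (tumor origin unconfirmed).
#'
#' @param calls calls after [flagIGC()].
#' @return logical scalar.
#' @export
samplePositivity <- function(calls) {
    any(calls$class == "CTC" & calls$igc)
}

#' Channel-positivity breakdown of rare cells
#'
#' Percentages of rare cells (DAPI-positive, CD45-negative, EPI- or
#' marker-positive) that are EPI+marker+, marker-only, and EPI+marker-.
#' With `epiRestricted = TRUE` (the LRP1 dialect, whose marker also stains
#' T cells) only EPI-positive cells enter the denominator.
#'
#' @param calls calls from [callCells()].
#' @param markerChannel positivity column prefix of the marker (default
#'   `"VAR"`).
#' @param epiRestricted restrict to EPI-positive cells.
#' @return data.frame with `combination`, `count`, `percent` (a zero-count
#'   all-zero table on empty input).
#' @export
positivityBreakdown <- function(calls, markerChannel = "VAR",
                                epiRestricted = FALSE) {
    mcol <- paste0(markerChannel, "_pos")
    if (!mcol %in% names(calls)) stop("missing channel: ", markerChannel)
    rare <- calls$DAPI_pos & !calls$CD45_pos & (calls$EPI_pos | calls[[mcol]])
    if (epiRestricted) rare <- rare & calls$EPI_pos
    epi <- calls$EPI_pos[rare]; mk <- calls[[mcol]][rare]
    n <- sum(rare)
    counts <- c(`EPI+marker+` = sum(epi & mk),
                `marker_only` = sum(!epi & mk),
                `EPI+marker-` = sum(epi & !mk))
    data.frame(combination = names(counts), count = as.integer(counts),
               percent = if (n > 0) 100 * as.integer(counts) / n else
                   rep(0, 3),
               stringsAsFactors = FALSE)
}

## exact two-sided rank-sum p by enumeration of all group assignments
.exactRankSumP <- function(x, y) {
    n <- length(x) + length(y); nx <- length(x)
    r <- rank(c(x, y))
    wObs <- sum(r[seq_len(nx)])
    mu <- nx * (n + 1) / 2
    combs <- utils::combn(n, nx)
    w <- colSums(matrix(r[combs], nrow = nx))
    mean(abs(w - mu) >= abs(wObs - mu) - 1e-9)
}

#' Compare morphometry between two groups (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test on, e.g., nuclear diameters. For small
#' samples (combined n <= 20) the p-value is computed by exact enumeration of
#' all group assignments of the (possibly tied) ranks; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param groupA,groupB numeric vectors (each non-empty).
#' @return list with `statistic` (rank-sum W of group A), `p.value`,
#'   `method`.
#' @export
compareMorphometry <- function(groupA, groupB) {
    if (length(groupA) == 0 || length(groupB) == 0)
        stop("both groups must be non-empty")
    n <- length(groupA) + length(groupB)
    r <- rank(c(groupA, groupB))
    w <- sum(r[seq_along(groupA)])
    if (n <= 20) {
        p <- .exactRankSumP(groupA, groupB)
        method <- "exact enumeration"
    } else {
        nx <- length(groupA); ny <- length(groupB)
        mu <- nx * (n + 1) / 2
        ties <- table(r)
        sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
        z <- (w - mu) / sqrt(sig2)
        p <- if (sig2 == 0) 1 else 2 * stats::pnorm(-abs(z))
        method <- "normal approximation with tie correction"
    }
    list(statistic = w, p.value = min(p, 1), method = method)
}

#' Select the largest cells by equivalent diameter
#'
#' Records whose cell equivalent diameter is at or above the
#' `(1 - fraction)` quantile (type-1 empirical quantile); ties at the cutoff
#' are all included, mirroring gate-style size sorting (e.g. keeping the
#' largest 15%).
#'
#' @param records cell records with `d_cell_um`.
#' @param fraction fraction to keep, in (0, 1].
#' @return subset of `records`.
#' @export
selectLargestFraction <- function(records, fraction = 0.15) {
    stopifnot(fraction > 0, fraction <= 1)
    if (nrow(records) == 0) return(records)
    k <- ceiling(fraction * nrow(records) - 1e-9)
    cut <- sort(records$d_cell_um, decreasing = TRUE)[k]
    records[records$d_cell_um >= cut, , drop = FALSE]
}
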