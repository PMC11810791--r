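#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator with Greenwood standard errors. Ties at
#' an event time are handled by the simultaneous-death convention; a
#' censoring tied with an event time is placed after the event (the censored
#' subject remains at risk for that event).
#'
#' @param time follow-up times (>= 0).
#' @param event 1 = progressed / event, 0 = censored.
#' @return data.frame with one row per distinct event time: `time`,
#'   `nRisk`, `nEvent`, `surv`, `se` (Greenwood). `S(0) = 1` is implicit;
#'   with no events the estimate is identically 1 (zero rows).
#' @examples
#' kmEstimate(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
#' @export
kmEstimate <- function(time, event) {
    stopifnot(length(time) == length(event), all(time >= 0),
              length(time) >= 1)
    et <- sort(unique(time[event == 1]))
    surv <- 1; out <- NULL; varsum <- 0
    for (t in et) {
        nRisk <- sum(time >= t)
        nEvent <- sum(time == t & event == 1)
        surv <- surv * (1 - nEvent / nRisk)
        if (nRisk > nEvent)
            varsum <- varsum + nEvent / (nRisk * (nRisk - nEvent))
        se <- surv * sqrt(varsum)
        out <- rbind(out, data.frame(time = t, nRisk = nRisk,
                                     nEvent = nEvent, surv = surv, se = se))
    }
    if (is.null(out))
        out <- data.frame(time = numeric(0), nRisk = integer(0),
                          nEvent = integer(0), surv = numeric(0),
                          se = numeric(0))
    out
}

#' Per-group Kaplan-Meier curves from a cohort table
#'
#' @param cohort data.frame with time, event and group columns.
#' @param timeCol,eventCol,groupCol column names.
#' @return named list of [kmEstimate()] data.frames, one per group level.
#' @export
kmByGroup <- function(cohort, timeCol = "time_months", eventCol = "event",
                      groupCol = "group") {
    gs <- unique(cohort[[groupCol]])
    out <- lapply(gs, function(g) {
        sel <- cohort[[groupCol]] == g
        if (!any(sel)) stop("empty group: ", g)
        kmEstimate(cohort[[timeCol]][sel], cohort[[eventCol]][sel])
    })
    names(out) <- as.character(gs)
    out
}

#' Two-group log-rank test
#'
#' Standard log-rank: at every distinct event time the observed events in
#' group 1 are compared with their hypergeometric expectation; the chi-square
#' statistic is `(O1 - E1)^2 / V` on 1 degree of freedom.
#'
#' @param time follow-up times.
#' @param event 1 = event, 0 = censored (at least one event overall).
#' @param group two-level group labels (both non-empty).
#' @return list with `statistic`, `p.value`, `observed`, `expected` (per
#'   group).
#' @export
logrankTest <- function(time, event, group) {
    g <- as.factor(group)
    if (nlevels(g) != 2) stop("exactly two groups required")
    if (any(table(g) == 0)) stop("empty group")
    if (sum(event) == 0) stop("no events")
    et <- sort(unique(time[event == 1]))
    O1 <- E1 <- V <- 0
    g1 <- g == levels(g)[1]
    for (t in et) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    stat <- if (V > 0) (O1 - E1)^2 / V else 0
    p <- if (V > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
    O <- c(O1, sum(event) - O1); E <- c(E1, sum(event) - E1)
    names(O) <- names(E) <- levels(g)
    list(statistic = stat, p.value = p, observed = O, expected = E)
}

#' Median split of an expression column
#'
#' Utility for marker-based survival grouping: labels values at or above the
#' median `"high"`, below `"low"`.
#'
#' @param x numeric vector.
#' @return factor with levels `low`, `high`.
#' @export
medianSplit <- function(x) {
    factor(ifelse(x >= stats::median(x), "high", "low"),
           levels = c("low", "high"))
}
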