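test_that("class calls follow the marker hierarchy", {
    rec <- recordsFromIntensity(
        dapi = c(5000, 5000, 5000, 5000, 200, 5000),
        epi  = c(5000,    0, 5000,    0, 5000,    0),
        cd45 = c(   0, 5000, 5000,    0,    0,    0),
        var  = c(   0,    0,    0, 5000,    0,    0))
    calls <- callCells(rec, fixedThresholds)
    expect_equal(calls$class,
                 c("CTC", "WBC", "WBC", "MARKER_ONLY", "OTHER", "OTHER"))
    ## classes partition the records
    expect_equal(sum(table(calls$class)), nrow(rec))
})

test_that("a missing channel is reported by name", {
    rec <- recordsFromIntensity(dapi = 5000, epi = 5000, cd45 = 0)
    expect_error(callCells(rec, c(DAPI = 1000, EPI = 1000)),
                 "missing channel: CD45")
})

test_that("the doubling rule flags only cells at twice the CTC median", {
    rec <- recordsFromIntensity(dapi = rep(5000, 4), epi = rep(5000, 4),
                                cd45 = rep(0, 4),
                                dnuc = c(10, 10, 10, 25))
    calls <- flagIGC(callCells(rec, fixedThresholds), rec)
    expect_equal(attr(calls, "d_ref"), 10)
    expect_equal(which(calls$igc), 4L)
    ## all equal diameters: nothing flagged
    rec2 <- recordsFromIntensity(dapi = rep(5000, 4), epi = rep(5000, 4),
                                 cd45 = rep(0, 4), dnuc = rep(12, 4))
    calls2 <- flagIGC(callCells(rec2, fixedThresholds), rec2)
    expect_false(any(calls2$igc))
})

test_that("IGC flagging is invariant to uniform diameter scaling", {
    set.seed(31)
    d <- c(rnorm(20, 12, 0.5), rnorm(3, 28, 1))
    rec <- recordsFromIntensity(dapi = rep(5000, 23), epi = rep(5000, 23),
                                cd45 = rep(0, 23), dnuc = d)
    f1 <- flagIGC(callCells(rec, fixedThresholds), rec)$igc
    for (c in c(0.1, 3, 40)) {
        rec2 <- rec; rec2$d_nuc_um <- d * c
        f2 <- flagIGC(callCells(rec2, fixedThresholds), rec2)$igc
        expect_identical(f2, f1)
    }
})

test_that("samples without CTCs warn and never become positive", {
    rec <- recordsFromIntensity(dapi = 5000, epi = 0, cd45 = 5000)
    expect_warning(calls <- flagIGC(callCells(rec, fixedThresholds), rec),
                   "no CTC")
    expect_false(samplePositivity(calls))
})

test_that("sample positivity requires a flagged CTC, not a MARKER_ONLY cell", {
    rec <- recordsFromIntensity(dapi = rep(5000, 3), epi = c(5000, 5000, 0),
                                cd45 = rep(0, 3), var = c(0, 0, 5000),
                                dnuc = c(10, 10, 30))
    calls <- flagIGC(callCells(rec, fixedThresholds), rec)
    expect_equal(calls$class[3], "MARKER_ONLY")
    expect_true(calls$igc[3])
    expect_false(samplePositivity(calls))   # MARKER_ONLY IGC excluded
    rec2 <- recordsFromIntensity(dapi = rep(5000, 3), epi = rep(5000, 3),
                                 cd45 = rep(0, 3), dnuc = c(10, 10, 30))
    calls2 <- flagIGC(callCells(rec2, fixedThresholds), rec2)
    expect_true(samplePositivity(calls2))
})

test_that("positivity breakdown recovers planted channel combinations", {
    ## 50% EPI+marker+, 25% marker-only, 25% EPI+marker-
    n <- 40
    rec <- recordsFromIntensity(
        dapi = rep(5000, n),
        epi = c(rep(5000, 20), rep(0, 10), rep(5000, 10)),
        cd45 = rep(0, n),
        var = c(rep(5000, 20), rep(5000, 10), rep(0, 10)))
    calls <- callCells(rec, fixedThresholds)
    bd <- positivityBreakdown(calls, "VAR")
    expect_equal(bd$percent, c(50, 25, 25))
    ## the EPI-restricted dialect drops the marker-only bar
    bdR <- positivityBreakdown(calls, "VAR", epiRestricted = TRUE)
    expect_equal(bdR$count[bdR$combination == "marker_only"], 0)
    expect_equal(sum(bdR$count), 30)
    ## all-positive and empty cases
    allPos <- callCells(recordsFromIntensity(dapi = rep(5000, 5),
                                             epi = rep(5000, 5),
                                             cd45 = rep(0, 5),
                                             var = rep(5000, 5)),
                        fixedThresholds)
    expect_equal(positivityBreakdown(allPos, "VAR")$percent, c(100, 0, 0))
    none <- callCells(recordsFromIntensity(dapi = numeric(0), epi = numeric(0),
                                           cd45 = numeric(0)),
                      fixedThresholds)
    expect_equal(positivityBreakdown(none, "VAR")$percent, c(0, 0, 0))
    expect_equal(sum(positivityBreakdown(none, "VAR")$count), 0)
})

test_that("rank-sum comparison matches exact enumeration on small groups", {
    ## smallest attainable two-sided p at 3 vs 3 is 2/20
    res <- compareMorphometry(c(1, 2, 3), c(10, 11, 12))
    expect_equal(res$p.value, 0.1)
    ## permutation-symmetric configuration: p = 1
    expect_equal(compareMorphometry(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
    expect_error(compareMorphometry(numeric(0), 1:3), "non-empty")
})

test_that("large-sample rank-sum agrees with the reference implementation", {
    set.seed(5)
    a <- rnorm(40, 10); b <- rnorm(35, 10.5)
    ours <- compareMorphometry(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("planted IGC-sized groups are separated at p < 0.01", {
    set.seed(77)
    ctrl <- rnorm(50, 12, 1.5)
    igc <- rnorm(50, 24, 3)
    expect_lt(compareMorphometry(ctrl, igc)$p.value, 0.01)
})

test_that("largest-fraction selection honors quantile and tie rules", {
    rec <- data.frame(cell_id = 1:100, d_cell_um = seq_len(100))
    expect_equal(nrow(selectLargestFraction(rec, 1)), 100)
    top <- selectLargestFraction(rec, 0.15)
    expect_equal(nrow(top), 15)
    expect_equal(sort(top$d_cell_um), 86:100)
    tied <- data.frame(cell_id = 1:30, d_cell_um = rep(7, 30))
    expect_equal(nrow(selectLargestFraction(tied, 0.15)), 30)
})
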