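test_that("adaptive threshold on a constant image is empty for positive offset", {
    img <- matrix(500, 100, 100)
    expect_equal(sum(segmentChannel(img, offset = 1, minArea = 0,
                                    openRadius = 0)), 0)
})

test_that("even block sizes are rejected", {
    expect_error(segmentChannel(matrix(0, 10, 10), blockSize = 50), "odd")
})

test_that("a bright disk is recovered with about its true area", {
    img <- matrix(100, 120, 120)
    xs <- row(img); ys <- col(img)
    img[(xs - 60)^2 + (ys - 60)^2 <= 7.5^2] <- 1000
    mask <- segmentChannel(img, blockSize = 51, offset = 100, minArea = 20)
    expect_lt(abs(sum(mask) - pi * 7.5^2) / (pi * 7.5^2), 0.10)
})

test_that("decreasing the offset never shrinks the foreground", {
    set.seed(8)
    img <- matrix(500 + rnorm(100 * 100, 0, 30), 100, 100)
    img[30:50, 30:50] <- img[30:50, 30:50] + 800
    m1 <- segmentChannel(img, offset = 200, minArea = 0, openRadius = 0)
    m2 <- segmentChannel(img, offset = 50, minArea = 0, openRadius = 0)
    expect_true(all(m2[m1 > 0] > 0))
})

test_that("segmentation is translation-equivariant away from borders", {
    img <- matrix(100, 140, 140)
    xs <- row(img); ys <- col(img)
    img[(xs - 60)^2 + (ys - 60)^2 <= 8^2] <- 2000
    shift <- 15
    img2 <- matrix(100, 140, 140)
    img2[(xs - 60 - shift)^2 + (ys - 60)^2 <= 8^2] <- 2000
    m1 <- segmentChannel(img, offset = 500)
    m2 <- segmentChannel(img2, offset = 500)
    core <- 40:100
    expect_identical(m1[core, core], m2[core + shift, core])
})

test_that("mask union behaves as set union", {
    a <- matrix(0, 40, 40); a[5:10, 5:10] <- 1
    b <- matrix(0, 40, 40); b[25:30, 25:30] <- 1
    empty <- matrix(0, 40, 40)
    expect_identical(mergeMasks(list(a, empty)), a)
    u <- mergeMasks(list(a, b))
    lab <- EBImage::bwlabel(u)
    expect_equal(max(lab), 2)
    expect_error(mergeMasks(list(a, matrix(0, 10, 10))), "mismatch")
})

test_that("equivalent diameter follows the circular-area formula", {
    expect_equal(equivalentDiameter(0), 0)
    expect_equal(equivalentDiameter(pi * 100, 1), 20)
    expect_equal(equivalentDiameter(100, 1), 11.28379, tolerance = 1e-5)
    expect_equal(equivalentDiameter(100, 0.5), 11.28379 / 2, tolerance = 1e-5)
    expect_error(equivalentDiameter(-1), "non-negative")
})

test_that("extractCells reports nuclear diameter from the DAPI intersection", {
    cellMask <- matrix(0, 80, 80)
    xs <- row(cellMask); ys <- col(cellMask)
    cellMask[(xs - 40)^2 + (ys - 40)^2 <= 15^2] <- 1
    dapiMask <- matrix(0, 80, 80)
    dapiMask[(xs - 40)^2 + (ys - 40)^2 <= 7.5^2] <- 1
    img <- SlideImage(list(DAPI = matrix(10, 80, 80)), pixelSize = 1)
    rec <- extractCells(cellMask, dapiMask, img)
    expect_equal(nrow(rec), 1)
    expect_equal(rec$d_nuc_um, 15, tolerance = 0.5 / 15)
    expect_lte(rec$area_nuc_px, rec$area_cell_px)
    expect_false(rec$anucleate)
})

test_that("empty masks yield an empty record table", {
    img <- SlideImage(list(DAPI = matrix(0, 30, 30)), pixelSize = 1)
    rec <- extractCells(matrix(0, 30, 30), matrix(0, 30, 30), img)
    expect_equal(nrow(rec), 0)
    expect_true(all(c("d_nuc_um", "anucleate") %in% names(rec)))
})

test_that("anucleate cells are flagged with zero nuclear diameter", {
    cellMask <- matrix(0, 40, 40); cellMask[10:20, 10:20] <- 1
    img <- SlideImage(list(DAPI = matrix(0, 40, 40)), pixelSize = 1)
    rec <- extractCells(cellMask, matrix(0, 40, 40), img)
    expect_true(rec$anucleate)
    expect_equal(rec$d_nuc_um, 0)
})

test_that("rendered slides are segmented into exactly the planted cells", {
    sp <- tinyCTCSpec(seed = 19, nCTC = 4, nIGC = 1, noiseSd = 25, size = 300)
    out <- renderSlide(sp)
    seg <- segmentSlide(out$image, offset = 2600, minArea = 20)
    expect_equal(nrow(seg$records), nrow(out$truth))
    ## every ground-truth centroid is covered by the cell mask
    cov <- mapply(function(x, y) seg$cellMask[round(x), round(y)] > 0,
                  out$truth$x, out$truth$y)
    expect_true(all(cov))
})

test_that("planted nuclear diameters are recovered within 1 px at low noise", {
    ## noise at 5% of the DAPI signal
    for (seed in c(1, 2)) {
        sp <- tinyCTCSpec(seed = seed, nCTC = 4, nIGC = 1,
                          noiseSd = 0.05 * 8000, size = 300)
        out <- renderSlide(sp)
        seg <- segmentSlide(out$image, offset = 2600, minArea = 20)
        expect_equal(nrow(seg$records), nrow(out$truth))
        d <- as.matrix(dist(rbind(cbind(out$truth$x, out$truth$y),
                                  cbind(seg$records$x, seg$records$y))))
        n1 <- nrow(out$truth)
        idx <- apply(d[seq_len(n1), -seq_len(n1), drop = FALSE], 1, which.min)
        err <- seg$records$d_nuc_um[idx] - out$truth$nuc_diam_um
        expect_lt(max(abs(err)), 1)
    }
})

test_that("slide TIFF round trip preserves channels and intensities", {
    sp <- tinyCTCSpec(seed = 23, nCTC = 2, size = 120)
    img <- renderSlide(sp)$image
    path <- tempfile(fileext = ".tiff")
    writeSlideTIFF(img, path)
    back <- readSlideTIFF(path, pixelSize = pixelSize(img))
    expect_equal(channelNames(back), channelNames(img))
    ## 16-bit quantization: within one intensity step
    expect_lt(max(abs(channel(back, "DAPI") - channel(img, "DAPI"))), 1.01)
    unlink(path)
})

test_that("cell record CSV round trip keeps the documented column order", {
    sp <- tinyCTCSpec(seed = 29, nCTC = 2, size = 200)
    out <- renderSlide(sp)
    rec <- segmentSlide(out$image, offset = 2600, minArea = 20)$records
    path <- tempfile(fileext = ".csv")
    writeCellRecords(rec, path)
    back <- readCellRecords(path)
    expect_identical(names(back), names(rec))
    expect_equal(back$d_nuc_um, rec$d_nuc_um)
    unlink(path)
})
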