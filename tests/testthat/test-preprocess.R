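test_that("grayscale conversion uses luminance weights and fixes gray points", {
    # already grayscale -> unchanged
    g <- ECGImage(matrix(c(0, 100, 200, 255), 2, 2), dpi = 300)
    expect_identical(toGrayscale(g), g)

    # uniform RGB (200,200,200) -> uniform 200
    a <- array(200, c(3, 3, 3))
    expect_true(all(imageData(toGrayscale(ECGImage(a, dpi = 300))) == 200))

    # green maps brighter than red under the chosen luminance weights
    rgb <- array(0, c(1, 2, 3))
    rgb[1, 1, 1] <- 255   # pure red
    rgb[1, 2, 2] <- 255   # pure green
    lum <- imageData(toGrayscale(ECGImage(rgb, dpi = 300)))
    expect_equal(as.vector(lum), c(round(0.299 * 255), round(0.587 * 255)))
    expect_gt(lum[1, 2], lum[1, 1])
})

test_that("downscaling follows the dpi ratio and refuses upscaling", {
    img <- ECGImage(matrix(128, 240, 300), dpi = 600)
    half <- downscaleToDpi(img, 300)
    expect_equal(dim(imageData(half)), c(120, 150))
    expect_equal(imageDpi(half), 300)

    expect_identical(downscaleToDpi(img, 600), img)

    img45 <- ECGImage(matrix(128, 45, 45), dpi = 450)
    expect_equal(dim(imageData(downscaleToDpi(img45, 300))), c(30, 30))

    expect_warning(out <- downscaleToDpi(img, 1200), "upscal")
    expect_identical(out, img)
})

test_that("skew estimation recovers rendered angles and rejects gridless input", {
    # axis-aligned grid
    rec0 <- smallRecord(nRows = 1, beats = 2, seed = 1)
    expect_lt(abs(skewAngle(estimateSkew(rec0$image))), 0.1)

    # rendered skew recovered within the documented band
    recP <- smallRecord(nRows = 1, beats = 2, seed = 1, skew = 2)
    expect_true(abs(skewAngle(estimateSkew(recP$image)) - 2) <= 0.2)
    recN <- smallRecord(nRows = 1, beats = 2, seed = 1, skew = -5)
    expect_true(abs(skewAngle(estimateSkew(recN$image)) + 5) <= 0.2)

    # blank page: no grid to vote with
    blank <- ECGImage(matrix(240, 400, 400), dpi = 300)
    expect_error(estimateSkew(blank), "no grid")
})

test_that("deskew is an identity at zero and undoes a rendered rotation", {
    img <- smallRecord(nRows = 1, beats = 1, seed = 2)$image
    expect_identical(imageData(deskew(img, 0)), imageData(img))

    rec <- smallRecord(nRows = 1, beats = 2, seed = 2, skew = 3)
    fixed <- deskew(rec$image, estimateSkew(rec$image))
    expect_lt(abs(skewAngle(estimateSkew(fixed))), 0.2)

    # grid pitch survives the rotate + deskew round trip within 1%
    ref <- smallRecord(nRows = 1, beats = 2, seed = 2)
    p0 <- measureGridPitch(ref$image)
    p1 <- measureGridPitch(fixed)
    expect_lt(abs(p1 - p0) / p0, 0.01)
})

test_that("region partition respects template boundaries and tiles the canvas", {
    rec <- smallRecord(nRows = 2, beats = 1, seed = 3,
        demographics = list(name = "AB"), demographicFields = "name")
    parts <- partitionRegions(rec$image, rec$template)
    tpl <- rec$template
    expect_equal(dim(imageData(parts$waveform)),
        c(tpl@waveformRegion[3] - tpl@waveformRegion[1] + 1L,
          tpl@waveformRegion[4] - tpl@waveformRegion[2] + 1L))
    # glyphs land in the demographic crop, traces in the waveform crop
    gl <- rec$manifest@glyphs
    demoGlyphs <- gl[is.na(gl$row), ]
    expect_true(all(demoGlyphs$bottom <= tpl@demographicRegion[3]))
    expect_true(all(rec$manifest@idealMask[, 1] >= tpl@waveformRegion[1]))

    # degenerate split: zero-height demographic region
    tpl0 <- tpl
    tpl0@demographicRegion <- c(1L, 1L, 0L, tpl@canvas[2])
    parts0 <- partitionRegions(rec$image, tpl0)
    expect_null(parts0$demographic)

    # a full-canvas two-region template reconstructs the image by stacking
    tplFull <- tpl
    tplFull@demographicRegion <- c(1L, 1L, 100L, tpl@canvas[2])
    tplFull@waveformRegion <- c(101L, 1L, tpl@canvas[1], tpl@canvas[2])
    pf <- partitionRegions(rec$image, tplFull)
    expect_identical(rbind(imageData(pf$demographic), imageData(pf$waveform)),
        imageData(rec$image))

    # out-of-bounds template is refused
    tplBad <- tpl
    tplBad@waveformRegion[4] <- tpl@canvas[2] + 50L
    expect_error(partitionRegions(rec$image, tplBad), "template error")
})

test_that("histogram valley thresholding separates ink from grid and paper", {
    set.seed(7)
    # bimodal: ink at 20, background at 230
    bi <- matrix(230, 200, 200)
    bi[sample(length(bi), 2000)] <- 20
    thr <- autoThreshold(ECGImage(bi, dpi = 300))
    expect_gt(as.numeric(thr), 20)
    expect_lt(as.numeric(thr), 230)

    # all-background page has nothing to threshold
    expect_error(autoThreshold(ECGImage(matrix(240, 100, 100), dpi = 300)),
        "no trace")

    # trimodal: ink 20 / grid 150 / paper 240; the mask keeps ink only
    tri <- matrix(240, 300, 300)
    gridIdx <- sample(length(tri), 9000)
    tri[gridIdx] <- 150
    inkIdx <- sample(setdiff(seq_along(tri), gridIdx), 3000)
    tri[inkIdx] <- 20
    img <- ECGImage(tri, dpi = 300)
    thr3 <- autoThreshold(img)
    mask <- maskData(binarize(img, thr3))
    expect_lt(abs(sum(mask) - 3000) / 3000, 0.01)
})

test_that("binarization is polarity- and threshold-faithful", {
    rec <- smallRecord(nRows = 1, beats = 1, seed = 5)
    img <- rec$image
    expect_equal(sum(maskData(binarize(img, 0))), 0)
    expect_equal(sum(maskData(binarize(img, 256))),
        length(imageData(img)))

    # at the oracle threshold, grid pixels (intensity 150) stay out
    mask <- maskData(binarize(img, 100))
    gridOnly <- imageData(img) > 100 & imageData(img) < 240
    expect_equal(sum(mask & gridOnly), 0)

    # monotonicity: lowering the threshold never grows the mask
    sizes <- vapply(c(200, 150, 100, 50, 25),
        function(t) sum(maskData(binarize(img, t))), 0)
    expect_true(all(diff(sizes) <= 0))
})

test_that("the 3x3 majority filter removes salt and keeps solid blocks", {
    m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
    expect_equal(sum(maskData(medianFilterMask(BinaryMask(m)))), 0)

    solid <- matrix(FALSE, 9, 9); solid[3:7, 3:7] <- TRUE
    out <- maskData(medianFilterMask(BinaryMask(solid)))
    expect_true(all(out[4:6, 4:6]))

    # on a noisy record: most noise specks removed, trace mostly intact
    rec <- smallRecord(nRows = 1, beats = 2, seed = 9, sp = 0.02, drift = 0)
    thr <- autoThreshold(rec$image)
    noisy <- binarize(rec$image, thr)
    filtered <- medianFilterMask(noisy)
    ideal <- maskData(idealTraceMask(rec$manifest))
    noise <- maskData(noisy) & !ideal
    # noise pixels include grid-crossing residue; pure salt dominates
    expect_gt(1 - sum(maskData(filtered) & noise) / sum(noise), 0.95)
    traceKept <- sum(maskData(filtered) & ideal) / sum(maskData(noisy) & ideal)
    expect_gt(traceKept, 0.98)
})

test_that("gap bridging is extensive, idempotent, and closes sub-kernel gaps", {
    line <- matrix(FALSE, 5, 30)
    line[3, c(5:12, 14:20)] <- TRUE   # one 1-px gap
    b <- bridgeGaps(BinaryMask(line), 3L)
    expect_true(maskData(b)[3, 13])
    expect_true(all(maskData(b)[line]))          # extensive

    nogap <- BinaryMask(matrix(TRUE, 4, 4))
    expect_equal(maskData(bridgeGaps(nogap, 5L)), matrix(TRUE, 4, 4))

    # idempotent at fixed kernel
    b2 <- bridgeGaps(b, 3L)
    expect_identical(maskData(b2), maskData(b))

    expect_error(bridgeGaps(nogap, 4L), "odd")

    # 20 small gaps in a row, kernel 5: the row becomes one component
    set.seed(21)
    gapStarts <- sort(sample(seq(10, 380, by = 15), 20))
    gaps <- unlist(lapply(gapStarts, function(s) s + 0:2))  # 3-px gaps
    m <- gappedRowsMask(nRows = 1, width = 400, gapCols = list(gaps))
    before <- nComponents(labelComponents(BinaryMask(m), 8L))
    expect_gt(before, 1)
    bridged <- bridgeGaps(BinaryMask(m), 5L)
    expect_equal(nComponents(labelComponents(bridged, 8L)), 1L)
})

test_that("full preprocessing matches the ideal trace mask on a clean record", {
    rec <- smallRecord(nRows = 2, beats = 2, seed = 13, drift = 0)
    thr <- autoThreshold(rec$image)
    mask <- bridgeGaps(medianFilterMask(binarize(rec$image, thr)), 5L)
    ideal <- maskData(idealTraceMask(rec$manifest))
    got <- maskData(mask)
    jaccard <- sum(got & ideal) / sum(got | ideal)
    expect_gte(jaccard, 0.9)
})
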