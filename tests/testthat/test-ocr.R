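test_that("glyph library construction, self-matching and serialization", {
    lib1 <- buildGlyphLibrary(list(list(bitmap = renderGlyph("V"),
        char = "V")))
    rec <- recognizeText(BinaryMask(renderGlyph("V")), lib = lib1,
        minScore = 0.5)
    expect_equal(recognizedText(rec), "V")
    expect_equal(recognitionBoxes(rec)$score, 1, tolerance = 1e-9)

    expect_error(buildGlyphLibrary(list(list(bitmap = renderGlyph("V"),
        char = ""))), "unlabeled")

    # save -> load round trip preserves recognition output exactly
    lib <- defaultGlyphLibrary(2L, characters = c("A", "B", "V", "1", "7"))
    dir <- tempfile()
    saveGlyphLibrary(lib, dir)
    lib2 <- loadGlyphLibrary(dir)
    expect_setequal(glyphCharacters(lib2), glyphCharacters(lib))
    probe <- BinaryMask(renderText("BA7", 2L))
    expect_identical(recognitionBoxes(recognizeText(probe, lib = lib,
        minScore = 0.6)),
        recognitionBoxes(recognizeText(probe, lib = lib2, minScore = 0.6)))
    unlink(dir, recursive = TRUE)

    # two exemplars of the same character: best-match score never drops
    shifted <- matrix(FALSE, 23, 17)
    shifted[2:22, 2:16] <- renderGlyph("V")
    lib3 <- buildGlyphLibrary(list(
        list(bitmap = renderGlyph("V"), char = "V"),
        list(bitmap = shifted, char = "V")))
    expect_equal(length(glyphExemplars(lib3, "V")), 2L)
    s1 <- recognitionBoxes(recognizeText(probe, lib = lib1, minScore = 0.3))
    s3 <- recognitionBoxes(recognizeText(probe, lib = lib3, minScore = 0.3))
    if (nrow(s1) && nrow(s3))
        expect_gte(max(s3$score), max(s1$score))
})

test_that("morphological opening agrees with the brute-force erode-dilate oracle", {
    expect_equal(sum(maskData(skeletonizeForOcr(
        BinaryMask(matrix(FALSE, 8, 8))))), 0)

    solid <- matrix(FALSE, 12, 12); solid[2:11, 2:11] <- TRUE
    opened <- maskData(skeletonizeForOcr(BinaryMask(solid)))
    expect_identical(opened, bruteOpen(solid))
    expect_true(all(opened[3:10, 3:10]))

    # glyph with 1-px protrusions: protrusions removed, oracle pixel-exact
    g <- matrix(FALSE, 15, 15)
    g[4:12, 4:9] <- TRUE
    g[8, 12] <- TRUE           # lone burr
    g[2, 5] <- TRUE            # burr above the stroke
    out <- maskData(skeletonizeForOcr(BinaryMask(g)))
    expect_identical(out, bruteOpen(g))
    expect_false(out[8, 12]); expect_false(out[2, 5])

    set.seed(31)
    for (i in 1:5) {
        m <- matrix(runif(20 * 20) < 0.45, 20, 20)
        expect_identical(maskData(skeletonizeForOcr(BinaryMask(m))),
            bruteOpen(m))
    }
})

test_that("recognition reads rendered strings, stays silent on blanks, and is translation-covariant", {
    lib <- defaultGlyphLibrary(3L)
    expect_equal(recognizedText(recognizeText(
        BinaryMask(matrix(FALSE, 40, 120)), lib = lib, minScore = 0.6)), "")

    canvas <- matrix(FALSE, 60, 260)
    txt <- renderText("AV27", 3L)
    canvas[10 + seq_len(nrow(txt)), 20 + seq_len(ncol(txt))] <- txt
    r1 <- recognizeText(BinaryMask(canvas), lib = lib, minScore = 0.6)
    expect_equal(recognizedText(r1), "AV27")

    # shift content by (7, 31): same text, boxes shifted by exactly (7, 31)
    canvas2 <- matrix(FALSE, 60, 260)
    canvas2[17 + seq_len(nrow(txt)), 51 + seq_len(ncol(txt))] <- txt
    r2 <- recognizeText(BinaryMask(canvas2), lib = lib, minScore = 0.6)
    expect_equal(recognizedText(r2), "AV27")
    expect_equal(recognitionBoxes(r2)$top, recognitionBoxes(r1)$top + 7)
    expect_equal(recognitionBoxes(r2)$left, recognitionBoxes(r1)$left + 31)

    expect_error(recognizeText(BinaryMask(canvas), lib = "x"), "library")

    # every reported score clears the threshold: no guesses below it
    expect_true(all(recognitionBoxes(r1)$score >= 0.6))
})

test_that("a 40-glyph demographic block is read nearly perfectly on a clean render", {
    lib <- defaultGlyphLibrary(3L)
    lines <- c("PATIENT 0123456789", "ABCDEFGHIJKLM 98765", "WXYZ 401")
    total <- 0L; correct <- 0L
    for (s in lines) {
        bmp <- renderText(s, 3L)
        canvas <- matrix(FALSE, nrow(bmp) + 12, ncol(bmp) + 12)
        canvas[6 + seq_len(nrow(bmp)), 6 + seq_len(ncol(bmp))] <- bmp
        got <- recognizedText(recognizeText(BinaryMask(canvas), lib = lib,
            minScore = 0.6))
        want <- gsub(" ", "", s)
        total <- total + nchar(want)
        correct <- correct + sum(strsplit(got, "")[[1]][seq_len(nchar(want))] ==
            strsplit(want, "")[[1]], na.rm = TRUE)
    }
    expect_gte(total, 40L)
    expect_gte(correct / total, 38 / 40)
})

test_that("ROI realignment recovers integer offsets and flags mismatches", {
    rec <- smallRecord(nRows = 1, beats = 2, seed = 7)
    img <- rec$image
    rois <- data.frame(name = "X", top = 50L, left = 60L, bottom = 90L,
        right = 160L)

    same <- alignRois(img, img, rois)
    expect_equal(attr(same, "offset"), c(0L, 0L))
    expect_equal(same$top, 50L)

    # translate the scan by (+7, -3) with background padding
    d <- imageData(img)
    shifted <- matrix(240, nrow(d), ncol(d))
    shifted[8:nrow(d), 1:(ncol(d) - 3)] <- d[1:(nrow(d) - 7), 4:ncol(d)]
    out <- alignRois(ECGImage(shifted, dpi = 300), img, rois)
    expect_equal(attr(out, "offset"), c(7L, -3L))
    expect_equal(out$top, 57L); expect_equal(out$left, 57L)

    # an ROI pushed outside the canvas is clamped with a warning
    roisEdge <- data.frame(name = "E", top = 2L, left = 10L, bottom = 40L,
        right = 60L)
    expect_warning(clamped <- alignRois(img, ECGImage(shifted, dpi = 300),
        roisEdge), "clamped")
    expect_gte(clamped$top[1], 1L)

    # white noise does not correlate with the record above the floor
    set.seed(3)
    noise <- ECGImage(matrix(runif(length(d), 0, 255), nrow(d), ncol(d)),
        dpi = 300)
    expect_error(alignRois(noise, img, rois), "template mismatch")
})

test_that("lead-character removal erases glyph footprints but never trace-only pixels", {
    # overlapping label (printed on the baseline)
    recO <- smallRecord(nRows = 1, beats = 2, seed = 9, drift = 0,
        labels = data.frame(text = "aVL", row = 1, colOffset = 300,
            overlap = TRUE))
    man <- recO$manifest
    thr <- autoThreshold(recO$image)
    mask <- binarize(recO$image, thr)
    lib <- defaultGlyphLibrary(3L)
    out <- removeLeadCharacters(mask, recO$template@leadRois, lib,
        minScore = 0.6)

    # never adds pixels; erased set within the glyph footprint pixels
    expect_true(all(maskData(out$mask) <= maskData(mask)))
    erased <- maskData(mask) & !maskData(out$mask)
    glyphSet <- matrix(FALSE, man@canvas[1], man@canvas[2])
    glyphSet[man@glyphPixels] <- TRUE
    expect_true(all(glyphSet[which(erased, arr.ind = TRUE)]))

    # all glyph ink inside the lead ROI is gone
    roi <- recO$template@leadRois[1, ]
    inRoi <- man@glyphPixels[, 1] >= roi$top & man@glyphPixels[, 1] <= roi$bottom &
             man@glyphPixels[, 2] >= roi$left & man@glyphPixels[, 2] <= roi$right
    expect_equal(sum(maskData(out$mask)[man@glyphPixels[inRoi, , drop = FALSE]]), 0)

    # the reported erased span is no wider than the label box
    sp <- out$erasedSpans[["aVL"]]
    expect_lte(sp[2] - sp[1] + 1,
        man@glyphs$right[1] - man@glyphs$left[1] + 1 + 8)

    # separated label (Fig-style non-overlap): trace pixels untouched
    # placed over the quiet segment after the T wave so it truly clears
    # the trace (an R peak reaches about as high as the label band)
    recS <- smallRecord(nRows = 1, beats = 2, seed = 9, drift = 0,
        labels = data.frame(text = "II", row = 1, colOffset = 180,
            overlap = FALSE))
    thrS <- autoThreshold(recS$image)
    maskS <- binarize(recS$image, thrS)
    outS <- removeLeadCharacters(maskS, recS$template@leadRois, lib,
        minScore = 0.6)
    manS <- recS$manifest
    glyphS <- matrix(FALSE, manS@canvas[1], manS@canvas[2])
    glyphS[manS@glyphPixels] <- TRUE
    expect_equal(sum(maskData(outS$mask) & glyphS), 0)  # glyph fully erased
    ideal <- maskData(idealTraceMask(manS))
    expect_equal(sum((maskData(maskS) & ideal) != (maskData(outS$mask) & ideal)), 0)

    # an ROI with no glyph leaves the mask unchanged
    emptyRois <- data.frame(name = "none", top = 5L, left = 5L,
        bottom = 40L, right = 60L)
    expect_identical(maskData(removeLeadCharacters(maskS, emptyRois, lib,
        minScore = 0.6)$mask), maskData(maskS))
})

test_that("demographic extraction reads fields verbatim and degrades honestly over grid", {
    demo <- list(name = "JANE A DOE", id = "4021-77", date = "2021/05/25")
    rec <- smallRecord(nRows = 1, beats = 1, seed = 15,
        demographics = demo, demographicFields = names(demo))
    parts <- partitionRegions(rec$image, rec$template)
    lib <- defaultGlyphLibrary(3L)
    got <- extractDemographics(parts$demographic, rec$template, lib)
    expect_equal(got$name, demo$name)
    expect_equal(got$id, demo$id)
    expect_equal(got$date, demo$date)

    # empty region: all fields reported as empty strings, never omitted
    blank <- ECGImage(matrix(240, 120, rec$template@canvas[2]), dpi = 300)
    gotBlank <- extractDemographics(blank, rec$template, lib)
    expect_setequal(names(gotBlank), names(demo))
    expect_true(all(unlist(gotBlank) == ""))

    # text over residual grid: per-character scores drop, and no character
    # is emitted below the threshold
    d <- imageData(parts$demographic)
    gridded <- d
    gridded[seq(3, nrow(d), by = 12), ] <- pmin(
        gridded[seq(3, nrow(d), by = 12), ], 50)
    gridded[, seq(3, ncol(d), by = 12)] <- pmin(
        gridded[, seq(3, ncol(d), by = 12)], 50)
    gimg <- ECGImage(gridded, dpi = 300, origin = parts$demographic@origin)
    gotGrid <- extractDemographics(gimg, rec$template, lib)
    recs <- attr(gotGrid, "recognitions")
    cleanRecs <- attr(got, "recognitions")
    meanClean <- mean(unlist(lapply(cleanRecs, function(r)
        recognitionBoxes(r)$score)))
    meanGrid <- mean(unlist(lapply(recs, function(r)
        recognitionBoxes(r)$score)))
    expect_lt(meanGrid, meanClean)
    for (r in recs)
        expect_true(all(recognitionBoxes(r)$score >= 0.6))
})
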