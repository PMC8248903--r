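test_that("component labelling respects connectivity and cross-checks EBImage", {
    d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
    expect_equal(nComponents(labelComponents(BinaryMask(d), 8L)), 1L)
    expect_equal(nComponents(labelComponents(BinaryMask(d), 4L)), 2L)

    empty <- labelComponents(BinaryMask(matrix(FALSE, 4, 4)), 8L)
    expect_equal(nComponents(empty), 0L)
    expect_equal(componentAreas(empty), integer(0))

    # independent cross-check against EBImage's 4-connected labeller on a
    # random blob field
    set.seed(5)
    m <- matrix(runif(80 * 80) < 0.3, 80, 80)
    mine <- labelComponents(BinaryMask(m), 4L)
    ref <- EBImage::bwlabel(m * 1)
    expect_equal(nComponents(mine), max(ref))
    # identical partition: every component of ours maps to one of theirs
    lut <- tapply(ref[mine@coords], mine@label, function(v) length(unique(v)))
    expect_true(all(lut == 1))

    # a clean record yields one trace component per row plus glyph bits
    rec <- smallRecord(nRows = 2, beats = 2, seed = 3, drift = 0,
        labels = data.frame(text = c("II", "V1"), row = 1:2,
            colOffset = c(500, 500), overlap = FALSE))
    ideal <- idealTraceMask(rec$manifest)
    comps <- labelComponents(ideal, 8L)
    big <- sum(componentAreas(comps) > 500)
    expect_equal(big, 2L)
})

test_that("small components are discarded by a strict-less rule", {
    # areas 30 / 99 / 100 / 5000 at min 100: exactly the last two survive
    m <- matrix(FALSE, 80, 300)
    m[1:5, 1:6] <- TRUE                       # 30
    m[10:18, 10:20] <- TRUE; m[18, 20] <- FALSE  # 98
    m[20, 25] <- TRUE  # lone pixel keeps areas distinct
    m[30:39, 30:39] <- TRUE                   # 100
    m[50:74, 50:249] <- TRUE                  # 5000
    cs <- labelComponents(BinaryMask(m), 8L)
    expect_equal(sort(componentAreas(cs)), c(1, 30, 98, 100, 5000))
    kept <- discardSmall(cs, 100L)
    expect_equal(sort(componentAreas(kept)), c(100, 5000))
    # min area 0 is the identity
    expect_equal(componentAreas(discardSmall(cs, 0L)), componentAreas(cs))
})

test_that("Hausdorff distances match the brute-force double-loop oracle", {
    expect_equal(hausdorffFull(cbind(1, 1), cbind(1, 1)), 0)
    expect_equal(hausdorffFull(cbind(0, 0), cbind(3, 4)), 5)

    set.seed(11)
    for (i in 1:20) {
        A <- randomBlob(40); B <- randomBlob(40, rowOffset = 10)
        expect_equal(hausdorffFull(A, B), bruteHausdorff(A, B))
        # symmetry and non-negativity
        expect_equal(hausdorffFull(A, B), hausdorffFull(B, A))
        expect_gte(hausdorffFull(A, B), 0)
    }

    # identity of indiscernibles for the full form
    A <- randomBlob(25)
    expect_equal(hausdorffFull(A, A[sample(nrow(A)), ]), 0)

    expect_error(hausdorffFull(A, A[0, , drop = FALSE]), "non-empty")
})

test_that("truncated Hausdorff equals the brute-force distance over endpoint subsets", {
    set.seed(13)
    # saturation: endpoint count >= area -> equals the full distance exactly
    for (i in 1:10) {
        A <- randomBlob(30); B <- randomBlob(30, colOffset = 25)
        expect_identical(hausdorffTruncated(A, B, endpointPixels = 30),
            hausdorffFull(A, B))
        expect_equal(hausdorffTruncated(A, B, endpointPixels = 7), 0 +
            bruteHausdorff(
                PaperECG:::.endpointSubset(A, 7),
                PaperECG:::.endpointSubset(B, 7)))
    }
    # 200-px components, 50 endpoint pixels per side
    A <- randomBlob(200); B <- randomBlob(200, rowOffset = 60)
    expect_equal(hausdorffTruncated(A, B, endpointPixels = 50),
        bruteHausdorff(PaperECG:::.endpointSubset(A, 50),
                       PaperECG:::.endpointSubset(B, 50)))
    # zero for identical components at any truncation
    expect_equal(hausdorffTruncated(A, A, endpointPixels = 5), 0)
})

test_that("row assembly recovers the true partition and rejects stray glyphs", {
    # three rows with <= 5-px gaps; rows 120 px apart
    set.seed(17)
    gaps <- lapply(1:3, function(i) {
        starts <- sort(sample(seq(10, 380, by = 19), 20))
        unlist(lapply(starts, function(s) s + 0:(sample(3, 1) - 1)))
    })
    m <- gappedRowsMask(nRows = 3, width = 400, rowSpacing = 120,
        gapCols = gaps)
    comps <- labelComponents(BinaryMask(m), 8L)
    expect_gt(nComponents(comps), 3)
    rows <- assembleRows(comps,
        mergeParams(distanceThreshold = 20, endpointPixels = 75,
            minComponentArea = 0), expectedRows = 3)
    expect_equal(nRows(rows), 3L)
    # each group's pixels equal the row's mask pixels exactly
    for (r in 1:3) {
        px <- rowPixels(rows, r)
        bandRows <- 20 + (r - 1) * 120 + 1:3
        expect_setequal(unique(px[, 1]), bandRows)
        expect_equal(nrow(px), sum(m[bandRows, ]))
    }

    # isolated per-row components stay singleton groups
    m1 <- gappedRowsMask(nRows = 3, width = 200, rowSpacing = 150)
    cs1 <- labelComponents(BinaryMask(m1), 8L)
    r1 <- assembleRows(cs1, mergeParams(distanceThreshold = 30,
        minComponentArea = 0), expectedRows = 3)
    expect_equal(lengths(r1@groups), c(1L, 1L, 1L))

    # glyph-like blobs far from the traces land in rejects
    m2 <- gappedRowsMask(nRows = 2, width = 300, rowSpacing = 160)
    m2[100:110, 50:60] <- TRUE   # a stray 11x11 blob between the rows
    cs2 <- labelComponents(BinaryMask(m2), 8L)
    r2 <- assembleRows(cs2, mergeParams(distanceThreshold = 25,
        minComponentArea = 0), expectedRows = 2)
    expect_equal(nRows(r2), 2L)
    expect_equal(length(rowRejects(r2)), 1L)

    expect_error(assembleRows(labelComponents(
        BinaryMask(matrix(FALSE, 3, 3)), 8L),
        mergeParams(distanceThreshold = 10)), "no waveform")
})

test_that("row assembly is order-invariant and coarsens monotonically in the threshold", {
    set.seed(19)
    gaps <- list(c(100:104, 200:203, 300:301))
    m <- gappedRowsMask(nRows = 2, width = 400, rowSpacing = 100,
        gapCols = c(gaps, gaps))
    cs <- labelComponents(BinaryMask(m), 8L)

    nGroups <- function(thr) {
        rw <- suppressWarnings(assembleRows(cs,
            mergeParams(distanceThreshold = thr, minComponentArea = 0),
            expectedRows = NA, minWidth = 0))
        length(rw@groups)
    }
    counts <- vapply(c(2, 4, 8, 20, 60, 150), nGroups, 0)
    expect_true(all(diff(counts) <= 0))

    # permuting pixel order leaves the partition identical (labels are
    # canonical in scan order, so compare pixel sets per group)
    rw <- assembleRows(cs, mergeParams(distanceThreshold = 20,
        minComponentArea = 0), expectedRows = 2)
    perm <- sample(nrow(cs@coords))
    cs2 <- new("ComponentSet", coords = cs@coords[perm, ],
        label = cs@label[perm], dim = cs@dim,
        connectivity = cs@connectivity)
    rw2 <- assembleRows(cs2, mergeParams(distanceThreshold = 20,
        minComponentArea = 0), expectedRows = 2)
    for (r in 1:2) {
        a <- rowPixels(rw, r); b <- rowPixels(rw2, r)
        expect_equal(a[order(a[, 1], a[, 2]), ], b[order(b[, 1], b[, 2]), ],
            ignore_attr = TRUE)
    }
})

test_that("assembly on a gap-split synthetic record matches the manifest rows", {
    rec <- smallRecord(nRows = 2, beats = 2, seed = 23, drift = 0)
    ideal <- idealTraceMask(rec$manifest)
    # punch 4-px gaps into each row's trace
    m <- maskData(ideal)
    man <- rec$manifest
    for (r in 1:2) {
        cols <- man@rows[[r]]$signalCols[1] + c(100, 250, 400)
        for (cc in cols) {
            band <- man@rows[[r]]$baselineRow + (-170:170)
            m[band, cc + 0:3] <- FALSE
        }
    }
    cs <- discardSmall(labelComponents(BinaryMask(m), 8L), 20L)
    rw <- assembleRows(cs, mergeParams(distanceThreshold = 30,
        minComponentArea = 20), expectedRows = 2)
    expect_equal(nRows(rw), 2L)
    for (r in 1:2) {
        px <- rowPixels(rw, r)
        expect_equal(nrow(px), sum(m[man@rows[[r]]$baselineRow + (-170:170), ]))
    }
})
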