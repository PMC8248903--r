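# Shared fixtures and independent oracles.

# A compact synthetic record: fewer beats/rows than the defaults so unit
# tests stay fast; acceptance tests build full-size records themselves.
smallRecord <- function(nRows = 2, beats = 2, seed = 1, skew = 0, sp = 0,
                        fade = 1, labels = NULL, demographics = list(),
                        demographicFields = character(0), drift = 0.05,
                        dpi = 300) {
    p <- waveformParams(beatsPerRow = beats, baselineDriftAmplitude = drift)
    cfg <- renderConfig(dpi = dpi, skewAngle = skew, saltPepperProb = sp,
        fadeFactor = fade, labels = labels, demographics = demographics,
        seed = seed)
    tpl <- makeSyntheticTemplate(p, cfg, nRows,
        demographicFields = demographicFields)
    w <- generateWaveform(p, nRows, seed = seed)
    rec <- renderRecord(w, cfg, tpl)
    list(image = rec$image, manifest = rec$manifest, template = tpl,
        cfg = cfg, waves = w, params = p)
}

# Brute-force symmetric Hausdorff distance: the O(N^2) double loop.
bruteHausdorff <- function(A, B) {
    dmin <- function(P, Q) {
        vapply(seq_len(nrow(P)), function(i)
            min(sqrt((P[i, 1] - Q[, 1])^2 + (P[i, 2] - Q[, 2])^2)), 0)
    }
    max(max(dmin(A, B)), max(dmin(B, A)))
}

# Brute-force morphological opening (erosion then dilation, 3x3 box,
# outside-image = background).
bruteOpen <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    getpx <- function(x, i, j)
        if (i >= 1 && i <= nr && j >= 1 && j <= nc) x[i, j] else FALSE
    ero <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        v <- TRUE
        for (di in -1:1) for (dj in -1:1)
            v <- v && getpx(m, i + di, j + dj)
        ero[i, j] <- v
    }
    dil <- matrix(FALSE, nr, nc)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
        v <- FALSE
        for (di in -1:1) for (dj in -1:1)
            v <- v || getpx(ero, i + di, j + dj)
        dil[i, j] <- v
    }
    dil
}

# Random connected-ish pixel blob for distance tests (not necessarily
# connected; the distance ops only need point sets).
randomBlob <- function(n, rowOffset = 0, colOffset = 0) {
    cbind(row = sample.int(40, n, replace = TRUE) + rowOffset,
          col = sample.int(40, n, replace = TRUE) + colOffset)
}

# Mask with nRows horizontal 3-px-thick lines split by known gaps.
gappedRowsMask <- function(nRows = 3, width = 400, rowSpacing = 120,
                           gapCols = list(), thick = 3) {
    H <- nRows * rowSpacing + 40
    m <- matrix(FALSE, H, width + 40)
    for (r in seq_len(nRows)) {
        y <- 20 + (r - 1) * rowSpacing + seq_len(thick)
        cols <- 20 + seq_len(width)
        if (length(gapCols) >= r && length(gapCols[[r]]))
            cols <- setdiff(cols, 20 + gapCols[[r]])
        m[y, cols] <- TRUE
    }
    m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
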