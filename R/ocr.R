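# Step C: correlation-template OCR over a trainable glyph library, ROI
# realignment against a standard template, lead-character erasure, and
# demographic text extraction.

#' Build a glyph library from labelled samples
#'
#' Each sample is a binary bitmap paired with the character it depicts.
#' Exemplars are normalized by trimming to their ink bounding box; several
#' exemplars per character are allowed and the matcher uses the best.
#'
#' @param samples list of \code{list(bitmap = <logical matrix>, char =
#'   <single character>)}.
#' @param meta optional list of source annotations.
#' @return a \linkS4class{GlyphLibrary}.
#' @examples
#' lib <- buildGlyphLibrary(list(list(bitmap = renderGlyph("V"), char = "V")))
#' glyphCharacters(lib)
#' @export
buildGlyphLibrary <- function(samples, meta = list()) {
    stopIfNot(length(samples) > 0, "at least one sample is required")
    glyphs <- list()
    for (s in samples) {
        if (is.null(s$char) || !nzchar(s$char))
            stop("annotation error: unlabeled sample", call. = FALSE)
        b <- .trimBitmap(s$bitmap)
        glyphs[[s$char]] <- c(glyphs[[s$char]], list(b))
    }
    new("GlyphLibrary", glyphs = glyphs, meta = meta)
}

.trimBitmap <- function(b) {
    stopIfNot(is.matrix(b) && is.logical(b) && any(b),
        "exemplar bitmaps must be non-empty logical matrices")
    rr <- range(which(rowSums(b) > 0)); cc <- range(which(colSums(b) > 0))
    out <- b[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
    if (all(out)) {
        # a solid block (e.g. '-' or '.') has zero variance and could never
        # be matched by zero-mean correlation: keep a background border
        pad <- 2L
        padded <- matrix(FALSE, nrow(out) + 2L * pad, ncol(out) + 2L * pad)
        padded[pad + seq_len(nrow(out)), pad + seq_len(ncol(out))] <- out
        out <- padded
    }
    out
}

#' The built-in glyph library
#'
#' Exemplars rendered from the package's 5x7 dot-matrix font at the given
#' scale -- the same bitmaps the synthetic renderer prints, so recognition
#' on synthetic records is self-consistent.
#'
#' @param scale integer font magnification (match the renderer's
#'   \code{glyphScale}).
#' @param characters which characters to include.
#' @return a \linkS4class{GlyphLibrary}.
#' @export
defaultGlyphLibrary <- function(scale = 3L, characters = fontCharacters()) {
    buildGlyphLibrary(
        lapply(characters, function(ch)
            list(bitmap = renderGlyph(ch, scale), char = ch)),
        meta = list(font = "builtin 5x7", scale = as.integer(scale)))
}

#' Save / load a glyph library
#'
#' The on-disk form is a directory of per-character PNG exemplars plus a
#' JSON index, and round-trips losslessly.
#'
#' @param lib a \linkS4class{GlyphLibrary}.
#' @param dir directory to create/read.
#' @return \code{dir} (save) or the reloaded \linkS4class{GlyphLibrary}.
#' @export
saveGlyphLibrary <- function(lib, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    index <- list(meta = lib@meta, entries = list())
    i <- 0L
    for (ch in names(lib@glyphs)) {
        for (k in seq_along(lib@glyphs[[ch]])) {
            i <- i + 1L
            f <- sprintf("glyph_%03d.png", i)
            png::writePNG(lib@glyphs[[ch]][[k]] * 1, file.path(dir, f))
            index$entries[[i]] <- list(char = ch, file = f)
        }
    }
    jsonlite::write_json(index, file.path(dir, "index.json"),
        auto_unbox = TRUE)
    invisible(dir)
}

#' @rdname saveGlyphLibrary
#' @export
loadGlyphLibrary <- function(dir) {
    index <- jsonlite::read_json(file.path(dir, "index.json"))
    samples <- lapply(index$entries, function(e) {
        b <- png::readPNG(file.path(dir, e$file))
        if (length(dim(b)) == 3L) b <- b[, , 1]
        list(bitmap = b > 0.5, char = e$char)
    })
    buildGlyphLibrary(samples, meta = lapply(index$meta, unlist))
}

#' Morphological opening to expose character skeletons
#'
#' Erosion followed by dilation with a 3x3 structuring element: removes
#' one-pixel burrs and protrusions while preserving solid strokes, cleaning
#' glyphs before correlation matching.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return the opened \linkS4class{BinaryMask}.
#' @export
skeletonizeForOcr <- function(mask) {
    m <- maskData(mask) * 1
    k <- matrix(1, 3, 3)
    ero <- slideSum(m, k) > 8.5          # all 9 present (border = background)
    dil <- slideSum(ero * 1, k) > 0.5
    BinaryMask(dil, origin = mask@origin,
        provenance = c(mask@provenance, list(opening = "3x3")))
}

# Cyclic FFT cross-correlation: C[i, j] = sum_{a,b} M[i+a-1, j+b-1] T[a, b].
# Valid (non-wrapping) placements are i <= nrow(M)-nrow(T)+1 etc.
.fftCorr <- function(M, Tm) {
    H <- nrow(M); W <- ncol(M)
    T0 <- matrix(0, H, W)
    T0[seq_len(nrow(Tm)), seq_len(ncol(Tm))] <- Tm
    Re(stats::fft(stats::fft(M) * Conj(stats::fft(T0)), inverse = TRUE)) /
        (H * W)
}

# Zero-mean normalized cross-correlation of one exemplar over a region.
# Returns the score matrix indexed by the exemplar's top-left placement.
.znccMap <- function(region, tmpl) {
    h <- nrow(tmpl); w <- ncol(tmpl)
    H <- nrow(region); W <- ncol(region)
    if (H < h || W < w) return(NULL)
    t0 <- tmpl - mean(tmpl)
    tNorm <- sqrt(sum(t0^2))
    if (tNorm == 0) return(NULL)
    nPix <- h * w
    ones <- matrix(1, h, w)
    val <- function(M) M[seq_len(H - h + 1L), seq_len(W - w + 1L),
        drop = FALSE]
    s1 <- val(.fftCorr(region, ones))
    s2 <- val(.fftCorr(region^2, ones))
    cc <- val(.fftCorr(region, t0))
    varW <- pmax(s2 - s1^2 / nPix, 0)
    den <- tNorm * sqrt(varW)
    sc <- ifelse(den > 1e-6, cc / den, 0)
    pmin(pmax(sc, -1), 1)
}

#' Recognize text in a region of interest by template correlation
#'
#' Slides every library exemplar over the ROI computing zero-mean normalized
#' cross-correlation; peaks at or above \code{minScore} become characters.
#' Overlapping candidates are resolved greedily by descending score (ties:
#' leftmost), and the surviving characters are ordered left to right.
#' Below-threshold regions yield no character -- the matcher never guesses.
#'
#' @param region a \linkS4class{BinaryMask} (or logical matrix).
#' @param roi integer(4) rectangle (top, left, bottom, right) within the
#'   region, or NULL for the whole region.
#' @param lib a \linkS4class{GlyphLibrary}.
#' @param minScore acceptance threshold in (0, 1\]; default 0.6.
#' @return a \linkS4class{Recognition}; box coordinates are relative to the
#'   full \code{region}.
#' @export
recognizeText <- function(region, roi = NULL, lib, minScore = 0.6) {
    stopIfNot(is(lib, "GlyphLibrary"), "configuration error: empty library")
    m <- if (is(region, "BinaryMask")) maskData(region) else region
    if (is.null(roi)) roi <- c(1L, 1L, nrow(m), ncol(m))
    stopIfNot(roi[1] >= 1 && roi[2] >= 1 && roi[3] <= nrow(m) &&
              roi[4] <= ncol(m), "roi must lie within the region")
    sub <- m[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE] * 1
    cand <- list()
    for (ch in names(lib@glyphs)) {
        for (tm in lib@glyphs[[ch]]) {
            sc <- .znccMap(sub, tm * 1)
            if (is.null(sc)) next
            hit <- which(sc >= minScore, arr.ind = TRUE)
            if (!nrow(hit)) next
            cand[[length(cand) + 1L]] <- data.frame(
                char = ch, top = hit[, 1], left = hit[, 2],
                bottom = hit[, 1] + nrow(tm) - 1L,
                right = hit[, 2] + ncol(tm) - 1L,
                score = sc[hit])
        }
    }
    boxes <- data.frame(char = character(0), top = integer(0),
        left = integer(0), bottom = integer(0), right = integer(0),
        score = numeric(0))
    if (length(cand)) {
        cand <- do.call(rbind, cand)
        # quantize scores so FFT rounding noise cannot reorder exact ties;
        # among tied scores prefer the larger glyph (a small glyph can be an
        # exact sub-pattern of a larger one), then the leftmost
        area <- (cand$bottom - cand$top + 1L) * (cand$right - cand$left + 1L)
        cand <- cand[order(-round(cand$score, 6), -area, cand$left,
            cand$top), , drop = FALSE]
        taken <- logical(nrow(cand))
        chosen <- integer(0)
        for (i in seq_len(nrow(cand))) {
            if (taken[i]) next
            chosen <- c(chosen, i)
            # suppress candidates whose box overlaps the accepted one
            ov <- !(cand$left > cand$right[i] | cand$right < cand$left[i] |
                    cand$top > cand$bottom[i] | cand$bottom < cand$top[i])
            taken[ov] <- TRUE
        }
        boxes <- cand[chosen, , drop = FALSE]
        boxes <- boxes[order(boxes$left, boxes$top), , drop = FALSE]
        boxes$top <- boxes$top + roi[1] - 1L
        boxes$bottom <- boxes$bottom + roi[1] - 1L
        boxes$left <- boxes$left + roi[2] - 1L
        boxes$right <- boxes$right + roi[2] - 1L
        rownames(boxes) <- NULL
    }
    new("Recognition", text = paste(boxes$char, collapse = ""), boxes = boxes)
}

#' Estimate the global ROI offset against a standard template image
#'
#' A scan that was fed slightly off-position shifts every ROI by the same
#' amount.  The offset is the integer translation maximizing the whole-image
#' cross-correlation (FFT-based, mean-removed) between the input and the
#' standard template scan, and is added to every ROI; ROIs pushed outside
#' the canvas are clamped with a warning.
#'
#' @param image the scan, an \linkS4class{ECGImage}.
#' @param standard the reference scan, an \linkS4class{ECGImage} of the same
#'   size.
#' @param rois data.frame with columns top, left, bottom, right (plus any
#'   id columns, preserved).
#' @param maxShift largest plausible misfeed, px.
#' @param minPeak floor on the normalized correlation peak; below it the
#'   scan does not match the template.
#' @return the shifted ROI data.frame, with the offset in attribute
#'   \code{offset} (c(drow, dcol)).
#' @export
alignRois <- function(image, standard, rois, maxShift = 30L,
                      minPeak = 0.2) {
    A <- imageData(image); B <- imageData(standard)
    stopIfNot(all(dim(A) == dim(B)),
        "image and standard must have equal dimensions")
    a <- A - mean(A); b <- B - mean(B)
    # cross-correlation via FFT; wrap-around is harmless for small shifts
    X <- stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE) /
        length(a)
    cc <- Re(X) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
    sh <- function(i, n) ifelse(i - 1L > n / 2, i - 1L - n, i - 1L)
    nr <- nrow(cc); nc <- ncol(cc)
    rIdx <- sh(seq_len(nr), nr); cIdx <- sh(seq_len(nc), nc)
    ok <- outer(abs(rIdx) <= maxShift, abs(cIdx) <= maxShift, "&")
    cc[!ok] <- -Inf
    k <- arrayInd(which.max(cc), dim(cc))
    peak <- max(cc[ok])
    if (!is.finite(peak) || peak < minPeak)
        stop("template mismatch: correlation peak below floor", call. = FALSE)
    off <- c(sh(k[1], nr), sh(k[2], nc))
    out <- rois
    out$top <- rois$top + off[1]; out$bottom <- rois$bottom + off[1]
    out$left <- rois$left + off[2]; out$right <- rois$right + off[2]
    H <- nrow(A); W <- ncol(A)
    clamped <- out$top < 1 | out$left < 1 | out$bottom > H | out$right > W
    if (any(clamped)) {
        warning(sprintf("%d ROI(s) clamped to the canvas after realignment",
            sum(clamped)))
        out$top <- pmax(out$top, 1L); out$left <- pmax(out$left, 1L)
        out$bottom <- pmin(out$bottom, H); out$right <- pmin(out$right, W)
    }
    attr(out, "offset") <- off
    out
}

#' Erase lead-label characters from the trace mask
#'
#' Within each lead-label ROI, the matched exemplar footprints (the TRUE
#' pixels of the best-scoring exemplar at its correlation peak) are set to
#' background -- including where they coincide with trace ink, which is what
#' makes overlapping labels removable at all.  The erased column span per
#' ROI is reported so extraction can re-interpolate the gap.  Unmatched ROIs
#' leave the mask untouched; no pixel is ever added.
#'
#' @param mask the waveform-region \linkS4class{BinaryMask} (ROI coordinates
#'   are interpreted in the mask's parent canvas via its origin).
#' @param rois data.frame of lead-label ROIs: name, top, left, bottom,
#'   right (canvas coordinates).  When a ROI's name is made of library
#'   characters, matching inside it is restricted to those characters: a
#'   lead ROI declares which label it holds, so other glyphs (and stray
#'   punctuation look-alikes) are not searched for.
#' @param lib a \linkS4class{GlyphLibrary}.
#' @param minScore correlation acceptance threshold for free-text matching.
#'   Inside a named lead ROI the label is known to be present, so the
#'   acceptance threshold is relaxed to \code{0.75 * minScore} for its own
#'   characters (a trace crossing a glyph depresses its correlation).
#' @return list: \code{mask} (erased \linkS4class{BinaryMask}),
#'   \code{recognitions} (per-ROI \linkS4class{Recognition}, mask-local
#'   coordinates), \code{erasedSpans} (list of column ranges per ROI, mask
#'   coordinates).
#' @export
removeLeadCharacters <- function(mask, rois, lib, minScore = 0.6) {
    m <- maskData(mask)
    o <- mask@origin
    recs <- list(); spans <- list()
    for (i in seq_len(nrow(rois))) {
        r <- c(rois$top[i], rois$left[i], rois$bottom[i], rois$right[i]) -
            c(o[1] - 1L, o[2] - 1L, o[1] - 1L, o[2] - 1L)
        r[1] <- max(r[1], 1L); r[2] <- max(r[2], 1L)
        r[3] <- min(r[3], nrow(m)); r[4] <- min(r[4], ncol(m))
        if (r[3] < r[1] || r[4] < r[2]) next
        labelChars <- unique(strsplit(rois$name[i] %||% "", "")[[1]])
        roiLib <- lib; roiScore <- minScore
        if (length(labelChars) &&
            all(labelChars %in% names(lib@glyphs))) {
            roiLib <- new("GlyphLibrary", glyphs = lib@glyphs[labelChars],
                meta = lib@meta)
            roiScore <- 0.75 * minScore
        }
        # whole-label matching first: the full label's correlation is far
        # more robust to a trace crossing one of its glyphs than any single
        # character's, and its footprint covers the label's entire ink
        scale <- lib@meta$scale
        wordDone <- FALSE
        if (!is.null(scale) && length(labelChars) &&
            all(labelChars %in% fontCharacters())) {
            bmp <- renderText(rois$name[i], as.integer(scale))
            sub <- m[r[1]:r[3], r[2]:r[4], drop = FALSE] * 1
            sc <- .znccMap(sub, bmp * 1)
            if (!is.null(sc) && max(sc) >= roiScore) {
                k <- arrayInd(which.max(sc), dim(sc))
                top <- r[1] + k[1] - 1L; left <- r[2] + k[2] - 1L
                rr2 <- top:(top + nrow(bmp) - 1L)
                cc2 <- left:(left + ncol(bmp) - 1L)
                blk <- m[rr2, cc2, drop = FALSE]
                blk[bmp] <- FALSE
                m[rr2, cc2] <- blk
                nm <- rois$name[i] %||% as.character(i)
                recs[[nm]] <- new("Recognition", text = rois$name[i],
                    boxes = data.frame(char = rois$name[i], top = top,
                        left = left, bottom = top + nrow(bmp) - 1L,
                        right = left + ncol(bmp) - 1L,
                        score = max(sc)))
                spans[[nm]] <- c(left, left + ncol(bmp) - 1L)
                wordDone <- TRUE
            }
        }
        if (wordDone) next
        rec <- recognizeText(BinaryMask(m, origin = o), roi = r,
            lib = roiLib, minScore = roiScore)
        nm <- rois$name[i] %||% as.character(i)
        recs[[nm]] <- rec
        if (!nrow(rec@boxes)) next
        colsErased <- integer(0)
        for (j in seq_len(nrow(rec@boxes))) {
            bx <- rec@boxes[j, ]
            tm <- .bestExemplar(lib, bx$char, bx$bottom - bx$top + 1L,
                bx$right - bx$left + 1L)
            rr <- bx$top:bx$bottom; ccc <- bx$left:bx$right
            blk <- m[rr, ccc, drop = FALSE]
            blk[tm] <- FALSE
            m[rr, ccc] <- blk
            colsErased <- c(colsErased, bx$left:bx$right)
        }
        spans[[nm]] <- range(colsErased)
    }
    list(mask = BinaryMask(m, origin = o,
            provenance = c(mask@provenance,
                list(leadCharactersRemoved = length(spans)))),
        recognitions = recs, erasedSpans = spans)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.bestExemplar <- function(lib, char, h, w) {
    exs <- lib@glyphs[[char]]
    for (tm in exs) if (nrow(tm) == h && ncol(tm) == w) return(tm)
    exs[[1]]
}

#' Extract patient demographic text
#'
#' The demographic region is re-thresholded independently of the waveform
#' threshold (text printed over residual grid needs its own level), opened
#' to expose character skeletons, and each demographic field ROI is read by
#' correlation OCR.  Fields with no recognized character are reported as
#' empty strings, never omitted.
#'
#' @param region the demographic \linkS4class{ECGImage} crop.
#' @param template a \linkS4class{TemplateSpec} with demographic ROIs.
#' @param lib a \linkS4class{GlyphLibrary}.
#' @param minScore correlation acceptance threshold.
#' @param open apply \code{\link{skeletonizeForOcr}} before matching.
#' @return named list of field texts, with per-field
#'   \linkS4class{Recognition} objects in attribute \code{recognitions}.
#' @export
extractDemographics <- function(region, template, lib, minScore = 0.6,
                                open = FALSE) {
    rois <- template@demographicRois
    out <- list(); recs <- list()
    if (length(imageData(region)) == 0 || !nrow(rois)) {
        for (f in rois$field) out[[f]] <- ""
        return(structure(out, recognitions = recs))
    }
    d <- imageData(region)
    thr <- tryCatch(autoThreshold(region),
        error = function(e) structure(
            round(EBImage::otsu(d / 255, range = c(0, 1)) * 255),
            method = "otsu"))
    msk <- binarize(region, thr)
    if (open) msk <- skeletonizeForOcr(msk)
    o <- region@origin
    for (i in seq_len(nrow(rois))) {
        f <- rois$field[i]
        r <- c(rois$top[i] - o[1] + 1L, rois$left[i] - o[2] + 1L,
               rois$bottom[i] - o[1] + 1L, rois$right[i] - o[2] + 1L)
        r[1] <- max(r[1], 1L); r[2] <- max(r[2], 1L)
        r[3] <- min(r[3], nrow(d)); r[4] <- min(r[4], ncol(d))
        if (r[3] < r[1] || r[4] < r[2]) { out[[f]] <- ""; next }
        rec <- recognizeText(msk, roi = r, lib = lib, minScore = minScore)
        out[[f]] <- .spaceText(rec)
        recs[[f]] <- rec
    }
    structure(out, recognitions = recs)
}

# reconstruct spacing: gaps wider than ~1.5 glyph widths become one space
.spaceText <- function(rec) {
    b <- rec@boxes
    if (nrow(b) < 2L) return(rec@text)
    w <- stats::median(b$right - b$left + 1)
    gaps <- b$left[-1] - b$right[-nrow(b)]
    paste0(b$char[1], paste0(ifelse(gaps > 0.6 * w, " ", ""), b$char[-1],
        collapse = ""))
}
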