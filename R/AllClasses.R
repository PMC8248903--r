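#' @import methods
#' @importFrom stats approx cor median quantile sd runif
#' @importFrom utils head tail
NULL

#' ECGImage: a raster scan of a paper ECG record
#'
#' Holds an 8-bit intensity grid together with its resolution metadata.
#' Grayscale images are stored as a numeric matrix (rows x columns, values in
#' \[0, 255\], row index increasing downward); colour scans as a rows x columns
#' x 3 array.  The \code{origin} slot records where a crop sits inside its
#' parent canvas (1-based top-left \code{c(row, col)}), so that template
#' coordinates remain meaningful after \code{\link{partitionRegions}}.
#'
#' @slot data numeric matrix or 3-d array of intensities in \[0, 255\].
#' @slot dpi numeric(1), pixels per inch.
#' @slot origin integer(2), 1-based (row, col) of this crop in its parent.
#' @exportClass ECGImage
setClass("ECGImage", representation(
    data = "array",
    dpi = "numeric",
    origin = "integer"
))

setValidity("ECGImage", function(object) {
    d <- object@data
    if (!(length(dim(d)) %in% c(2L, 3L)))
        return("data must be a matrix or a rows x cols x channels array")
    if (any(dim(d)[1:2] < 1L))
        return("image must have positive extent")
    if (length(dim(d)) == 3L && dim(d)[3] != 3L)
        return("colour images must have exactly 3 channels")
    rng <- range(d)
    if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255)
        return("intensities must be finite and within [0, 255]")
    if (length(object@dpi) != 1L || object@dpi <= 0)
        return("dpi must be a single positive number")
    if (length(object@origin) != 2L || any(object@origin < 1L))
        return("origin must be a 1-based (row, col) pair")
    TRUE
})

#' Construct an ECGImage
#'
#' @param data numeric matrix (grayscale) or rows x cols x 3 array (colour),
#'   intensities in \[0, 255\].
#' @param dpi resolution in pixels per inch.
#' @param origin 1-based (row, col) of the crop inside its parent canvas.
#' @return An \linkS4class{ECGImage}.
#' @examples
#' img <- ECGImage(matrix(255, 10, 10), dpi = 300)
#' imageDpi(img)
#' @export
ECGImage <- function(data, dpi, origin = c(1L, 1L)) {
    if (is.matrix(data)) storage.mode(data) <- "double"
    new("ECGImage", data = data, dpi = as.numeric(dpi),
        origin = as.integer(origin))
}

#' @rdname ECGImage
#' @param x an ECGImage.
#' @export
imageData <- function(x) x@data

#' @rdname ECGImage
#' @export
imageDpi <- function(x) x@dpi

#' @rdname ECGImage
#' @export
isColor <- function(x) length(dim(x@data)) == 3L

setMethod("show", "ECGImage", function(object) {
    d <- dim(object@data)
    cat(sprintf("ECGImage: %d x %d px, %s, %.0f dpi, origin (%d, %d)\n",
        d[1], d[2], if (isColor(object)) "colour" else "grayscale",
        object@dpi, object@origin[1], object@origin[2]))
})

#' BinaryMask: a thresholded view of a record region
#'
#' Logical grid in which TRUE marks ink.  \code{provenance} records how the
#' mask was produced (threshold used, filters applied) so every downstream
#' output can state its processing history.
#'
#' @slot data logical matrix.
#' @slot origin integer(2), 1-based (row, col) in the parent canvas.
#' @slot provenance list of processing annotations.
#' @exportClass BinaryMask
setClass("BinaryMask", representation(
    data = "matrix",
    origin = "integer",
    provenance = "list"
))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@data)) return("mask data must be logical")
    if (any(dim(object@data) < 1L)) return("mask must have positive extent")
    if (length(object@origin) != 2L || any(object@origin < 1L))
        return("origin must be a 1-based (row, col) pair")
    TRUE
})

#' Construct a BinaryMask
#'
#' @param data logical matrix, TRUE = ink.
#' @param origin 1-based (row, col) of the mask inside its parent canvas.
#' @param provenance list of processing annotations.
#' @return A \linkS4class{BinaryMask}.
#' @export
BinaryMask <- function(data, origin = c(1L, 1L), provenance = list()) {
    new("BinaryMask", data = data, origin = as.integer(origin),
        provenance = provenance)
}

#' @rdname BinaryMask
#' @param x a BinaryMask.
#' @export
maskData <- function(x) x@data

#' @rdname BinaryMask
#' @export
maskProvenance <- function(x) x@provenance

setMethod("show", "BinaryMask", function(object) {
    cat(sprintf("BinaryMask: %d x %d px, %d ink pixels, origin (%d, %d)\n",
        nrow(object@data), ncol(object@data), sum(object@data),
        object@origin[1], object@origin[2]))
    if (length(object@provenance))
        cat("  provenance:", paste(names(object@provenance), collapse = ", "),
            "\n")
})

#' SkewEstimate: dominant grid-line deviation from axis alignment
#'
#' @slot angle numeric(1), degrees in (-45, 45\]; positive angles mean the
#'   grid's horizontal lines rise (toward smaller row indices) with
#'   increasing column.
#' @slot support numeric(1), fraction of voting pixels in the dominant
#'   accumulator bin (a confidence score, not a probability).
#' @exportClass SkewEstimate
setClass("SkewEstimate", representation(angle = "numeric", support = "numeric"))

setValidity("SkewEstimate", function(object) {
    if (length(object@angle) != 1L || object@angle <= -45 || object@angle > 45)
        return("angle must be a single value in (-45, 45]")
    TRUE
})

#' @rdname estimateSkew
#' @param x a SkewEstimate.
#' @export
skewAngle <- function(x) x@angle

setMethod("show", "SkewEstimate", function(object) {
    cat(sprintf("SkewEstimate: %.2f deg (support %.3f)\n",
        object@angle, object@support))
})

#' ComponentSet: labelled connected components of a binary mask
#'
#' Stores every ink pixel's coordinate together with its component label.
#' Labels are contiguous from 1 and assigned in column-major scan order of
#' each component's first pixel, so labelling is deterministic.
#'
#' @slot coords integer matrix (n x 2), columns (row, col), 1-based.
#' @slot label integer vector of length n, component id per pixel.
#' @slot dim integer(2), extent of the source mask.
#' @slot connectivity integer(1), 4 or 8.
#' @exportClass ComponentSet
setClass("ComponentSet", representation(
    coords = "matrix",
    label = "integer",
    dim = "integer",
    connectivity = "integer"
))

setValidity("ComponentSet", function(object) {
    if (nrow(object@coords) != length(object@label))
        return("one label per pixel required")
    if (!object@connectivity %in% c(4L, 8L))
        return("connectivity must be 4 or 8")
    if (nrow(object@coords) > 0) {
        if (min(object@label) < 1L)
            return("labels must be positive")
        if (any(object@coords[, 1] < 1L) || any(object@coords[, 2] < 1L) ||
            any(object@coords[, 1] > object@dim[1]) ||
            any(object@coords[, 2] > object@dim[2]))
            return("pixel coordinates outside mask extent")
    }
    TRUE
})

#' @rdname labelComponents
#' @export
nComponents <- function(x) if (length(x@label)) max(x@label) else 0L

#' @rdname labelComponents
#' @export
componentAreas <- function(x) {
    if (!length(x@label)) return(integer(0))
    tabulate(x@label, nbins = max(x@label))
}

#' @rdname labelComponents
#' @param label component id.
#' @export
componentPixels <- function(x, label) {
    x@coords[x@label == label, , drop = FALSE]
}

#' @rdname labelComponents
#' @export
componentBoundingBoxes <- function(x) {
    n <- nComponents(x)
    if (n == 0L)
        return(data.frame(label = integer(0), top = integer(0),
            left = integer(0), bottom = integer(0), right = integer(0),
            area = integer(0)))
    r <- x@coords[, 1]; cc <- x@coords[, 2]; l <- x@label
    data.frame(
        label = seq_len(n),
        top = as.integer(tapply(r, l, min)),
        left = as.integer(tapply(cc, l, min)),
        bottom = as.integer(tapply(r, l, max)),
        right = as.integer(tapply(cc, l, max)),
        area = componentAreas(x))
}

setMethod("show", "ComponentSet", function(object) {
    cat(sprintf("ComponentSet: %d components, %d pixels, connectivity %d\n",
        nComponents(object), nrow(object@coords), object@connectivity))
})

#' RowWaveforms: connected components fused into ordered ECG rows
#'
#' The result of \code{\link{assembleRows}}: a partition of component labels
#' into row-waveform groups ordered top to bottom, plus the labels set aside
#' as rejects (stray specks or non-overlapping lead characters).
#'
#' @slot components the source \linkS4class{ComponentSet}.
#' @slot groups list of integer vectors: component labels per row, ordered by
#'   mean row coordinate.
#' @slot rejects integer vector of rejected component labels.
#' @slot flagged logical(1), TRUE when more groups were found than the
#'   template expects.
#' @exportClass RowWaveforms
setClass("RowWaveforms", representation(
    components = "ComponentSet",
    groups = "list",
    rejects = "integer",
    flagged = "logical"
))

#' @rdname assembleRows
#' @param x a RowWaveforms object.
#' @export
nRows <- function(x) length(x@groups)

#' @rdname assembleRows
#' @param row row index (1-based, top to bottom).
#' @export
rowPixels <- function(x, row) {
    labs <- x@groups[[row]]
    x@components@coords[x@components@label %in% labs, , drop = FALSE]
}

#' @rdname assembleRows
#' @export
rowRejects <- function(x) x@rejects

setMethod("show", "RowWaveforms", function(object) {
    cat(sprintf("RowWaveforms: %d rows, %d rejected components%s\n",
        length(object@groups), length(object@rejects),
        if (isTRUE(object@flagged)) " [more rows than expected]" else ""))
})

#' GlyphLibrary: exemplar bitmaps for correlation-template OCR
#'
#' Maps each character to one or more binary exemplar bitmaps, trimmed to
#' their ink bounding box.  Used both by the OCR matcher and by the synthetic
#' renderer, so recognition on synthetic records has a self-consistent
#' ceiling.
#'
#' @slot glyphs named list; each element a list of logical matrices.
#' @slot meta list of source annotations (scale, font name, ...).
#' @exportClass GlyphLibrary
setClass("GlyphLibrary", representation(glyphs = "list", meta = "list"))

setValidity("GlyphLibrary", function(object) {
    if (length(object@glyphs) == 0L) return("library must not be empty")
    if (is.null(names(object@glyphs)) || any(names(object@glyphs) == ""))
        return("every glyph entry must be named by its character")
    for (ex in object@glyphs) {
        if (!length(ex)) return("every character needs at least one exemplar")
        for (b in ex)
            if (!is.matrix(b) || !is.logical(b) || !any(b))
                return("exemplars must be non-empty logical matrices")
    }
    TRUE
})

#' @rdname buildGlyphLibrary
#' @export
glyphCharacters <- function(lib) names(lib@glyphs)

#' @rdname buildGlyphLibrary
#' @param char character to look up.
#' @export
glyphExemplars <- function(lib, char) lib@glyphs[[char]]

setMethod("show", "GlyphLibrary", function(object) {
    cat(sprintf("GlyphLibrary: %d characters, %d exemplars\n",
        length(object@glyphs), sum(lengths(object@glyphs))))
})

#' Recognition: OCR output for one region of interest
#'
#' @slot text recognised string (characters ordered left to right).
#' @slot boxes data.frame with one row per character: char, top, left,
#'   bottom, right (1-based, in the searched region's coordinates), score.
#' @exportClass Recognition
setClass("Recognition", representation(text = "character", boxes = "data.frame"))

setMethod("show", "Recognition", function(object) {
    cat(sprintf("Recognition: \"%s\" (%d characters)\n",
        object@text, nrow(object@boxes)))
})

#' @rdname recognizeText
#' @param x a Recognition.
#' @export
recognizedText <- function(x) x@text

#' @rdname recognizeText
#' @export
recognitionBoxes <- function(x) x@boxes

#' PixelTrace: per-column trace position of one ECG row
#'
#' The column scan of a row-waveform group: for every column in the group's
#' span, the mean row index of its ink pixels, with NA marking gaps.
#'
#' @slot columns integer vector of column indices (contiguous span).
#' @slot rowIndex numeric vector, mean ink row per column (NA = gap).
#' @slot filled logical vector, TRUE where a gap was interpolated.
#' @slot groupId integer(1), source row group.
#' @exportClass PixelTrace
setClass("PixelTrace", representation(
    columns = "integer",
    rowIndex = "numeric",
    filled = "logical",
    groupId = "integer"
))

setValidity("PixelTrace", function(object) {
    n <- length(object@columns)
    if (length(object@rowIndex) != n || length(object@filled) != n)
        return("columns, rowIndex and filled must have equal length")
    if (n > 1 && any(diff(object@columns) != 1L))
        return("columns must form a contiguous span")
    TRUE
})

setMethod("show", "PixelTrace", function(object) {
    cat(sprintf("PixelTrace: columns %d..%d, %d gaps, %d filled\n",
        min(object@columns), max(object@columns),
        sum(is.na(object@rowIndex)), sum(object@filled)))
})

#' DigitizedSignal: one lead's calibrated voltage-time series
#'
#' @slot lead lead name (e.g. "II", "V5").
#' @slot time numeric vector, seconds, strictly increasing, uniform.
#' @slot voltage numeric vector, millivolts.
#' @slot interpolated logical vector, TRUE where the source column was a gap
#'   bridged by interpolation (including character-removal gaps).
#' @slot samplingInterval numeric(1), seconds between samples.
#' @slot provenance list (record id, row index, threshold, parameters, ...).
#' @exportClass DigitizedSignal
setClass("DigitizedSignal", representation(
    lead = "character",
    time = "numeric",
    voltage = "numeric",
    interpolated = "logical",
    samplingInterval = "numeric",
    provenance = "list"
))

setValidity("DigitizedSignal", function(object) {
    n <- length(object@time)
    if (length(object@voltage) != n || length(object@interpolated) != n)
        return("time, voltage and interpolated must have equal length")
    if (n > 1) {
        dt <- diff(object@time)
        if (any(dt <= 0)) return("time must be strictly increasing")
        if (max(abs(dt - object@samplingInterval)) > 1e-9)
            return("time must be uniformly spaced at samplingInterval")
    }
    if (any(!is.finite(object@voltage)))
        return("voltages must be finite")
    TRUE
})

#' @rdname calibrateTrace
#' @param x a DigitizedSignal.
#' @export
signalTime <- function(x) x@time

#' @rdname calibrateTrace
#' @export
signalVoltage <- function(x) x@voltage

#' @rdname calibrateTrace
#' @export
signalLead <- function(x) x@lead

setMethod("show", "DigitizedSignal", function(object) {
    cat(sprintf(
        "DigitizedSignal lead %s: %d samples @ %.2f ms, %.3f..%.3f mV\n",
        object@lead, length(object@time), object@samplingInterval * 1000,
        min(object@voltage), max(object@voltage)))
})

#' As data.frame: one row per sample
#' @param x a DigitizedSignal.
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.DigitizedSignal <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
    data.frame(time_s = x@time, voltage_mV = x@voltage,
        interpolated = x@interpolated)
}

#' TemplateSpec: one vendor's fixed page layout
#'
#' Everything the pipeline needs to know about a particular ECG machine's
#' printout: where the demographic block and the waveform block sit, how many
#' trace rows to expect, where lead labels are printed, and the calibration
#' conventions (paper speed, gain, grid pitch, DC pulse amplitude/duration).
#' Rectangles are 1-based closed intervals \code{c(top, left, bottom, right)}
#' on the canvas.
#'
#' @slot vendor character(1).
#' @slot canvas integer(2), (rows, cols) of the page at \code{dpi}.
#' @slot dpi numeric(1).
#' @slot demographicRegion integer(4) rectangle (may be zero-height).
#' @slot waveformRegion integer(4) rectangle.
#' @slot rows integer(1), expected number of trace rows.
#' @slot leadRois data.frame: name, top, left, bottom, right.
#' @slot demographicRois data.frame: field, top, left, bottom, right.
#' @slot calibration list: paperSpeed (mm/s), gain (mm/mV), gridPitch (mm),
#'   dcAmplitude (mV), dcDuration (s); plus \code{assumed}, the names of any
#'   constants filled from conventional defaults rather than the template
#'   file.
#' @slot standardImagePath character(1) or NA; reference scan for ROI
#'   realignment.
#' @exportClass TemplateSpec
setClass("TemplateSpec", representation(
    vendor = "character",
    canvas = "integer",
    dpi = "numeric",
    demographicRegion = "integer",
    waveformRegion = "integer",
    rows = "integer",
    leadRois = "data.frame",
    demographicRois = "data.frame",
    calibration = "list",
    standardImagePath = "character"
))

.rectOk <- function(r, canvas, allowEmpty = FALSE) {
    if (length(r) != 4L) return(FALSE)
    if (allowEmpty && r[3] < r[1]) return(TRUE)
    r[1] >= 1L && r[2] >= 1L && r[3] >= r[1] && r[4] >= r[2] &&
        r[3] <= canvas[1] && r[4] <= canvas[2]
}

setValidity("TemplateSpec", function(object) {
    cv <- object@canvas
    if (length(cv) != 2L || any(cv < 1L)) return("canvas must be positive")
    if (object@rows < 1L) return("expected row count must be >= 1")
    if (!.rectOk(object@demographicRegion, cv, allowEmpty = TRUE))
        return("demographicRegion outside canvas")
    if (!.rectOk(object@waveformRegion, cv))
        return("waveformRegion outside canvas")
    dr <- object@demographicRegion; wr <- object@waveformRegion
    if (dr[3] >= dr[1]) {  # non-empty demographic block
        if (!(dr[3] < wr[1] || wr[3] < dr[1]))
            return("demographicRegion and waveformRegion overlap (rows)")
    }
    need <- c("paperSpeed", "gain", "gridPitch", "dcAmplitude", "dcDuration")
    miss <- setdiff(need, names(object@calibration))
    if (length(miss))
        return(paste("calibration missing:", paste(miss, collapse = ", ")))
    vals <- unlist(object@calibration[need])
    if (any(!is.finite(vals)) || any(vals <= 0))
        return("calibration constants must be positive")
    for (nm in c("leadRois", "demographicRois")) {
        df <- slot(object, nm)
        if (nrow(df)) {
            bad <- !(df$top >= 1 & df$left >= 1 & df$bottom >= df$top &
                     df$right >= df$left & df$bottom <= cv[1] &
                     df$right <= cv[2])
            if (any(bad))
                return(sprintf("%s: ROI '%s' outside canvas or degenerate",
                    nm, df[[1]][which(bad)[1]]))
        }
    }
    TRUE
})

setMethod("show", "TemplateSpec", function(object) {
    cat(sprintf(
        "TemplateSpec '%s': %d x %d px @ %.0f dpi, %d rows, %d lead ROIs\n",
        object@vendor, object@canvas[1], object@canvas[2], object@dpi,
        object@rows, nrow(object@leadRois)))
    cal <- object@calibration
    cat(sprintf("  calibration: %.0f mm/s, %.0f mm/mV, grid %.1f mm, DC %.1f mV x %.2f s\n",
        cal$paperSpeed, cal$gain, cal$gridPitch, cal$dcAmplitude,
        cal$dcDuration))
})

#' GroundTruthManifest: everything the synthetic renderer knows
#'
#' Sidecar truth for a rendered record: per-row continuous ground-truth
#' samples, the true skew, glyph placements, the calibration constants
#' actually used, and the ideal (threshold-free) binary trace mask.  Round
#' trips losslessly through JSON via \code{\link{writeManifest}} /
#' \code{\link{readManifest}}.
#'
#' @slot rows list, one entry per trace row with elements: \code{baselineRow},
#'   \code{pulseCols} (first, last), \code{pulseHeightPx}, \code{signalCols}
#'   (first, last), \code{time} (s), \code{mV}.
#' @slot skew numeric(1), degrees applied at render time.
#' @slot glyphs data.frame: char, row (trace row or NA for demographics),
#'   top, left, bottom, right, overlap (logical).
#' @slot calibration list: dpi, paperSpeed, gain, gridPitch, dcAmplitude,
#'   dcDuration, pxPerMm, pxPerMv, pxPerSec.
#' @slot idealMask integer matrix (n x 2) of (row, col) trace-ink pixels in
#'   the unrotated canvas.
#' @slot glyphPixels integer matrix (n x 2) of (row, col) glyph-ink pixels in
#'   the unrotated canvas (lead labels and demographic text).
#' @slot canvas integer(2).
#' @slot demographics named list of rendered demographic strings.
#' @exportClass GroundTruthManifest
setClass("GroundTruthManifest", representation(
    rows = "list",
    skew = "numeric",
    glyphs = "data.frame",
    calibration = "list",
    idealMask = "matrix",
    glyphPixels = "matrix",
    canvas = "integer",
    demographics = "list"
))

setMethod("show", "GroundTruthManifest", function(object) {
    cat(sprintf(
        "GroundTruthManifest: %d rows, skew %.2f deg, %d glyphs, %d ideal ink px\n",
        length(object@rows), object@skew, nrow(object@glyphs),
        nrow(object@idealMask)))
})
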