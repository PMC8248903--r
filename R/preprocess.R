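# Step A: grayscale conversion, optional downscaling, Hough-based deskewing,
# region partition, histogram thresholding, speck filtering, gap bridging.

#' Convert a scan to 8-bit grayscale
#'
#' Colour scans are combined with the ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale input is returned unchanged.
#'
#' @param image an \linkS4class{ECGImage}.
#' @return a grayscale \linkS4class{ECGImage}.
#' @examples
#' a <- array(c(200, 10, 50), c(1, 1, 3))
#' imageData(toGrayscale(ECGImage(a, dpi = 300)))
#' @export
toGrayscale <- function(image) {
    stopIfNot(length(imageData(image)) > 0, "input error: empty image")
    if (!isColor(image)) return(image)
    d <- imageData(image)
    g <- 0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
    g <- matrix(round(g), dim(d)[1], dim(d)[2])
    ECGImage(g, dpi = imageDpi(image), origin = image@origin)
}

#' Downscale a scan to a target resolution
#'
#' Dimensions scale by \code{targetDpi / dpi} (rounded); bilinear resampling.
#' An upscaling request is refused: the image is returned unchanged with a
#' warning.
#'
#' @param image a grayscale \linkS4class{ECGImage}.
#' @param targetDpi desired resolution, <= the image's dpi.
#' @return an \linkS4class{ECGImage} at \code{targetDpi}.
#' @export
downscaleToDpi <- function(image, targetDpi) {
    if (targetDpi > imageDpi(image)) {
        warning("upscaling refused; image returned unchanged")
        return(image)
    }
    if (targetDpi == imageDpi(image)) return(image)
    d <- imageData(image)
    f <- targetDpi / imageDpi(image)
    nr <- max(1L, round(nrow(d) * f)); nc <- max(1L, round(ncol(d) * f))
    out <- as.matrix(EBImage::resize(d, w = nr, h = nc, filter = "bilinear"))
    ECGImage(pmin(pmax(out, 0), 255), dpi = targetDpi, origin = image@origin)
}

# Radon/Hough accumulator sharpness for the near-horizontal line family at
# one candidate angle: project dark pixels onto rho = row cos(a) + col sin(a)
# and score how concentrated the votes are.
.houghScore <- function(r, cc, angleDeg) {
    a <- angleDeg * pi / 180
    rho <- r * cos(a) + cc * sin(a)
    counts <- tabulate(as.integer(round(rho - min(rho))) + 1L)
    list(energy = sum(as.numeric(counts)^2), peak = max(counts))
}

#' Estimate page skew from the background grid
#'
#' A Hough-transform vote over the near-horizontal line family: dark pixels
#' (grid and ink) are projected onto candidate line orientations and the
#' orientation whose accumulator is sharpest is the grid direction.  Search
#' is restricted to +/- 15 degrees (coarse 0.5-degree sweep, then a 0.05-degree
#' refinement); a scan skewed further than that is treated as misfed.
#'
#' @param image a grayscale \linkS4class{ECGImage} containing a visible grid.
#' @param maxAngle search half-range, degrees.
#' @param maxPixels cap on voting pixels (deterministic thinning).
#' @return a \linkS4class{SkewEstimate}; positive angles mean grid lines
#'   rise with increasing column.
#' @export
estimateSkew <- function(image, maxAngle = 15, maxPixels = 150000L) {
    d <- imageData(image)
    stopIfNot(!isColor(image), "estimateSkew expects a grayscale image")
    cut <- quantile(d, 0.5) - 20
    idx <- which(d < cut, arr.ind = TRUE)
    if (nrow(idx) < 500L)
        stop("no grid detected: too few line pixels", call. = FALSE)
    if (nrow(idx) > maxPixels)
        idx <- idx[seq(1L, nrow(idx), length.out = maxPixels), , drop = FALSE]
    r <- idx[, 1]; cc <- idx[, 2]
    coarse <- seq(-maxAngle, maxAngle, by = 0.5)
    eCoarse <- vapply(coarse, function(a) .houghScore(r, cc, a)$energy, 0)
    best <- coarse[which.max(eCoarse)]
    fine <- seq(best - 0.6, best + 0.6, by = 0.05)
    fine <- fine[abs(fine) <= maxAngle + 0.6]
    sFine <- lapply(fine, function(a) .houghScore(r, cc, a))
    eFine <- vapply(sFine, `[[`, 0, "energy")
    k <- which.max(eFine)
    peakFrac <- sFine[[k]]$peak / nrow(idx)
    if (max(eCoarse) < 1.3 * median(eCoarse))
        stop("no grid detected: no dominant line family", call. = FALSE)
    new("SkewEstimate", angle = fine[k], support = peakFrac)
}

#' Rotate a scan back to axis alignment
#'
#' Rotates by the negated skew estimate about the image centre with bilinear
#' interpolation, keeping the canvas size and filling exposed corners with
#' the background (paper) intensity, so template coordinates stay valid.
#'
#' @param image a grayscale \linkS4class{ECGImage}.
#' @param est a \linkS4class{SkewEstimate} (or a bare angle in degrees).
#' @return the deskewed \linkS4class{ECGImage}.
#' @export
deskew <- function(image, est) {
    angle <- if (is(est, "SkewEstimate")) est@angle else est
    stopIfNot(abs(angle) < 45, "deskew requires |angle| < 45 degrees")
    if (angle == 0) return(image)
    d <- imageData(image)
    bg <- as.numeric(quantile(d, 0.9))
    ECGImage(rotateMatrix(d, -angle, bg = bg), dpi = imageDpi(image),
        origin = image@origin)
}

#' Split a record into demographic and waveform regions
#'
#' Crops the two template rectangles; each crop keeps its origin so template
#' coordinates (lead ROIs, demographic ROIs) can be mapped into it.
#'
#' @param image an \linkS4class{ECGImage} on the template's canvas.
#' @param template a \linkS4class{TemplateSpec}.
#' @return list with elements \code{demographic} (may have zero rows) and
#'   \code{waveform}, both \linkS4class{ECGImage}.
#' @export
partitionRegions <- function(image, template) {
    d <- imageData(image)
    wr <- template@waveformRegion; dr <- template@demographicRegion
    if (wr[3] > nrow(d) || wr[4] > ncol(d))
        stop("template error: waveform region outside image", call. = FALSE)
    wf <- ECGImage(d[wr[1]:wr[3], wr[2]:wr[4], drop = FALSE],
        dpi = imageDpi(image), origin = c(wr[1], wr[2]))
    dem <- if (dr[3] >= dr[1]) {
        if (dr[3] > nrow(d) || dr[4] > ncol(d))
            stop("template error: demographic region outside image",
                call. = FALSE)
        ECGImage(d[dr[1]:dr[3], dr[2]:dr[4], drop = FALSE],
            dpi = imageDpi(image), origin = c(dr[1], dr[2]))
    } else NULL
    list(demographic = dem, waveform = wf)
}

#' Automatic ink threshold from the histogram profile
#'
#' Smooths the 256-bin intensity histogram and seeks the valley between the
#' trace-ink mode (darkest) and the next mode to its right (grid or paper).
#' When no valley can be found the Otsu threshold is used and flagged.  A
#' manual override simply bypasses this function.
#'
#' @param region a grayscale \linkS4class{ECGImage}.
#' @return the threshold intensity, with attribute \code{method} equal to
#'   \code{"valley"} or \code{"otsu"}.
#' @export
autoThreshold <- function(region) {
    d <- imageData(region)
    stopIfNot(length(d) > 0, "region must be non-empty")
    h <- tabulate(as.integer(d) + 1L, nbins = 256L)
    # Gaussian smoothing, sigma 3 bins
    x <- -10:10
    kern <- exp(-x^2 / 18); kern <- kern / sum(kern)
    hs <- as.numeric(stats::filter(c(rep(0, 10), h, rep(0, 10)), kern,
        sides = 2))[11:266]
    floorCnt <- max(length(d) * 5e-4, 4)
    isPeak <- vapply(seq_along(hs), function(i) {
        lo <- max(1L, i - 5L); hi <- min(256L, i + 5L)
        hs[i] >= max(hs[lo:hi]) && hs[i] > floorCnt
    }, TRUE)
    peaks <- which(isPeak)
    # collapse neighbouring peaks: modes closer than 40 gray levels belong
    # to the same constituent (e.g. pure-black salt next to the ink mode)
    if (length(peaks) > 1) {
        grp <- cumsum(c(TRUE, diff(peaks) > 40))
        peaks <- vapply(split(peaks, grp),
            function(g) g[which.max(hs[g])], 0L)
    }
    if (length(peaks) < 2)
        stop("no trace found: intensity histogram is unimodal", call. = FALSE)
    inkPeak <- peaks[1]; nextPeak <- peaks[2]
    # valley = midpoint of the minimal plateau between the two modes
    seg <- hs[inkPeak:nextPeak]
    lows <- which(seg <= min(seg) + 1e-9)
    valley <- inkPeak + as.integer(round(mean(range(lows)))) - 1L
    thr <- valley - 1L  # bin index -> intensity
    method <- "valley"
    if (thr <= inkPeak - 1L || thr >= nextPeak - 1L) {
        thr <- round(EBImage::otsu(d / 255, range = c(0, 1)) * 255)
        method <- "otsu"
    }
    structure(as.numeric(thr), method = method)
}

#' Binarize a region at a threshold
#'
#' Ink is dark: the mask is TRUE where intensity is strictly below the
#' threshold.
#'
#' @param region a grayscale \linkS4class{ECGImage}.
#' @param threshold intensity in \[0, 256\].
#' @return a \linkS4class{BinaryMask} with the threshold in its provenance.
#' @export
binarize <- function(region, threshold) {
    stopIfNot(threshold >= 0 && threshold <= 256,
        "threshold must be within the 8-bit range")
    BinaryMask(imageData(region) < threshold, origin = region@origin,
        provenance = list(threshold = as.numeric(threshold),
            method = attr(threshold, "method")))
}

#' 3x3 majority (median) filter for binary masks
#'
#' Each output pixel takes the majority value of its 3x3 neighbourhood; at
#' the borders the window shrinks to the pixels that exist.  On a binary
#' mask the median and the majority coincide; isolated salt/pepper pixels
#' are removed while solid regions are preserved.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @return the filtered \linkS4class{BinaryMask}.
#' @export
medianFilterMask <- function(mask) {
    m <- maskData(mask) * 1
    k <- matrix(1, 3, 3)
    s <- slideSum(m, k)
    n <- slideSum(matrix(1, nrow(m), ncol(m)), k)
    BinaryMask(2 * s > n, origin = mask@origin,
        provenance = c(mask@provenance, list(medianFilter = "3x3 majority")))
}

#' Bridge short horizontal gaps in the trace
#'
#' One-dimensional horizontal morphological closing with a kernel of
#' \code{kernelLength} pixels: runs of background shorter than the kernel
#' that are flanked by ink in the same row are filled.  The result is then
#' united with the input, so the operation never loses ink pixels, and it is
#' idempotent at a fixed kernel.
#'
#' @param mask a \linkS4class{BinaryMask}.
#' @param kernelLength odd integer >= 1.
#' @return the bridged \linkS4class{BinaryMask}.
#' @export
bridgeGaps <- function(mask, kernelLength = 5L) {
    stopIfNot(kernelLength >= 1 && kernelLength %% 2 == 1,
        "kernelLength must be odd and >= 1")
    m <- maskData(mask)
    if (kernelLength > ncol(m))
        kernelLength <- max(1L, ncol(m) - (1L - ncol(m) %% 2L))
    if (kernelLength > 1L) {
        k <- matrix(1, 1, kernelLength)
        dil <- slideSum(m * 1, k) > 0.5
        ero <- slideSum(dil * 1, k) > kernelLength - 0.5
        m <- m | ero
    }
    BinaryMask(m, origin = mask@origin,
        provenance = c(mask@provenance,
            list(bridgeKernel = as.integer(kernelLength))))
}

#' Measure the background grid pitch
#'
#' Autocorrelation of the dark-pixel row profile: the fundamental lag of the
#' horizontal grid-line family is the pitch in pixels.
#'
#' @param image a grayscale \linkS4class{ECGImage} containing a grid.
#' @param maxPitchPx largest pitch considered, px.
#' @return pitch in pixels (fractional, by parabolic peak interpolation).
#' @export
measureGridPitch <- function(image, maxPitchPx = 200L) {
    d <- imageData(image)
    cut <- quantile(d, 0.5) - 20
    p <- rowSums(d < cut)
    p <- p - mean(p)
    n <- length(p)
    maxLag <- min(maxPitchPx, floor(n / 3))
    ac <- vapply(1:maxLag, function(L)
        sum(p[1:(n - L)] * p[(1 + L):n]), 0)
    # skip the short-range ink-thickness correlation: start searching after
    # the profile first decorrelates, then take the first strong peak
    k0 <- which(ac < 0)[1]
    if (is.na(k0)) k0 <- which(diff(ac) > 0)[1] %||% 2L
    glob <- max(ac[k0:maxLag])
    cand <- which(ac >= 0.8 * glob & seq_along(ac) >= k0)
    k <- cand[1]
    while (k < maxLag && ac[k + 1] > ac[k]) k <- k + 1
    if (k <= 1 || k >= maxLag) return(as.numeric(k))
    # parabolic interpolation around the peak
    y0 <- ac[k - 1]; y1 <- ac[k]; y2 <- ac[k + 1]
    k + 0.5 * (y0 - y2) / (y0 - 2 * y1 + y2)
}
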