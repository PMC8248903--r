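# Synthetic paper-ECG record renderer with exhaustive ground truth.
#
# Each heartbeat is a sum of five Gaussian bumps (P, Q, R, S, T); the page is
# composed as paper background, a regular grid, one trace per row preceded by
# a rectangular DC calibration pulse, printed lead labels (optionally
# overlapping the trace) and demographic text, then degraded in the fixed
# order rotate -> fade -> salt-and-pepper.

#' Waveform synthesis parameters
#'
#' One heartbeat is modelled as a sum of Gaussian bumps, one per named wave.
#' Defaults give a plausible sinus-rhythm morphology at 75 bpm: amplitudes in
#' mV, centers as offsets (s) from the beat start, widths as Gaussian sigma
#' (s).
#'
#' @param beatsPerRow complete beats rendered per row.
#' @param beatPeriod beat-to-beat period, seconds.
#' @param amplitudes named numeric (P, Q, R, S, T), mV.
#' @param centers named numeric, offsets within one beat, seconds.
#' @param widths named numeric, Gaussian sigma per wave, seconds.
#' @param baselineDriftAmplitude slow sinusoidal baseline wander, mV.
#' @return a validated list of class \code{WaveformParams}.
#' @examples
#' p <- waveformParams()
#' p$amplitudes[["R"]]
#' @export
waveformParams <- function(beatsPerRow = 3L,
                           beatPeriod = 0.8,
                           amplitudes = c(P = 0.15, Q = -0.12, R = 1.0,
                                          S = -0.25, T = 0.3),
                           centers = c(P = 0.16, Q = 0.27, R = 0.30,
                                       S = 0.33, T = 0.52),
                           widths = c(P = 0.025, Q = 0.012, R = 0.016,
                                      S = 0.014, T = 0.045),
                           baselineDriftAmplitude = 0.05) {
    stopIfNot(beatPeriod > 0, "beatPeriod must be positive")
    stopIfNot(beatsPerRow >= 1, "beatsPerRow must be at least 1")
    waves <- c("P", "Q", "R", "S", "T")
    stopIfNot(all(waves %in% names(amplitudes)) &&
              all(waves %in% names(centers)) &&
              all(waves %in% names(widths)),
        "amplitudes, centers and widths must name all of P, Q, R, S, T")
    stopIfNot(all(widths[waves] > 0), "wave widths must be positive")
    stopIfNot(all(centers[waves] >= 0) && all(centers[waves] <= beatPeriod),
        "wave centers must lie within one beat period")
    structure(list(beatsPerRow = as.integer(beatsPerRow),
                   beatPeriod = beatPeriod,
                   amplitudes = amplitudes[waves],
                   centers = centers[waves],
                   widths = widths[waves],
                   baselineDriftAmplitude = baselineDriftAmplitude),
              class = "WaveformParams")
}

# Evaluate one row's continuous waveform (mV) at times t (s from row start).
.evalRow <- function(params, driftPhase, t) {
    v <- numeric(length(t))
    for (b in seq_len(params$beatsPerRow)) {
        t0 <- (b - 1L) * params$beatPeriod
        for (w in names(params$amplitudes)) {
            v <- v + params$amplitudes[[w]] *
                exp(-((t - t0 - params$centers[[w]])^2) /
                    (2 * params$widths[[w]]^2))
        }
    }
    dur <- params$beatsPerRow * params$beatPeriod
    if (params$baselineDriftAmplitude != 0)
        v <- v + params$baselineDriftAmplitude *
            sin(2 * pi * t / dur + driftPhase)
    v
}

#' Generate per-row ground-truth waveform samples
#'
#' Synthesizes \code{nRows} row waveforms from one parameter set.  Rows share
#' the beat morphology and differ only in the random phase of the baseline
#' wander, drawn deterministically from \code{seed}.  Samples are returned on
#' a uniform time grid of spacing \code{dt}; the continuous model is kept so
#' the renderer can re-evaluate it at arbitrary times.
#'
#' @param params a \code{\link{waveformParams}} object.
#' @param nRows number of rows to synthesize.
#' @param seed integer seed; identical inputs give identical samples.
#' @param dt sample spacing, seconds.
#' @return an \code{ECGWaveforms} list: \code{params}, \code{dt}, \code{t}
#'   (time grid), \code{rows} (list with \code{driftPhase} and \code{mv} per
#'   row).
#' @examples
#' w <- generateWaveform(waveformParams(), nRows = 2, seed = 1)
#' range(w$rows[[1]]$mv)
#' @export
generateWaveform <- function(params, nRows, seed, dt = 0.002) {
    stopIfNot(inherits(params, "WaveformParams"),
        "params must come from waveformParams()")
    stopIfNot(nRows >= 1, "nRows must be at least 1")
    stopIfNot(dt > 0, "dt must be positive")
    dur <- params$beatsPerRow * params$beatPeriod
    t <- seq(0, dur, by = dt)
    phases <- withSeed(seed, runif(nRows, 0, 2 * pi))
    if (params$baselineDriftAmplitude == 0) phases[] <- 0
    rows <- lapply(seq_len(nRows), function(i)
        list(driftPhase = phases[i],
             mv = .evalRow(params, phases[i], t)))
    structure(list(params = params, dt = dt, t = t, rows = rows),
              class = "ECGWaveforms")
}

#' Evaluate a generated waveform row at arbitrary times
#'
#' @param waves an \code{ECGWaveforms} object from
#'   \code{\link{generateWaveform}}.
#' @param row row index.
#' @param t times in seconds from the row start.
#' @return voltages in mV.
#' @export
waveformValue <- function(waves, row, t) {
    .evalRow(waves$params, waves$rows[[row]]$driftPhase, t)
}

#' Rendering configuration for the synthetic record
#'
#' Defaults follow conventional ECG printing: 25 mm/s paper speed, 10 mm/mV
#' gain, 5 mm grid, a 1 mV x 0.2 s DC calibration pulse, 300 DPI.
#'
#' @param dpi render resolution, pixels per inch.
#' @param paperSpeed mm/s.
#' @param gain mm/mV.
#' @param gridPitch grid line spacing, mm.
#' @param dcAmplitude DC pulse amplitude, mV.
#' @param dcDuration DC pulse duration, s.
#' @param skewAngle page rotation applied after composition, degrees
#'   (positive = grid lines rise with increasing column).
#' @param saltPepperProb per-pixel probability of a salt/pepper flip.
#' @param fadeFactor foreground contrast multiplier in (0, 1\]; 1 = no fade.
#' @param labels data.frame of lead-label placements: \code{text},
#'   \code{row} (trace row), \code{colOffset} (px right of the signal
#'   start), \code{overlap} (logical; TRUE prints the label on the
#'   baseline so it crosses the trace).
#' @param demographics named list of strings printed into the template's
#'   demographic field ROIs.
#' @param strokeWidth trace/glyph ink thickness, px (the ink thickness of
#'   the simulated printer is not standardized; exposed as a parameter).
#' @param glyphScale integer magnification of the built-in 5x7 font.
#' @param inkIntensity,gridIntensity,paperIntensity 8-bit gray levels of the
#'   three page constituents (darker to lighter).
#' @param seed integer seed driving all stochastic degradation.
#' @return a validated list of class \code{RenderConfig}.
#' @export
renderConfig <- function(dpi = 300,
                         paperSpeed = 25,
                         gain = 10,
                         gridPitch = 5,
                         dcAmplitude = 1,
                         dcDuration = 0.2,
                         skewAngle = 0,
                         saltPepperProb = 0,
                         fadeFactor = 1,
                         labels = NULL,
                         demographics = list(),
                         strokeWidth = 3L,
                         glyphScale = 3L,
                         inkIntensity = 20,
                         gridIntensity = 150,
                         paperIntensity = 240,
                         seed = 1L) {
    stopIfNot(dpi > 0, "dpi must be positive")
    stopIfNot(saltPepperProb >= 0 && saltPepperProb < 1,
        "saltPepperProb must be in [0, 1)")
    stopIfNot(fadeFactor > 0 && fadeFactor <= 1,
        "fadeFactor must be in (0, 1]")
    stopIfNot(all(c(paperSpeed, gain, gridPitch, dcAmplitude,
                    dcDuration) > 0), "calibration constants must be positive")
    stopIfNot(strokeWidth >= 1 && strokeWidth %% 2 == 1,
        "strokeWidth must be odd (symmetric ink spread)")
    if (is.null(labels))
        labels <- data.frame(text = character(0), row = integer(0),
            colOffset = integer(0), overlap = logical(0))
    structure(list(dpi = dpi, paperSpeed = paperSpeed, gain = gain,
        gridPitch = gridPitch, dcAmplitude = dcAmplitude,
        dcDuration = dcDuration, skewAngle = skewAngle,
        saltPepperProb = saltPepperProb, fadeFactor = fadeFactor,
        labels = labels, demographics = demographics,
        strokeWidth = as.integer(strokeWidth),
        glyphScale = as.integer(glyphScale),
        inkIntensity = inkIntensity, gridIntensity = gridIntensity,
        paperIntensity = paperIntensity, seed = as.integer(seed)),
        class = "RenderConfig")
}

# Shared page geometry: where each row's trace starts and sits vertically.
.recordGeometry <- function(template, cfg) {
    pxmm <- pxPerMm(template@dpi)
    pxps <- pxmm * cfg$paperSpeed
    wr <- template@waveformRegion
    bandH <- (wr[3] - wr[1] + 1L) / template@rows
    baselines <- round(wr[1] + (seq_len(template@rows) - 0.5) * bandH)
    traceLeft <- wr[2] + 40L
    nLead <- round(0.05 * pxps)
    nPulse <- round(cfg$dcDuration * pxps)
    nPost <- round(0.05 * pxps)
    list(pxmm = pxmm, pxps = pxps, pxmv = cfg$gain * pxmm,
         baselines = baselines, bandH = bandH,
         traceLeft = traceLeft,
         pulseFirst = traceLeft + nLead,
         pulseLast = traceLeft + nLead + nPulse - 1L,
         signalFirst = traceLeft + nLead + nPulse + nPost)
}

# Placement box of one label bitmap (top-left corner + dims), pre-rotation.
.labelPlacement <- function(template, cfg, text, row, colOffset, overlap) {
    g <- .recordGeometry(template, cfg)
    bmp <- renderText(text, cfg$glyphScale)
    b <- g$baselines[row]
    top <- if (isTRUE(overlap)) b - floor(nrow(bmp) / 2)
           else b - round(0.38 * g$bandH) - floor(nrow(bmp) / 2)
    left <- g$signalFirst + colOffset
    list(top = as.integer(top), left = as.integer(left),
         height = nrow(bmp), width = ncol(bmp), bitmap = bmp)
}

#' Build a vendor template matching the synthetic renderer's layout
#'
#' Computes canvas size and region boundaries from the waveform and render
#' parameters, and derives lead-label ROIs (with a small padding margin) from
#' the label placements, so that a record rendered with the same arguments
#' can be digitized end-to-end using this template.
#'
#' @param params a \code{\link{waveformParams}} object.
#' @param cfg a \code{\link{renderConfig}} object.
#' @param nRows number of trace rows.
#' @param rowSpacingMm vertical space allotted per row, mm.
#' @param demographicFields character vector of demographic field names; ROIs
#'   are stacked in the demographic block (empty vector = no block).
#' @return a \linkS4class{TemplateSpec}.
#' @examples
#' tpl <- makeSyntheticTemplate(waveformParams(), renderConfig(), nRows = 2)
#' tpl
#' @export
makeSyntheticTemplate <- function(params, cfg, nRows,
                                  rowSpacingMm = 25,
                                  demographicFields = character(0)) {
    pxmm <- pxPerMm(cfg$dpi)
    pxps <- pxmm * cfg$paperSpeed
    dur <- params$beatsPerRow * params$beatPeriod
    nSig <- round(dur * pxps)
    traceCols <- 40L + round(0.05 * pxps) + round(cfg$dcDuration * pxps) +
        round(0.05 * pxps) + nSig
    width <- as.integer(30L + traceCols + 70L)
    demH <- if (length(demographicFields))
        as.integer(40L + length(demographicFields) * (7L * cfg$glyphScale + 16L))
        else 0L
    wfTop <- demH + 30L
    wfH <- as.integer(round(nRows * rowSpacingMm * pxmm))
    height <- as.integer(wfTop + wfH + 30L)
    demRois <- if (length(demographicFields)) {
        lineH <- 7L * cfg$glyphScale + 16L
        data.frame(field = demographicFields,
            top = as.integer(20L + (seq_along(demographicFields) - 1L) * lineH),
            left = 40L,
            bottom = as.integer(20L + seq_along(demographicFields) * lineH - 9L),
            right = as.integer(width - 40L))
    } else data.frame(field = character(0), top = integer(0),
        left = integer(0), bottom = integer(0), right = integer(0))
    tpl <- new("TemplateSpec",
        vendor = "synthetic",
        canvas = c(height, width),
        dpi = cfg$dpi,
        demographicRegion = c(1L, 1L, demH, width),
        waveformRegion = c(as.integer(wfTop + 1L), 16L,
                           as.integer(wfTop + wfH), as.integer(width - 15L)),
        rows = as.integer(nRows),
        leadRois = data.frame(name = character(0), top = integer(0),
            left = integer(0), bottom = integer(0), right = integer(0)),
        demographicRois = demRois,
        calibration = list(paperSpeed = cfg$paperSpeed, gain = cfg$gain,
            gridPitch = cfg$gridPitch, dcAmplitude = cfg$dcAmplitude,
            dcDuration = cfg$dcDuration, assumed = character(0)),
        standardImagePath = NA_character_)
    if (nrow(cfg$labels)) {
        pad <- 4L
        rois <- do.call(rbind, lapply(seq_len(nrow(cfg$labels)), function(i) {
            lb <- cfg$labels[i, ]
            p <- .labelPlacement(tpl, cfg, lb$text, lb$row, lb$colOffset,
                lb$overlap)
            data.frame(name = lb$text,
                top = p$top - pad, left = p$left - pad,
                bottom = p$top + p$height - 1L + pad,
                right = p$left + p$width - 1L + pad)
        }))
        tpl@leadRois <- rois
    }
    validObject(tpl)
    tpl
}

#' Render a synthetic paper-ECG record
#'
#' Composes paper background, grid, per-row traces (each preceded by a DC
#' calibration pulse), lead labels and demographic text; then applies the
#' degradations in the fixed order rotate -> fade -> salt-and-pepper.  The
#' returned manifest records the continuous ground truth per row, the true
#' skew, every glyph placement and pixel, the calibration actually used, and
#' the ideal (pre-degradation) trace mask.
#'
#' @param waves an \code{ECGWaveforms} object from
#'   \code{\link{generateWaveform}}.
#' @param cfg a \code{\link{renderConfig}} object.
#' @param template a \linkS4class{TemplateSpec} whose row count matches
#'   \code{waves}.
#' @return list with elements \code{image} (\linkS4class{ECGImage}) and
#'   \code{manifest} (\linkS4class{GroundTruthManifest}).
#' @examples
#' p <- waveformParams(); cfg <- renderConfig(dpi = 150)
#' tpl <- makeSyntheticTemplate(p, cfg, nRows = 1)
#' rec <- renderRecord(generateWaveform(p, 1, seed = 1), cfg, tpl)
#' rec$image
#' @export
renderRecord <- function(waves, cfg, template) {
    stopIfNot(inherits(waves, "ECGWaveforms"), "waves must be ECGWaveforms")
    stopIfNot(inherits(cfg, "RenderConfig"), "cfg must be a renderConfig()")
    stopIfNot(template@rows == length(waves$rows),
        "template row count must match the number of waveform rows")
    g <- .recordGeometry(template, cfg)
    H <- template@canvas[1]; W <- template@canvas[2]
    canvas <- matrix(cfg$paperIntensity, H, W)

    # grid over the waveform region
    wr <- template@waveformRegion
    pitch <- cfg$gridPitch * g$pxmm
    gridRows <- round(seq(wr[1], wr[3], by = pitch))
    gridCols <- round(seq(wr[2], wr[4], by = pitch))
    canvas[gridRows, wr[2]:wr[4]] <- pmin(canvas[gridRows, wr[2]:wr[4]],
        cfg$gridIntensity)
    canvas[wr[1]:wr[3], gridCols] <- pmin(canvas[wr[1]:wr[3], gridCols],
        cfg$gridIntensity)

    # per-row trace band: for each column the vertical span of the continuous
    # curve over that column's time interval (sub-column sampling), so
    # adjacent columns always connect without explicit joins
    traceMask <- matrix(FALSE, H, W)
    rowsMeta <- vector("list", length(waves$rows))
    nSig <- round(waves$params$beatsPerRow * waves$params$beatPeriod * g$pxps)
    pulseHeightPx <- round(cfg$dcAmplitude * g$pxmv)
    for (r in seq_along(waves$rows)) {
        b <- g$baselines[r]
        sigCols <- g$signalFirst:(g$signalFirst + nSig - 1L)
        tCenter <- (sigCols - g$signalFirst) / g$pxps
        sub <- 4L
        tt <- rep(tCenter, each = sub) +
            rep(seq(-0.5, 0.5, length.out = sub) / g$pxps, times = nSig)
        vv <- matrix(waveformValue(waves, r, tt), nrow = sub)
        vLo <- apply(vv, 2, min); vHi <- apply(vv, 2, max)
        yTop <- round(b - g$pxmv * vHi)
        yBot <- round(b - g$pxmv * vLo)
        for (i in seq_along(sigCols))
            traceMask[yTop[i]:yBot[i], sigCols[i]] <- TRUE
        # lead-in baseline, DC pulse (plateau + vertical strokes), post run
        traceMask[b, g$traceLeft:(g$pulseFirst - 1L)] <- TRUE
        pTop <- b - pulseHeightPx
        traceMask[pTop, g$pulseFirst:g$pulseLast] <- TRUE
        traceMask[pTop:b, g$pulseFirst] <- TRUE
        traceMask[pTop:b, g$pulseLast] <- TRUE
        traceMask[b, (g$pulseLast + 1L):(g$signalFirst - 1L)] <- TRUE
        rowsMeta[[r]] <- list(baselineRow = b,
            pulseCols = c(g$pulseFirst, g$pulseLast),
            pulseHeightPx = pulseHeightPx,
            signalCols = c(sigCols[1], sigCols[nSig]),
            time = tCenter,
            mv = waveformValue(waves, r, tCenter))
    }
    # ink thickness: square dilation to strokeWidth
    if (cfg$strokeWidth > 1L) {
        k <- matrix(1, cfg$strokeWidth, cfg$strokeWidth)
        traceMask <- slideSum(traceMask * 1, k) > 0.5
    }

    # lead labels
    glyphMask <- matrix(FALSE, H, W)
    glyphBoxes <- list()
    if (nrow(cfg$labels)) {
        for (i in seq_len(nrow(cfg$labels))) {
            lb <- cfg$labels[i, ]
            p <- .labelPlacement(template, cfg, lb$text, lb$row,
                lb$colOffset, lb$overlap)
            if (p$top < 1L || p$left < 1L || p$top + p$height - 1L > H ||
                p$left + p$width - 1L > W)
                stop(sprintf("render error: label '%s' outside canvas",
                    lb$text), call. = FALSE)
            rr <- p$top:(p$top + p$height - 1L)
            cc <- p$left:(p$left + p$width - 1L)
            glyphMask[rr, cc] <- glyphMask[rr, cc] | p$bitmap
            glyphBoxes[[length(glyphBoxes) + 1L]] <- data.frame(
                char = lb$text, row = lb$row, top = p$top, left = p$left,
                bottom = p$top + p$height - 1L,
                right = p$left + p$width - 1L, overlap = lb$overlap)
        }
    }

    # demographic text
    demo <- list()
    if (length(cfg$demographics) && nrow(template@demographicRois)) {
        for (i in seq_len(nrow(template@demographicRois))) {
            fld <- template@demographicRois$field[i]
            txt <- cfg$demographics[[fld]]
            if (is.null(txt)) next
            bmp <- renderText(txt, cfg$glyphScale)
            top <- template@demographicRois$top[i] + 4L
            left <- template@demographicRois$left[i] + 4L
            if (top + nrow(bmp) - 1L > H || left + ncol(bmp) - 1L > W)
                stop(sprintf("render error: demographic field '%s' outside canvas",
                    fld), call. = FALSE)
            rr <- top:(top + nrow(bmp) - 1L)
            cc <- left:(left + ncol(bmp) - 1L)
            glyphMask[rr, cc] <- glyphMask[rr, cc] | bmp
            glyphBoxes[[length(glyphBoxes) + 1L]] <- data.frame(
                char = txt, row = NA_integer_, top = top, left = left,
                bottom = top + nrow(bmp) - 1L, right = left + ncol(bmp) - 1L,
                overlap = FALSE)
            demo[[fld]] <- txt
        }
    }

    canvas[traceMask | glyphMask] <- pmin(canvas[traceMask | glyphMask],
        cfg$inkIntensity)

    # degradation: rotate -> fade -> salt-and-pepper
    if (cfg$skewAngle != 0)
        canvas <- rotateMatrix(canvas, cfg$skewAngle, bg = cfg$paperIntensity)
    img <- degradeImage(ECGImage(canvas, dpi = cfg$dpi),
        saltPepperProb = cfg$saltPepperProb,
        fadeFactor = cfg$fadeFactor, seed = cfg$seed)

    manifest <- new("GroundTruthManifest",
        rows = rowsMeta,
        skew = cfg$skewAngle,
        glyphs = if (length(glyphBoxes)) do.call(rbind, glyphBoxes)
            else data.frame(char = character(0), row = integer(0),
                top = integer(0), left = integer(0), bottom = integer(0),
                right = integer(0), overlap = logical(0)),
        calibration = list(dpi = cfg$dpi, paperSpeed = cfg$paperSpeed,
            gain = cfg$gain, gridPitch = cfg$gridPitch,
            dcAmplitude = cfg$dcAmplitude, dcDuration = cfg$dcDuration,
            pxPerMm = g$pxmm, pxPerMv = g$pxmv, pxPerSec = g$pxps),
        idealMask = which(traceMask, arr.ind = TRUE),
        glyphPixels = which(glyphMask, arr.ind = TRUE),
        canvas = c(H, W),
        demographics = demo)
    list(image = img, manifest = manifest)
}

#' Degrade a rendered record
#'
#' Fading multiplies foreground contrast by \code{fadeFactor} (intensities
#' move toward white); salt-and-pepper flips each pixel independently with
#' probability \code{saltPepperProb} to pure black or pure white (equal
#' odds), driven by \code{seed}.
#'
#' @param image an \linkS4class{ECGImage}.
#' @param saltPepperProb per-pixel flip probability in \[0, 1\].
#' @param fadeFactor contrast multiplier in (0, 1\].
#' @param seed integer seed.
#' @return a degraded \linkS4class{ECGImage}.
#' @export
degradeImage <- function(image, saltPepperProb = 0, fadeFactor = 1,
                         seed = 1L) {
    stopIfNot(saltPepperProb >= 0 && saltPepperProb <= 1,
        "saltPepperProb must be in [0, 1]")
    stopIfNot(fadeFactor > 0 && fadeFactor <= 1,
        "fadeFactor must be in (0, 1]")
    m <- imageData(image)
    if (fadeFactor < 1) m <- 255 - fadeFactor * (255 - m)
    if (saltPepperProb > 0) {
        n <- length(m)
        draw <- withSeed(seed, {
            flip <- runif(n) < saltPepperProb
            list(flip = flip, salt = runif(sum(flip)) < 0.5)
        })
        m[draw$flip] <- ifelse(draw$salt, 255, 0)
    }
    ECGImage(m, dpi = imageDpi(image), origin = image@origin)
}

#' Write a ground-truth manifest to its JSON sidecar
#'
#' @param manifest a \linkS4class{GroundTruthManifest}.
#' @param path output file (conventionally \code{<record>.truth.json}).
#' @return \code{path}, invisibly.
#' @export
writeManifest <- function(manifest, path) {
    x <- list(
        rows = lapply(manifest@rows, function(r) list(
            baselineRow = r$baselineRow, pulseCols = r$pulseCols,
            pulseHeightPx = r$pulseHeightPx, signalCols = r$signalCols,
            time = r$time, mv = r$mv)),
        skew = manifest@skew,
        glyphs = manifest@glyphs,
        calibration = manifest@calibration,
        idealMask = unname(manifest@idealMask),
        glyphPixels = unname(manifest@glyphPixels),
        canvas = manifest@canvas,
        demographics = manifest@demographics)
    jsonlite::write_json(x, path, digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' Read a ground-truth manifest back from JSON
#'
#' @param path the sidecar file written by \code{\link{writeManifest}}.
#' @return a \linkS4class{GroundTruthManifest}.
#' @export
readManifest <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE,
        simplifyDataFrame = FALSE)
    toMat <- function(m) {
        m <- if (!length(m)) matrix(integer(0), 0, 2)
             else if (is.matrix(m)) m
             else do.call(rbind, m)
        storage.mode(m) <- "integer"
        colnames(m) <- c("row", "col")
        m
    }
    glyphs <- if (length(x$glyphs))
        do.call(rbind, lapply(x$glyphs, function(g) data.frame(
            char = g$char, row = if (is.null(g$row) || is.na(g$row))
                NA_integer_ else as.integer(g$row),
            top = as.integer(g$top), left = as.integer(g$left),
            bottom = as.integer(g$bottom), right = as.integer(g$right),
            overlap = as.logical(g$overlap))))
        else data.frame()
    if (!nrow(glyphs))
        glyphs <- data.frame(char = character(0), row = integer(0),
            top = integer(0), left = integer(0), bottom = integer(0),
            right = integer(0), overlap = logical(0))
    new("GroundTruthManifest",
        rows = lapply(x$rows, function(r) list(
            baselineRow = as.numeric(r$baselineRow),
            pulseCols = as.numeric(r$pulseCols),
            pulseHeightPx = as.numeric(r$pulseHeightPx),
            signalCols = as.numeric(r$signalCols),
            time = as.numeric(r$time), mv = as.numeric(r$mv))),
        skew = as.numeric(x$skew),
        glyphs = glyphs,
        calibration = as.list(x$calibration),
        idealMask = toMat(x$idealMask),
        glyphPixels = toMat(x$glyphPixels),
        canvas = as.integer(x$canvas),
        demographics = as.list(x$demographics))
}

#' Rasterize the manifest's ideal trace mask
#'
#' @param manifest a \linkS4class{GroundTruthManifest}.
#' @return a \linkS4class{BinaryMask} on the unrotated canvas.
#' @export
idealTraceMask <- function(manifest) {
    m <- matrix(FALSE, manifest@canvas[1], manifest@canvas[2])
    m[manifest@idealMask] <- TRUE
    BinaryMask(m, provenance = list(source = "ground-truth manifest"))
}
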