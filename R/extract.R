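# Step D: column scanning, gap interpolation, DC-pulse detection, and
# conversion to calibrated voltage-time pairs.

#' Calibration constants for voltage-time conversion
#'
#' @param pxPerMm pixels per millimetre (from DPI or measured grid pitch).
#' @param paperSpeed mm/s.
#' @param gain mm/mV (used only when no DC pulse is available).
#' @param dcAmplitude DC pulse amplitude, mV.
#' @param pulseHeightPx measured pulse height, px (from
#'   \code{\link{detectDcPulse}}).
#' @param baselineRow isoelectric reference row, px.
#' @return a list of class \code{CalibrationConstants}.
#' @export
calibrationConstants <- function(pxPerMm, paperSpeed = 25, gain = 10,
                                 dcAmplitude = 1, pulseHeightPx = NA,
                                 baselineRow = NA) {
    stopIfNot(pxPerMm > 0 && paperSpeed > 0 && gain > 0 && dcAmplitude > 0,
        "calibration constants must be positive")
    structure(list(pxPerMm = pxPerMm, paperSpeed = paperSpeed, gain = gain,
        dcAmplitude = dcAmplitude, pulseHeightPx = pulseHeightPx,
        baselineRow = baselineRow), class = "CalibrationConstants")
}

#' Column-scan a row waveform group into a pixel trace
#'
#' For every column in the group's span, the mean of the ink pixels' row
#' indices (the printed trace has thickness; the mean collapses it to a
#' curve).  Columns without ink are marked as gaps (NA).
#'
#' @param group a \linkS4class{RowWaveforms} object and row index, or an
#'   integer (row, col) pixel matrix.
#' @param row row index when \code{group} is a \linkS4class{RowWaveforms}.
#' @return a \linkS4class{PixelTrace}.
#' @examples
#' px <- cbind(row = c(10, 11, 12, 40), col = c(5, 5, 5, 6))
#' columnScan(px)
#' @export
columnScan <- function(group, row = 1L) {
    px <- if (is(group, "RowWaveforms")) rowPixels(group, row) else group
    stopIfNot(nrow(px) > 0, "group must be non-empty")
    cols <- min(px[, 2]):max(px[, 2])
    mean_by_col <- tapply(px[, 1], factor(px[, 2], levels = cols), mean)
    new("PixelTrace", columns = as.integer(cols),
        rowIndex = as.numeric(mean_by_col),
        filled = logical(length(cols)),
        groupId = as.integer(if (is(group, "RowWaveforms")) row else 1L))
}

#' Fill gaps in a pixel trace by linear interpolation
#'
#' Interior gaps are bridged linearly between the flanking defined columns;
#' leading and trailing gaps take the nearest defined value.  Filled columns
#' are flagged.  Idempotent.
#'
#' @param trace a \linkS4class{PixelTrace}.
#' @return the gap-free \linkS4class{PixelTrace}.
#' @export
interpolateGaps <- function(trace) {
    y <- trace@rowIndex
    def <- which(!is.na(y))
    stopIfNot(length(def) >= 2L,
        "extraction error: fewer than 2 defined columns")
    if (length(def) == length(y)) return(trace)
    yi <- approx(trace@columns[def], y[def], xout = trace@columns,
        method = "linear", rule = 2)$y
    new("PixelTrace", columns = trace@columns, rowIndex = yi,
        filled = trace@filled | is.na(y), groupId = trace@groupId)
}

#' Locate the leading DC calibration pulse
#'
#' Every trace is assumed to begin with a rectangular calibration pulse; its
#' plateau height against the baseline fixes the voltage scale.  The
#' baseline is the modal trace row outside the pulse; the pulse is the first
#' sustained run of columns deviating from the baseline, and must be flat.
#' Absence of the pulse is a hard failure -- without it the record cannot be
#' calibrated.
#'
#' @param trace a gap-free \linkS4class{PixelTrace}.
#' @param minDeviation pixels above baseline that count as pulse, default 4.
#' @param minRun minimum pulse width in columns, default 5.
#' @param startFraction the pulse must start within this leading fraction of
#'   the trace.
#' @param flatTol maximal standard deviation of the plateau interior, px.
#' @return list: \code{pulseCols} (first, last column), \code{heightPx},
#'   \code{baselineRow}.
#' @export
detectDcPulse <- function(trace, minDeviation = 4, minRun = 5L,
                          startFraction = 0.25, flatTol = 2) {
    y <- trace@rowIndex
    stopIfNot(!anyNA(y), "interpolate gaps before pulse detection")
    # reference level: the median is robust both to the pulse plateau and
    # to baseline wander (the mode is not: a long flat plateau can outvote
    # a drifting baseline)
    ref <- median(y)
    dev <- (ref - y) > minDeviation   # pulse rises: smaller row index
    maxDev <- max(ref - y)
    r <- rle(dev)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= minRun)
    # a pulse must stand clear of baseline wander: demand a substantial
    # fraction of the largest deviation seen anywhere on the trace
    if (length(cand)) {
        h <- vapply(cand, function(k)
            ref - roundedMode(y[starts[k]:ends[k]]), 0)
        cand <- cand[h >= 0.4 * maxDev]
    }
    if (!length(cand))
        stop("missing DC pulse: no sustained plateau at trace start",
            call. = FALSE)
    k <- cand[1]
    if (starts[k] > startFraction * length(y))
        stop("missing DC pulse: first plateau is not at the trace start",
            call. = FALSE)
    s <- starts[k]; e <- ends[k]
    interior <- y[s:e]
    # drop the rise/fall flanks (ink thickness widens them) before judging
    # flatness; keep the central 70% of the run
    if (length(interior) > 6L) {
        trim <- max(2L, ceiling(0.15 * length(interior)))
        interior <- interior[(trim + 1L):(length(interior) - trim)]
    }
    if (sd(interior) > flatTol)
        stop("missing DC pulse: leading deviation is not a flat plateau",
            call. = FALSE)
    plateau <- roundedMode(interior)
    baseline <- roundedMode(y[-(s:e)])
    list(pulseCols = c(trace@columns[s], trace@columns[e]),
         heightPx = baseline - plateau,
         baselineRow = baseline)
}

#' Calibrate a pixel trace into a voltage-time signal
#'
#' Converts the per-column trace rows into millivolts against the DC pulse:
#' \code{voltage = (baselineRow - row) * dcAmplitude / pulseHeightPx} (row
#' index grows downward, voltage upward), and columns into seconds:
#' \code{time = (col - firstSignalCol) / (pxPerMm * paperSpeed)}.  Pulse
#' columns (and everything before them) are excluded from the signal.  When
#' no pulse measurement is supplied the template gain is used instead
#' (\code{pulseHeightPx = gain * dcAmplitude * pxPerMm}).
#'
#' @param trace a gap-free \linkS4class{PixelTrace}.
#' @param cal \code{\link{calibrationConstants}} including
#'   \code{pulseHeightPx} and \code{baselineRow} (from
#'   \code{\link{detectDcPulse}}), or with a template gain.
#' @param lead lead name for the output signal.
#' @param pulseCols pulse column range to exclude, or NULL if the trace
#'   starts directly with signal.
#' @param guard columns dropped after the pulse fall, default 3.
#' @param provenance extra provenance entries.
#' @return a \linkS4class{DigitizedSignal}.
#' @export
calibrateTrace <- function(trace, cal, lead = "?", pulseCols = NULL,
                           guard = 3L, provenance = list()) {
    hp <- cal$pulseHeightPx
    if (is.na(hp)) hp <- cal$gain * cal$dcAmplitude * cal$pxPerMm
    stopIfNot(is.finite(hp) && hp > 0,
        "calibration error: zero or unknown pulse height")
    stopIfNot(is.finite(cal$baselineRow),
        "calibration error: unknown baseline row")
    y <- trace@rowIndex
    stopIfNot(!anyNA(y), "interpolate gaps before calibration")
    keep <- if (!is.null(pulseCols))
        trace@columns > pulseCols[2] + guard else !logical(length(y))
    stopIfNot(sum(keep) >= 2L, "calibration error: no signal columns left")
    cols <- trace@columns[keep]
    dt <- 1 / (cal$pxPerMm * cal$paperSpeed)
    new("DigitizedSignal",
        lead = as.character(lead),
        time = (cols - cols[1]) * dt,
        voltage = (cal$baselineRow - y[keep]) * cal$dcAmplitude / hp,
        interpolated = trace@filled[keep],
        samplingInterval = dt,
        provenance = c(provenance, list(
            pulseHeightPx = hp, baselineRow = cal$baselineRow,
            pxPerMm = cal$pxPerMm, paperSpeed = cal$paperSpeed,
            firstSignalCol = cols[1], groupId = trace@groupId)))
}

#' Resample a digitized signal to a uniform rate
#'
#' The native column-grid samples are the primary output; this helper
#' offers a conventional uniform rate (default 500 Hz) by linear
#' interpolation for consumers that expect one.
#'
#' @param signal a \linkS4class{DigitizedSignal}.
#' @param rate target sampling rate, Hz.
#' @return a resampled \linkS4class{DigitizedSignal}.
#' @export
resampleSignal <- function(signal, rate = 500) {
    stopIfNot(rate > 0, "rate must be positive")
    t2 <- seq(min(signal@time), max(signal@time), by = 1 / rate)
    v2 <- approx(signal@time, signal@voltage, xout = t2)$y
    f2 <- approx(signal@time, as.numeric(signal@interpolated), xout = t2,
        method = "constant", f = 0, rule = 2)$y > 0.5
    new("DigitizedSignal", lead = signal@lead, time = t2, voltage = v2,
        interpolated = f2, samplingInterval = 1 / rate,
        provenance = c(signal@provenance, list(resampledHz = rate)))
}

#' Write a digitized signal as CSV
#'
#' Columns: time_s, voltage_mV, interpolated; a comment header carries the
#' lead name and provenance.
#'
#' @param signal a \linkS4class{DigitizedSignal}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSignalCsv <- function(signal, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# lead: %s", signal@lead), con)
    prov <- signal@provenance
    if (length(prov))
        writeLines(sprintf("# %s: %s", names(prov),
            vapply(prov, function(p) paste(format(p), collapse = " "), "")),
            con)
    utils::write.csv(as.data.frame(signal), con, row.names = FALSE)
    invisible(path)
}
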