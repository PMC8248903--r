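# Batch orchestration: the full digitization pipeline in the data-flow
# order preprocess -> character removal -> segmentation -> extraction.

#' Run configuration
#'
#' @param merge a \code{\link{mergeParams}} object.
#' @param threshold \code{"auto"} (histogram valley) or a manual intensity.
#' @param ocrMinScore OCR correlation acceptance threshold.
#' @param bridgeKernel horizontal gap-bridging kernel length, px (odd).
#' @param targetDpi downscale target, or NA to keep the native resolution.
#' @param samplingRate optional uniform resampling rate, Hz (NA = native
#'   column grid only).
#' @param glyphLibrary a \linkS4class{GlyphLibrary}; NULL uses the built-in
#'   font at scale 3.
#' @param alignToStandard realign ROIs against the template's standard image
#'   when one is available.
#' @param removeLeadChars erase lead-label characters before segmentation
#'   (disable to measure the damage overlapping labels cause).
#' @param seed seed for any stochastic debug sampling.
#' @return a list of class \code{RunConfig}.
#' @export
runConfig <- function(merge = mergeParams(), threshold = "auto",
                      ocrMinScore = 0.6, bridgeKernel = 5L,
                      targetDpi = NA, samplingRate = NA,
                      glyphLibrary = NULL, alignToStandard = FALSE,
                      removeLeadChars = TRUE, seed = 1L) {
    stopIfNot(identical(threshold, "auto") ||
        (is.numeric(threshold) && threshold >= 0 && threshold <= 256),
        "threshold must be 'auto' or an intensity in [0, 256]")
    stopIfNot(bridgeKernel >= 1 && bridgeKernel %% 2 == 1,
        "bridgeKernel must be odd")
    stopIfNot(ocrMinScore > 0 && ocrMinScore <= 1,
        "ocrMinScore must be in (0, 1]")
    structure(list(merge = merge, threshold = threshold,
        ocrMinScore = ocrMinScore, bridgeKernel = as.integer(bridgeKernel),
        targetDpi = targetDpi, samplingRate = samplingRate,
        glyphLibrary = glyphLibrary, alignToStandard = alignToStandard,
        removeLeadChars = isTRUE(removeLeadChars),
        seed = as.integer(seed)), class = "RunConfig")
}

# short stable hash of the configuration for output provenance
.configHash <- function(cfg) {
    raw <- serialize(cfg[setdiff(names(cfg), "glyphLibrary")], NULL,
        version = 2)
    h <- 0
    for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", h)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Digitize one scanned ECG record
#'
#' Executes the full pipeline: grayscale + optional downscale, skew
#' estimation and correction, region partition, histogram thresholding,
#' median filtering and gap bridging (preprocessing); correlation-OCR
#' erasure of lead-label characters (so glyph components cannot contaminate
#' row merging); connected-component labelling, speck discarding and
#' row assembly (segmentation); column scanning, gap interpolation, DC-pulse
#' detection and calibration (extraction); plus demographic OCR.
#'
#' @param image an \linkS4class{ECGImage} or a path to a PNG/JPEG scan.
#' @param template a \linkS4class{TemplateSpec}.
#' @param cfg a \code{\link{runConfig}}.
#' @return list: \code{signals} (list of \linkS4class{DigitizedSignal}),
#'   \code{demographics} (named list of field texts), \code{mask} (the
#'   final waveform-region \linkS4class{BinaryMask}), \code{rows} (the
#'   \linkS4class{RowWaveforms}), \code{report} (every parameter,
#'   threshold, offset and reject count).
#' @export
digitizeRecord <- function(image, template, cfg = runConfig()) {
    t0 <- proc.time()[["elapsed"]]
    lib <- cfg$glyphLibrary %||% defaultGlyphLibrary(3L)
    img <- if (is.character(image))
        .stage("input", readRecordImage(image, dpi = template@dpi))
        else image
    img <- .stage("preprocess", toGrayscale(img))
    if (!is.na(cfg$targetDpi))
        img <- .stage("preprocess", downscaleToDpi(img, cfg$targetDpi))
    est <- tryCatch(estimateSkew(img), error = function(e) {
        warning("skew estimation skipped: ", conditionMessage(e))
        new("SkewEstimate", angle = 0, support = 0)
    })
    img <- .stage("preprocess", deskew(img, est))
    regions <- .stage("preprocess", partitionRegions(img, template))
    thr <- if (identical(cfg$threshold, "auto"))
        .stage("preprocess", autoThreshold(regions$waveform))
        else structure(as.numeric(cfg$threshold), method = "manual")
    mask <- .stage("preprocess", {
        m <- binarize(regions$waveform, thr)
        m <- medianFilterMask(m)
        bridgeGaps(m, cfg$bridgeKernel)
    })

    rois <- template@leadRois
    offset <- c(0L, 0L)
    if (isTRUE(cfg$alignToStandard) && !is.na(template@standardImagePath)) {
        std <- .stage("ocr", readRecordImage(template@standardImagePath,
            dpi = template@dpi))
        rois <- .stage("ocr", alignRois(img, toGrayscale(std), rois))
        offset <- attr(rois, "offset")
    }
    removal <- if (isTRUE(cfg$removeLeadChars))
        .stage("ocr", removeLeadCharacters(mask, rois, lib,
            minScore = cfg$ocrMinScore))
        else list(mask = mask, recognitions = list(), erasedSpans = list())
    mask <- removal$mask

    gridPx <- template@calibration$gridPitch * pxPerMm(template@dpi)
    mp <- cfg$merge
    if (is.null(mp$distanceThreshold)) mp$distanceThreshold <- 2 * gridPx
    rowsObj <- .stage("segmentation", {
        comps <- labelComponents(mask, mp$connectivity)
        comps <- discardSmall(comps, mp$minComponentArea)
        assembleRows(comps, mp, expectedRows = template@rows)
    })

    leadNames <- .rowLeadNames(rowsObj, mask, template)
    signals <- vector("list", nRows(rowsObj))
    for (r in seq_len(nRows(rowsObj))) {
        signals[[r]] <- .stage("extract", {
            tr <- interpolateGaps(columnScan(rowsObj, r))
            pulse <- detectDcPulse(tr)
            cal <- calibrationConstants(
                pxPerMm = pxPerMm(template@dpi),
                paperSpeed = template@calibration$paperSpeed,
                gain = template@calibration$gain,
                dcAmplitude = template@calibration$dcAmplitude,
                pulseHeightPx = pulse$heightPx,
                baselineRow = pulse$baselineRow)
            sig <- calibrateTrace(tr, cal, lead = leadNames[r],
                pulseCols = pulse$pulseCols,
                provenance = list(rowIndex = r,
                    regionOrigin = mask@origin,
                    threshold = as.numeric(thr),
                    thresholdMethod = attr(thr, "method"),
                    skewDeg = skewAngle(est),
                    roiOffset = offset,
                    configHash = .configHash(cfg),
                    template = template@vendor))
            if (!is.na(cfg$samplingRate))
                sig <- resampleSignal(sig, cfg$samplingRate)
            sig
        })
    }

    demographics <- if (!is.null(regions$demographic) &&
                        nrow(template@demographicRois))
        .stage("ocr", extractDemographics(regions$demographic, template, lib,
            minScore = cfg$ocrMinScore))
        else structure(list(), recognitions = list())

    report <- list(
        template = template@vendor,
        configHash = .configHash(cfg),
        skewDeg = skewAngle(est), skewSupport = est@support,
        threshold = as.numeric(thr), thresholdMethod = attr(thr, "method"),
        roiOffset = offset,
        mergeDistance = mp$distanceThreshold,
        endpointPixels = mp$endpointPixels,
        minComponentArea = mp$minComponentArea,
        connectivity = mp$connectivity,
        rowsFound = nRows(rowsObj),
        rowsExpected = template@rows,
        rejects = length(rowRejects(rowsObj)),
        erasedSpans = removal$erasedSpans,
        elapsedSec = proc.time()[["elapsed"]] - t0)
    list(signals = signals, demographics = demographics, mask = mask,
        rows = rowsObj, report = report)
}

# name each row after the lead-label ROI whose centre row is nearest
.rowLeadNames <- function(rowsObj, mask, template) {
    n <- nRows(rowsObj)
    nm <- paste0("row", seq_len(n))
    rois <- template@leadRois
    if (!nrow(rois)) return(nm)
    o <- mask@origin
    centers <- (rois$top + rois$bottom) / 2
    for (r in seq_len(n)) {
        mr <- mean(rowPixels(rowsObj, r)[, 1]) + o[1] - 1L
        k <- which.min(abs(centers - mr))
        if (abs(centers[k] - mr) < (template@waveformRegion[3] -
                template@waveformRegion[1]) / template@rows)
            nm[r] <- rois$name[k]
    }
    nm
}

#' Digitize every record in a directory
#'
#' Processes each PNG/JPEG independently; one record's failure never aborts
#' the batch.  When \code{outDir} is given, per-lead CSVs, a demographics
#' text file and a JSON run report are written per record.
#'
#' @param inputDir directory of scans.
#' @param template a \linkS4class{TemplateSpec}.
#' @param cfg a \code{\link{runConfig}}.
#' @param outDir optional output directory.
#' @return list of class \code{BatchReport}: \code{summary} data.frame
#'   (record, status, rowsFound, fieldsRecovered, message), \code{results},
#'   \code{status} (0 all ok, 2 partial failure, 1 all failed).
#' @export
batchDigitize <- function(inputDir, template, cfg = runConfig(),
                          outDir = NULL) {
    stopIfNot(dir.exists(inputDir),
        sprintf("input error: no such directory: %s", inputDir))
    files <- list.files(inputDir, pattern = "\\.(png|jpe?g)$",
        ignore.case = TRUE, full.names = TRUE)
    stopIfNot(length(files) >= 1L,
        "input error: directory contains no PNG/JPEG records")
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rows <- list(); results <- list()
    for (f in files) {
        id <- tools::file_path_sans_ext(basename(f))
        res <- tryCatch(digitizeRecord(f, template, cfg),
            error = function(e) e)
        if (inherits(res, "error")) {
            rows[[id]] <- data.frame(record = id, status = "failed",
                rowsFound = NA_integer_, fieldsRecovered = NA_integer_,
                message = conditionMessage(res))
        } else {
            results[[id]] <- res
            rows[[id]] <- data.frame(record = id, status = "ok",
                rowsFound = res$report$rowsFound,
                fieldsRecovered = sum(nzchar(unlist(res$demographics))),
                message = "")
            if (!is.null(outDir)) .writeRecordOutputs(res, id, outDir)
        }
    }
    summary <- do.call(rbind, rows); rownames(summary) <- NULL
    nOk <- sum(summary$status == "ok")
    status <- if (nOk == nrow(summary)) 0L
              else if (nOk > 0L) 2L else 1L
    structure(list(summary = summary, results = results, status = status),
        class = "BatchReport")
}

.writeRecordOutputs <- function(res, id, outDir) {
    for (sig in res$signals)
        writeSignalCsv(sig, file.path(outDir,
            sprintf("%s_%s.csv", id, gsub("[^A-Za-z0-9]", "_", sig@lead))))
    demo <- res$demographics
    writeLines(sprintf("%s: %s", names(demo), unlist(demo)),
        file.path(outDir, sprintf("%s_demographics.txt", id)))
    jsonlite::write_json(res$report,
        file.path(outDir, sprintf("%s_report.json", id)),
        auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' @export
print.BatchReport <- function(x, ...) {
    cat("Batch:", nrow(x$summary), "records,",
        sum(x$summary$status == "ok"), "ok, exit status", x$status, "\n")
    print(x$summary)
    invisible(x)
}

#' Correlate digitized signals with a ground-truth manifest
#'
#' For every row, interpolates the digitized voltage onto the manifest's
#' time grid and reports the Pearson correlation.  When the signal carries
#' pipeline provenance, the time origins are anchored through the canvas
#' column of the first signal sample; a small residual integer column lag is
#' searched either way (skew correction and pulse-fall detection can shift
#' the origin by a few pixels).
#'
#' @param signals list of \linkS4class{DigitizedSignal}, top to bottom.
#' @param manifest the record's \linkS4class{GroundTruthManifest}.
#' @param maxLag largest residual column lag tried, each direction.
#' @return data.frame: row, r, lag (columns, including the anchor), n.
#' @export
compareToManifest <- function(signals, manifest, maxLag = 6L) {
    nR <- min(length(signals), length(manifest@rows))
    dtCol <- 1 / manifest@calibration$pxPerSec
    out <- lapply(seq_len(nR), function(r) {
        truth <- manifest@rows[[r]]
        sig <- signals[[r]]
        prov <- sig@provenance
        lag0 <- if (!is.null(prov$firstSignalCol) &&
                    !is.null(prov$regionOrigin)) {
            firstCanvas <- prov$firstSignalCol + prov$regionOrigin[2] - 1L
            truth$signalCols[1] - firstCanvas
        } else 0L
        best <- c(r = -Inf, lag = NA)
        for (lag in lag0 + (-maxLag:maxLag)) {
            v <- approx(sig@time, sig@voltage, xout = truth$time +
                lag * dtCol)$y
            ok <- !is.na(v)
            if (sum(ok) < 10) next
            rr <- suppressWarnings(cor(v[ok], truth$mv[ok]))
            if (is.finite(rr) && rr > best["r"])
                best <- c(r = rr, lag = lag)
        }
        data.frame(row = r, r = best[["r"]], lag = best[["lag"]],
            n = length(truth$time))
    })
    do.call(rbind, out)
}
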