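# Vendor template files: YAML serialization of TemplateSpec with validation
# and conventional defaulting.

.CAL_DEFAULTS <- list(paperSpeed = 25, gain = 10, gridPitch = 5,
    dcAmplitude = 1, dcDuration = 0.2)

#' Load a vendor template from YAML
#'
#' Reads and validates a \linkS4class{TemplateSpec}.  Missing calibration
#' constants are filled with the conventional ECG printing values (25 mm/s,
#' 10 mm/mV, 5 mm grid, 1 mV x 0.2 s pulse) and the filled names recorded in
#' \code{calibration$assumed}, so downstream provenance can flag them.
#'
#' @param path YAML file; see \code{\link{writeTemplate}} for the schema.
#' @return a validated \linkS4class{TemplateSpec}.
#' @export
loadTemplate <- function(path) {
    stopIfNot(file.exists(path), sprintf("template file not found: %s", path))
    x <- yaml::read_yaml(path)
    for (f in c("vendor", "canvas", "dpi", "waveform_region", "rows"))
        if (is.null(x[[f]]))
            stop(sprintf("template error: missing field '%s'", f),
                call. = FALSE)
    cal <- x$calibration %||% list()
    names(cal) <- vapply(names(cal), .camel, "")
    assumed <- setdiff(names(.CAL_DEFAULTS), names(cal))
    cal <- c(cal, .CAL_DEFAULTS[assumed])
    cal$assumed <- assumed
    roiDf <- function(lst, key) {
        if (is.null(lst) || !length(lst))
            return(data.frame(name = character(0), top = integer(0),
                left = integer(0), bottom = integer(0), right = integer(0),
                stringsAsFactors = FALSE) |>
                stats::setNames(c(key, "top", "left", "bottom", "right")))
        df <- do.call(rbind, lapply(lst, function(e) data.frame(
            name = e[[key]] %||% e$name, top = e$rect[[1]], left = e$rect[[2]],
            bottom = e$rect[[3]], right = e$rect[[4]])))
        names(df)[1] <- key
        df
    }
    dem <- x$demographic_region %||% c(1L, 1L, 0L, as.integer(x$canvas[2]))
    tpl <- new("TemplateSpec",
        vendor = as.character(x$vendor),
        canvas = as.integer(x$canvas),
        dpi = as.numeric(x$dpi),
        demographicRegion = as.integer(dem),
        waveformRegion = as.integer(x$waveform_region),
        rows = as.integer(x$rows),
        leadRois = roiDf(x$lead_rois, "name"),
        demographicRois = roiDf(x$demographic_rois, "field"),
        calibration = cal,
        standardImagePath = as.character(x$standard_image %||% NA))
    v <- validObject(tpl, test = TRUE)
    if (!isTRUE(v))
        stop(sprintf("template error: %s", v), call. = FALSE)
    tpl
}

.camel <- function(s) {
    parts <- strsplit(s, "_", fixed = TRUE)[[1]]
    paste0(parts[1], paste0(toupper(substring(parts[-1], 1, 1)),
        substring(parts[-1], 2), collapse = ""))
}

#' Write a template to YAML
#'
#' @param template a \linkS4class{TemplateSpec}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTemplate <- function(template, path) {
    roiList <- function(df, key) lapply(seq_len(nrow(df)), function(i)
        stats::setNames(list(df[[key]][i], c(df$top[i], df$left[i],
            df$bottom[i], df$right[i])), c(key, "rect")))
    cal <- template@calibration
    x <- list(
        vendor = template@vendor,
        canvas = template@canvas,
        dpi = template@dpi,
        demographic_region = template@demographicRegion,
        waveform_region = template@waveformRegion,
        rows = template@rows,
        lead_rois = roiList(template@leadRois, "name"),
        demographic_rois = roiList(template@demographicRois, "field"),
        calibration = list(paper_speed = cal$paperSpeed, gain = cal$gain,
            grid_pitch = cal$gridPitch, dc_amplitude = cal$dcAmplitude,
            dc_duration = cal$dcDuration))
    if (!is.na(template@standardImagePath))
        x$standard_image <- template@standardImagePath
    yaml::write_yaml(x, path)
    invisible(path)
}

#' Read a record scan from PNG or JPEG
#'
#' @param path image file.
#' @param dpi the scan resolution (image files rarely carry it reliably).
#' @return an \linkS4class{ECGImage}; colour scans keep their 3 channels.
#' @export
readRecordImage <- function(path, dpi) {
    stopIfNot(file.exists(path), sprintf("image not found: %s", path))
    img <- EBImage::readImage(path)
    d <- EBImage::imageData(img)
    d <- if (length(dim(d)) == 2L) t(d)
         else aperm(d[, , 1:3, drop = FALSE], c(2, 1, 3))
    ECGImage(round(d * 255), dpi = dpi)
}

#' Write an \linkS4class{ECGImage} as PNG
#'
#' @param image the image.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRecordImage <- function(image, path) {
    d <- imageData(image) / 255
    png::writePNG(d, path)
    invisible(path)
}
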