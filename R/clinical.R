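# Step E: the validation statistics -- QTc, abnormality flags, Pearson
# correlation and Cohen's kappa over interval tables.

#' Rate-corrected QT interval (Bazett)
#'
#' \eqn{QT_c = QT / \sqrt{RR}} with QT in milliseconds and RR in seconds;
#' the result is in milliseconds.  (Consistent units in and out scale the
#' result accordingly.)
#'
#' @param qt QT interval, ms (> 0).
#' @param rr RR interval, s (> 0).
#' @return QTc, ms.
#' @examples
#' computeQtc(440, 0.81)  # 488.9 ms
#' @export
computeQtc <- function(qt, rr) {
    stopIfNot(all(qt > 0) && all(rr > 0),
        "domain error: QT and RR must be positive")
    qt / sqrt(rr)
}

#' Interval measurements for one record
#'
#' PR is read on lead II, QRS on V1, QT on V3 and RR on V6 by convention;
#' QTc is derived from QT and RR.
#'
#' @param PR PR interval, ms.
#' @param QRS QRS duration, ms.
#' @param QT QT interval, ms.
#' @param RR RR interval, s.
#' @return a list of class \code{IntervalMeasurements} including \code{QTc}.
#' @export
intervalMeasurements <- function(PR, QRS, QT, RR) {
    stopIfNot(all(c(PR, QRS, QT, RR) > 0), "intervals must be positive")
    structure(list(PR = PR, QRS = QRS, QT = QT, RR = RR,
        QTc = computeQtc(QT, RR)), class = "IntervalMeasurements")
}

#' Classify the four interval abnormalities
#'
#' Strict-inequality thresholds: QTc prolongation (QTc > 450 ms),
#' first-degree atrioventricular block (PR > 200 ms), bradycardia
#' (RR > 1 s), intra-ventricular conduction delay (QRS > 120 ms).
#' Boundary values are negative.
#'
#' @param m an \code{\link{intervalMeasurements}} object.
#' @return named logical vector: \code{qtc_prolonged},
#'   \code{first_degree_av_block}, \code{bradycardia}, \code{ivcd}.
#' @examples
#' flagAbnormalities(intervalMeasurements(PR = 200, QRS = 100,
#'   QT = 400, RR = 1))  # all FALSE: boundaries are negative
#' @export
flagAbnormalities <- function(m) {
    stopIfNot(inherits(m, "IntervalMeasurements"),
        "m must come from intervalMeasurements()")
    c(qtc_prolonged = m$QTc > 450,
      first_degree_av_block = m$PR > 200,
      bradycardia = m$RR > 1,
      ivcd = m$QRS > 120)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper: sequences must be equally long (>= 3) with
#' non-zero variance; a zero-variance input is an error, never silently 0.
#'
#' @param x,y numeric sequences.
#' @return correlation in \[-1, 1\].
#' @export
pearsonR <- function(x, y) {
    stopIfNot(length(x) == length(y), "sequences must have equal length")
    stopIfNot(length(x) >= 3, "at least 3 pairs are required")
    stopIfNot(sd(x) > 0 && sd(y) > 0,
        "undefined correlation: zero-variance input")
    cor(x, y, method = "pearson")
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} from
#' the 2x2 agreement table, with \eqn{p_o} the observed agreement and
#' \eqn{p_e} the chance agreement implied by the marginals.  Perfect
#' agreement with degenerate marginals (\eqn{p_e = 1}) is defined as 1.
#'
#' @param a,b logical sequences of equal length >= 2.
#' @return kappa, <= 1.
#' @examples
#' cohenKappa(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))  # 1
#' @export
cohenKappa <- function(a, b) {
    stopIfNot(length(a) == length(b), "sequences must have equal length")
    stopIfNot(length(a) >= 2, "at least 2 pairs are required")
    a <- as.logical(a); b <- as.logical(b)
    stopIfNot(!anyNA(a) && !anyNA(b), "NA ratings are not allowed")
    n <- length(a)
    po <- mean(a == b)
    pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
    if (abs(1 - pe) < 1e-12) {
        if (po == 1) return(1)
        stop("undefined kappa: degenerate marginals without perfect agreement",
            call. = FALSE)
    }
    (po - pe) / (1 - pe)
}

#' Agreement report between paper and digital interval readings
#'
#' Matches the two tables on \code{record_id}, computes the per-interval
#' Pearson correlation (PR, QRS, QT, RR, QTc) and the per-flag Cohen kappa
#' for the four abnormality classifications.
#'
#' @param paperReads,digitalReads data.frames with columns \code{record_id},
#'   \code{PR_ms}, \code{QRS_ms}, \code{QT_ms}, \code{RR_s}.
#' @return list of class \code{AgreementStats}: \code{pearson} (named
#'   numeric), \code{kappa} (named numeric), \code{n}.
#' @export
agreementReport <- function(paperReads, digitalReads) {
    need <- c("record_id", "PR_ms", "QRS_ms", "QT_ms", "RR_s")
    stopIfNot(all(need %in% names(paperReads)) &&
              all(need %in% names(digitalReads)),
        "interval tables need columns record_id, PR_ms, QRS_ms, QT_ms, RR_s")
    if (!setequal(paperReads$record_id, digitalReads$record_id) ||
        anyDuplicated(paperReads$record_id) ||
        anyDuplicated(digitalReads$record_id))
        stop("pairing error: record ids must match one-to-one",
            call. = FALSE)
    dg <- digitalReads[match(paperReads$record_id, digitalReads$record_id), ]
    pp <- paperReads
    pp$QTc_ms <- computeQtc(pp$QT_ms, pp$RR_s)
    dg$QTc_ms <- computeQtc(dg$QT_ms, dg$RR_s)
    ivs <- c(PR = "PR_ms", QRS = "QRS_ms", QT = "QT_ms", RR = "RR_s",
        QTc = "QTc_ms")
    pearson <- vapply(ivs, function(cn) pearsonR(pp[[cn]], dg[[cn]]), 0)
    flagsOf <- function(d) cbind(
        qtc_prolonged = d$QTc_ms > 450,
        first_degree_av_block = d$PR_ms > 200,
        bradycardia = d$RR_s > 1,
        ivcd = d$QRS_ms > 120)
    fp <- flagsOf(pp); fd <- flagsOf(dg)
    kappa <- vapply(colnames(fp), function(cn)
        tryCatch(cohenKappa(fp[, cn], fd[, cn]),
            error = function(e) NA_real_), 0)
    structure(list(pearson = pearson, kappa = kappa, n = nrow(pp)),
        class = "AgreementStats")
}

#' @export
print.AgreementStats <- function(x, ...) {
    cat("Agreement over", x$n, "records\n")
    cat("Pearson r :", paste(sprintf("%s=%.3f", names(x$pearson),
        x$pearson), collapse = "  "), "\n")
    cat("Cohen kappa:", paste(sprintf("%s=%s", names(x$kappa),
        ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa))),
        collapse = "  "), "\n")
    invisible(x)
}

#' Write an agreement report as CSV and Markdown
#'
#' @param stats an \code{AgreementStats} object.
#' @param csvPath,mdPath output files (NULL skips one).
#' @return invisibly, the report data.frame.
#' @export
writeAgreementReport <- function(stats, csvPath = NULL, mdPath = NULL) {
    df <- rbind(
        data.frame(statistic = "pearson_r", name = names(stats$pearson),
            value = unname(stats$pearson)),
        data.frame(statistic = "cohen_kappa", name = names(stats$kappa),
            value = unname(stats$kappa)))
    if (!is.null(csvPath)) utils::write.csv(df, csvPath, row.names = FALSE)
    if (!is.null(mdPath)) {
        lines <- c("| statistic | name | value |", "|---|---|---|",
            sprintf("| %s | %s | %.4f |", df$statistic, df$name, df$value))
        writeLines(lines, mdPath)
    }
    invisible(df)
}
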