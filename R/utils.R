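# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded from `seed`; the caller's
# .Random.seed is untouched. All package randomness flows through this.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Statistical mode of a numeric vector after rounding; ties -> smallest.
roundedMode <- function(x) {
    x <- round(x[is.finite(x)])
    if (!length(x)) return(NA_real_)
    tb <- table(x)
    as.numeric(names(tb)[which.max(tb)])
}

# Rotate a grayscale intensity matrix about its centre, keeping the canvas
# size, bilinear interpolation, background fill. Positive angle makes
# horizontal lines rise (toward smaller row index) with increasing column.
rotateMatrix <- function(m, angle, bg) {
    if (angle == 0) return(m)
    out <- as.matrix(EBImage::rotate(m, angle, filter = "bilinear",
        output.dim = dim(m), bg.col = bg))
    out[!is.finite(out)] <- bg
    pmin(pmax(out, 0), 255)
}

# Sliding-window sum via EBImage::filter2 with zero boundary. kern is a
# matrix of 0/1 weights (will be used as given).
slideSum <- function(m, kern) {
    as.matrix(EBImage::filter2(m, kern, boundary = 0))
}

pxPerMm <- function(dpi) dpi / 25.4

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
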