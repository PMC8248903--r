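# Built-in 5x7 dot-matrix glyph set.
#
# The renderer prints lead labels and demographic text with these bitmaps and
# the OCR module trains its default library from the very same bitmaps, so
# recognition on synthetic records has a self-consistent ceiling.  Each glyph
# is 7 rows of 5 columns; '#' = ink.

.FONT5x7 <- list(
"0" = c("01110","10001","10011","10101","11001","10001","01110"),
"1" = c("00100","01100","00100","00100","00100","00100","01110"),
"2" = c("01110","10001","00001","00010","00100","01000","11111"),
"3" = c("11111","00010","00100","00010","00001","10001","01110"),
"4" = c("00010","00110","01010","10010","11111","00010","00010"),
"5" = c("11111","10000","11110","00001","00001","10001","01110"),
"6" = c("00110","01000","10000","11110","10001","10001","01110"),
"7" = c("11111","00001","00010","00100","01000","01000","01000"),
"8" = c("01110","10001","10001","01110","10001","10001","01110"),
"9" = c("01110","10001","10001","01111","00001","00010","01100"),
"A" = c("01110","10001","10001","11111","10001","10001","10001"),
"B" = c("11110","10001","10001","11110","10001","10001","11110"),
"C" = c("01110","10001","10000","10000","10000","10001","01110"),
"D" = c("11100","10010","10001","10001","10001","10010","11100"),
"E" = c("11111","10000","10000","11110","10000","10000","11111"),
"F" = c("11111","10000","10000","11110","10000","10000","10000"),
"G" = c("01110","10001","10000","10111","10001","10001","01111"),
"H" = c("10001","10001","10001","11111","10001","10001","10001"),
"I" = c("01110","00100","00100","00100","00100","00100","01110"),
"J" = c("00111","00010","00010","00010","00010","10010","01100"),
"K" = c("10001","10010","10100","11000","10100","10010","10001"),
"L" = c("10000","10000","10000","10000","10000","10000","11111"),
"M" = c("10001","11011","10101","10101","10001","10001","10001"),
"N" = c("10001","11001","10101","10011","10001","10001","10001"),
"O" = c("01110","10001","10001","10001","10001","10001","01110"),
"P" = c("11110","10001","10001","11110","10000","10000","10000"),
"Q" = c("01110","10001","10001","10001","10101","10010","01101"),
"R" = c("11110","10001","10001","11110","10100","10010","10001"),
"S" = c("01111","10000","10000","01110","00001","00001","11110"),
"T" = c("11111","00100","00100","00100","00100","00100","00100"),
"U" = c("10001","10001","10001","10001","10001","10001","01110"),
"V" = c("10001","10001","10001","10001","10001","01010","00100"),
"W" = c("10001","10001","10001","10101","10101","11011","10001"),
"X" = c("10001","10001","01010","00100","01010","10001","10001"),
"Y" = c("10001","10001","01010","00100","00100","00100","00100"),
"Z" = c("11111","00001","00010","00100","01000","10000","11111"),
"a" = c("00000","00000","01110","00001","01111","10001","01111"),
"v" = c("00000","00000","10001","10001","10001","01010","00100"),
"-" = c("00000","00000","00000","01110","00000","00000","00000"),
"/" = c("00001","00010","00010","00100","01000","01000","10000"),
":" = c("00000","00100","00000","00000","00000","00100","00000"),
"." = c("00000","00000","00000","00000","00000","01100","01100")
)

#' Characters available in the built-in dot-matrix font
#'
#' @return character vector of glyph names (digits, upper case, the lower
#'   case letters used in augmented-lead names, and basic punctuation).
#' @export
fontCharacters <- function() names(.FONT5x7)

#' Render one character as a logical bitmap
#'
#' Scales the built-in 5x7 dot-matrix glyph by integer nearest-neighbour
#' replication, so a scale of 3 yields a 21 x 15 bitmap with 3-px strokes.
#'
#' @param char single character, one of \code{fontCharacters()}.
#' @param scale positive integer magnification.
#' @return logical matrix, TRUE = ink.
#' @examples
#' dim(renderGlyph("V", scale = 3))
#' @export
renderGlyph <- function(char, scale = 3L) {
    stopIfNot(char %in% names(.FONT5x7),
        sprintf("no glyph for character '%s'", char))
    stopIfNot(scale >= 1, "scale must be a positive integer")
    rows <- .FONT5x7[[char]]
    m <- do.call(rbind, lapply(rows,
        function(s) as.integer(strsplit(s, "")[[1]]) == 1L))
    m[rep(seq_len(nrow(m)), each = scale),
      rep(seq_len(ncol(m)), each = scale), drop = FALSE]
}

#' Render a text string as a logical bitmap
#'
#' Glyphs are placed left to right with a one-glyph-column space between
#' them (scaled).  Space characters advance the cursor without ink.
#'
#' @param text string made of \code{fontCharacters()} and spaces.
#' @param scale positive integer magnification.
#' @return logical matrix, TRUE = ink.
#' @export
renderText <- function(text, scale = 3L) {
    chars <- strsplit(text, "")[[1]]
    h <- 7L * scale
    gap <- 1L * scale
    width <- 0L
    mats <- list()
    for (ch in chars) {
        if (ch == " ") {
            mats[[length(mats) + 1L]] <- matrix(FALSE, h, 3L * scale)
        } else {
            mats[[length(mats) + 1L]] <- renderGlyph(ch, scale)
        }
        mats[[length(mats) + 1L]] <- matrix(FALSE, h, gap)
    }
    if (!length(mats)) return(matrix(FALSE, h, 0L))
    do.call(cbind, mats[-length(mats)])
}
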