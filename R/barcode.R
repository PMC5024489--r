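#' Encode text as a Code 128B symbol sequence
#'
#' Code 128 subset B covers ASCII 32-126, which includes every character a
#' structured identifier can contain. The symbol sequence is
#' `[104, data..., checksum, 106]`: start code B, one value per character
#' (ASCII minus 32), the mod-103 weighted checksum
#' `(104 + sum(i * value_i)) mod 103` with 1-based data positions, and the
#' stop code.
#'
#' @param text Non-empty string, all characters in ASCII 32-126.
#' @return A `code128` object: list with `text` and integer `values`.
#' @examples
#' encode_128b("ABC")$values # 104 33 34 35 1 106
#' @export
encode_128b <- function(text) {
  text <- as.character(text)
  if (length(text) != 1L || !nzchar(text)) {
    stop("text must be a non-empty string", call. = FALSE)
  }
  codes <- utf8ToInt(text)
  if (any(codes < 32L | codes > 126L)) {
    stop("Code 128B encodes ASCII 32-126 only; offending character in '",
         text, "'", call. = FALSE)
  }
  data <- codes - 32L
  checksum <- (104L + sum(seq_along(data) * data)) %% 103L
  structure(list(text = text, values = c(104L, data, checksum, 106L)),
            class = "code128")
}

#' @export
print.code128 <- function(x, ...) {
  cat("<code128> \"", x$text, "\": ", paste(x$values, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

# conventional Code 128 barcode-font mapping: symbol values 0-94 print as
# ASCII 32-126; values 95-106 as codepoints 195-206
font_char <- function(values) {
  intToUtf8(ifelse(values <= 94L, values + 32L, values + 100L), multiple = FALSE)
}

#' Barcode-font string for a Code 128 sequence
#'
#' Maps each symbol value to the codepoint a standard Code 128 barcode font
#' prints as bars: values 0-94 to ASCII 32-126, values 95-106 (including
#' start/stop) to codepoints 195-206. The mapping is invertible;
#' [decode_font_string()] recovers the symbol values exactly.
#'
#' @param x A `code128` object from [encode_128b()].
#' @return A single string, one character per symbol.
#' @examples
#' s <- to_font_string(encode_128b("ABC"))
#' decode_font_string(s)
#' @export
to_font_string <- function(x) {
  stopifnot(inherits(x, "code128"))
  font_char(x$values)
}

#' @rdname to_font_string
#' @param font Font string produced by [to_font_string()].
#' @export
decode_font_string <- function(font) {
  cp <- utf8ToInt(font)
  if (any(cp < 32L | (cp > 126L & cp < 195L) | cp > 206L)) {
    stop("not a Code 128 font string", call. = FALSE)
  }
  as.integer(ifelse(cp <= 126L, cp - 32L, cp - 100L))
}

#' Validate the embedded checksum of a Code 128 sequence
#'
#' Recomputes the mod-103 weighted checksum from the start code and data
#' values and compares it with the embedded symbol.
#'
#' @param values Integer vector of symbol values (start, data..., checksum,
#'   stop).
#' @return `TRUE` iff start/stop codes are in place and the checksum matches.
#' @export
validate_128b <- function(values) {
  if (length(values) < 4L) return(FALSE)
  n <- length(values)
  if (values[1L] != 104L || values[n] != 106L) return(FALSE)
  data <- values[2:(n - 2L)]
  values[n - 1L] == (104L + sum(seq_along(data) * data)) %% 103L
}
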