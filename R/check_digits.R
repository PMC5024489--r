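#' Character values for check-digit arithmetic
#'
#' Digits contribute their numeric value; letters contribute their ASCII code
#' (65 for "A"). The parity and weighted-parity schemes use this value
#' directly; the table-based schemes (Damm, Gumm) reduce it modulo 10 so the
#' quasigroup/modular tables stay on the digit domain.
#'
#' @param chars Character vector of single characters (digits or letters).
#' @return Integer vector of character values.
#' @examples
#' char_value(c("A", "7", "B"))
#' @export
char_value <- function(chars) {
  chars <- as.character(chars)
  if (any(nchar(chars) != 1L) || any(!grepl("^[0-9A-Za-z]$", chars))) {
    stop("characters must be single digits or letters", call. = FALSE)
  }
  is_digit <- grepl("^[0-9]$", chars)
  out <- integer(length(chars))
  out[is_digit] <- as.integer(chars[is_digit])
  out[!is_digit] <- vapply(chars[!is_digit], utf8ToInt, integer(1),
                           USE.NAMES = FALSE)
  out
}

payload_chars <- function(payload) {
  payload <- as.character(payload)
  if (length(payload) != 1L || !nzchar(payload)) {
    stop("payload must be a non-empty string", call. = FALSE)
  }
  strsplit(payload, "", fixed = TRUE)[[1]]
}

#' Check-digit algorithms
#'
#' Four schemes, differing in the error classes they detect when an ID is
#' typed by hand:
#'
#' * `check_parity()`: sum of character values mod 10. Detects any single
#'   substitution whose value change is nonzero mod 10, but no transpositions.
#' * `check_weighted_parity()`: sum of position-weighted character values
#'   (1-based from the left) mod 10. Additionally detects every adjacent
#'   transposition of distinct digits, but misses some non-adjacent ones.
#' * `check_damm()`: walk through a totally anti-symmetric quasigroup of
#'   order 10 (Damm's construction), starting at interim digit 0; the final
#'   interim digit is the check. Detects all single-digit substitutions and
#'   all adjacent transpositions; appending the check digit to its payload
#'   makes the walk end at 0.
#' * `check_gumm()`: a mod-11 scheme with position weights `2^i`: the check
#'   digit `c` satisfies `sum(2^i * value_i) + c == 0 (mod 11)`. Because 2
#'   generates the multiplicative group mod 11, all substitutions and all
#'   transpositions (adjacent or not) within payloads of up to 9 characters
#'   are detected. When the required `c` is 10 no single decimal digit works
#'   and the function returns `NA` — the REDRAW signal: the caller discards
#'   the candidate random number and draws another, keeping IDs fixed-width.
#'
#' Letters are valued by [char_value()]; the table-based schemes (Damm, Gumm)
#' reduce letter values mod 10.
#'
#' @param payload Non-empty string of digits/letters (the rendered ID minus
#'   its check position).
#' @return A single check digit 0-9, or `NA` (REDRAW) for `check_gumm()` when
#'   the scheme yields check value 10.
#' @examples
#' check_parity("123")          # 6
#' check_weighted_parity("123") # 4
#' check_damm("572")            # 4
#' check_gumm("124")            # 2
#' check_gumm("123")            # NA: REDRAW
#' @name check_digit_algorithms
NULL

#' @rdname check_digit_algorithms
#' @export
check_parity <- function(payload) {
  sum(char_value(payload_chars(payload))) %% 10
}

#' @rdname check_digit_algorithms
#' @export
check_weighted_parity <- function(payload) {
  v <- char_value(payload_chars(payload))
  sum(seq_along(v) * v) %% 10
}

# Damm's published totally anti-symmetric quasigroup of order 10
# (zero diagonal, so the check digit of p is the digit d with walk(p, d) = 0)
DAMM_TABLE <- matrix(c(
  0, 3, 1, 7, 5, 9, 8, 6, 4, 2,
  7, 0, 9, 2, 1, 5, 4, 8, 6, 3,
  4, 2, 0, 6, 8, 7, 1, 3, 5, 9,
  1, 7, 5, 0, 9, 8, 3, 4, 2, 6,
  6, 1, 2, 3, 0, 4, 5, 9, 7, 8,
  3, 6, 7, 4, 2, 0, 9, 5, 8, 1,
  5, 8, 6, 9, 7, 2, 0, 1, 3, 4,
  8, 9, 4, 5, 3, 6, 2, 0, 1, 7,
  9, 4, 3, 8, 6, 1, 7, 2, 0, 5,
  2, 5, 8, 1, 4, 3, 6, 7, 9, 0
), nrow = 10, byrow = TRUE)

#' @rdname check_digit_algorithms
#' @export
check_damm <- function(payload) {
  v <- char_value(payload_chars(payload)) %% 10
  interim <- 0L
  for (d in v) interim <- DAMM_TABLE[interim + 1L, d + 1L]
  as.integer(interim)
}

#' @rdname check_digit_algorithms
#' @export
check_gumm <- function(payload) {
  v <- char_value(payload_chars(payload)) %% 10
  # 2^i mod 11 cycles with period 10; payloads here are short but keep it exact
  w <- vapply(seq_along(v), function(i) 2^(i %% 10) %% 11, numeric(1))
  s <- sum(w * v) %% 11
  c_val <- (11 - s) %% 11
  if (c_val == 10) NA_integer_ else as.integer(c_val)
}

#' Compute a check digit under a named algorithm
#'
#' Dispatch over the configured algorithm name. `NA` (REDRAW) can only arise
#' for `"GUMM_1986"`.
#'
#' @param payload Non-empty digits/letters string.
#' @param algorithm One of `"PARITY"`, `"WEIGHTED_PARITY"`, `"GUMM_1986"`,
#'   `"DAMM_2004"`.
#' @return Check digit 0-9, or `NA` for the Gumm REDRAW signal.
#' @examples
#' compute_check("123", "PARITY")
#' @export
compute_check <- function(payload, algorithm) {
  switch(toupper(algorithm),
    PARITY = check_parity(payload),
    WEIGHTED_PARITY = check_weighted_parity(payload),
    GUMM_1986 = check_gumm(payload),
    DAMM_2004 = check_damm(payload),
    stop("unknown check algorithm: ", algorithm, call. = FALSE)
  )
}

#' Verify the check digit of an assembled identifier
#'
#' Parses `id` by the fixed block widths of `config`, recomputes the check
#' digit over all non-check characters in rendered order, and compares it with
#' the embedded one. An unparseable string (wrong length, non-digit check
#' position) is an error, distinct from a clean `FALSE`.
#'
#' @param id The identifier string.
#' @param config A [study_config()] whose layout contains a check block.
#' @return `TRUE` iff the embedded check digit matches the recomputed one.
#' @examples
#' cfg <- study_config("S", "C,T,N,V,X", k = 5, center = "9",
#'                     tracks = c("1" = 10), check_algorithm = "PARITY")
#' verify_id("911234516", cfg)
#' @export
verify_id <- function(id, config) {
  stopifnot(inherits(config, "study_config"))
  if (!has_block(config$layout, "X")) {
    stop("layout has no check block to verify", call. = FALSE)
  }
  parts <- parse_id(id, config)
  payload <- paste(parts$payload_chars, collapse = "")
  expected <- compute_check(payload, config$check_algorithm)
  if (!grepl("^[0-9]$", parts$check)) {
    stop("check position of '", id, "' is not a digit", call. = FALSE)
  }
  !is.na(expected) && as.integer(parts$check) == expected
}
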