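#' ID blocks and block layouts
#'
#' A structured study identifier is assembled from an ordered sequence of
#' blocks: `C` (study center code), `T` (study track code), `N` (the unique
#' random number), `V` (study visit code) and `X` (check digit). The random
#' number block is mandatory; every other block is optional and the order is
#' free. `block_layout()` builds and validates a layout from block kind codes;
#' `parse_layout()` parses the compact comma-separated form used on the
#' command line (e.g. `"C,T,N,V,X"`).
#'
#' @param kinds Character vector of block kind codes, each one of
#'   `"C"`, `"T"`, `"N"`, `"V"`, `"X"`, in the order they appear in the
#'   rendered identifier.
#' @return A `block_layout` object: a character vector of block kinds with
#'   class attribute, order preserved.
#' @examples
#' block_layout(c("C", "T", "N", "V", "X"))
#' parse_layout("N,V")
#' @export
block_layout <- function(kinds) {
  kinds <- toupper(as.character(kinds))
  valid <- c("C", "T", "N", "V", "X")
  if (length(kinds) == 0L) {
    stop("layout must contain at least the number block 'N'", call. = FALSE)
  }
  bad <- setdiff(kinds, valid)
  if (length(bad) > 0L) {
    stop("unknown block kind(s): ", paste(bad, collapse = ", "),
         " (valid: C, T, N, V, X)", call. = FALSE)
  }
  if (sum(kinds == "N") != 1L) {
    stop("layout must contain exactly one number block 'N'", call. = FALSE)
  }
  dup <- names(which(table(kinds) > 1L))
  if (length(dup) > 0L) {
    stop("block(s) may appear at most once: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(kinds, class = "block_layout")
}

#' @rdname block_layout
#' @param spec A compact layout string, block kinds separated by commas
#'   (whitespace tolerated), e.g. `"C,T,N,V,X"`.
#' @export
parse_layout <- function(spec) {
  spec <- paste(spec, collapse = ",")
  kinds <- strsplit(gsub("[[:space:]]", "", spec), ",", fixed = TRUE)[[1]]
  block_layout(kinds[nzchar(kinds)])
}

#' @export
print.block_layout <- function(x, ...) {
  cat("<block_layout> [", paste(unclass(x), collapse = "]["), "]\n", sep = "")
  invisible(x)
}

#' @export
format.block_layout <- function(x, ...) paste(unclass(x), collapse = ",")

has_block <- function(layout, kind) kind %in% unclass(layout)

#' Block character widths for fixed-width parsing
#'
#' Every block has a fixed character width within one study: the center and
#' track widths are the lengths of the configured codes (all track codes must
#' share one width), the number block is `k` characters wide, and the visit
#' and check blocks are one character each. Fixed widths make assembled
#' identifiers parseable without delimiters.
#'
#' @param config A [study_config()] object.
#' @return Named integer vector of widths for the blocks present in the
#'   layout, in layout order.
#' @keywords internal
block_widths <- function(config) {
  w <- vapply(unclass(config$layout), function(kind) {
    switch(kind,
      C = nchar(config$center),
      T = if (length(config$tracks) > 0L) nchar(config$tracks[[1L]]$code) else 0L,
      N = as.integer(config$k),
      V = 1L,
      X = 1L
    )
  }, integer(1))
  names(w) <- unclass(config$layout)
  w
}
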