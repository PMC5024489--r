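#' Visit code actually rendered for one identifier layer
#'
#' The personal-data identifier ID-P always carries visit "0" — personal data
#' do not vary by visit — while the study-data ID-S and linkage ID-T carry the
#' configured visit code.
#'
#' @param layer One of `"P"`, `"S"`, `"T"`.
#' @param configured_visit The study's visit code.
#' @return The single visit character to render.
#' @examples
#' visit_code_for_layer("P", "1") # "0"
#' visit_code_for_layer("S", "A") # "A"
#' @export
visit_code_for_layer <- function(layer, configured_visit) {
  layer <- match.arg(toupper(layer), c("P", "S", "T"))
  if (layer == "P") "0" else as.character(configured_visit)
}

#' Assemble an identifier string from its blocks
#'
#' Concatenates the configured blocks in layout order: center code, track
#' code, the k-digit random number, visit code and — last computed — the check
#' digit, which is taken over all other rendered characters in their rendered
#' order and substituted into the check block's position. Deterministic: the
#' same inputs always give the same string.
#'
#' @param config A [study_config()].
#' @param number The layer's random number; must have exactly `k` digits.
#' @param track Track code (required when the layout has a track block).
#' @param visit Visit character actually rendered (see
#'   [visit_code_for_layer()]); defaults to the configured visit.
#' @return The identifier string. Errors if the number has the wrong digit
#'   count, a code for a selected block is missing, or the Gumm scheme signals
#'   REDRAW for this payload (`condition` class `cohortid_redraw`).
#' @examples
#' cfg <- study_config("S", "C,T,N,V", k = 5, center = "9",
#'                     tracks = c("1" = 10), visit = "1")
#' assemble_id(cfg, 12345, track = "1") # "9112345 1" without the space
#' @export
assemble_id <- function(config, number, track = NULL, visit = config$visit) {
  stopifnot(inherits(config, "study_config"))
  number <- as.numeric(number)
  if (length(number) != 1L || is.na(number) || number != round(number) ||
      nchar(format(number, scientific = FALSE)) != config$k) {
    stop("number must have exactly k = ", config$k, " digits", call. = FALSE)
  }
  rendered <- vapply(unclass(config$layout), function(kind) {
    switch(kind,
      C = {
        if (is.null(config$center)) stop("layout has a center block but no center code", call. = FALSE)
        config$center
      },
      T = {
        if (is.null(track)) stop("layout has a track block but no track code given", call. = FALSE)
        as.character(track)
      },
      N = format(number, scientific = FALSE),
      V = {
        v <- as.character(visit)
        if (nchar(v) != 1L) stop("visit code must be one character", call. = FALSE)
        v
      },
      X = "X" # placeholder, substituted below
    )
  }, character(1))

  if (has_block(config$layout, "X")) {
    payload <- paste(rendered[names(rendered) != "X"], collapse = "")
    digit <- compute_check(payload, config$check_algorithm)
    if (is.na(digit)) {
      stop(structure(
        class = c("cohortid_redraw", "error", "condition"),
        list(message = paste0("check scheme yields no single digit for payload '",
                              payload, "': redraw the random number"),
             call = NULL)))
    }
    rendered[names(rendered) == "X"] <- as.character(digit)
  }
  paste(rendered, collapse = "")
}

#' Parse an assembled identifier by its fixed block widths
#'
#' The inverse of [assemble_id()]: splits an identifier string into its
#' blocks using the study's fixed widths (center/track widths from the
#' configured codes, `k` for the number, 1 for visit and check).
#'
#' @param id Identifier string.
#' @param config A [study_config()].
#' @return A list with one entry per block present (`center`, `track`,
#'   `number` as numeric, `visit`, `check`) plus `payload_chars`, the
#'   non-check characters in rendered order.
#' @export
parse_id <- function(id, config) {
  stopifnot(inherits(config, "study_config"))
  id <- as.character(id)
  widths <- block_widths(config)
  if (nchar(id) != sum(widths)) {
    stop("'", id, "' has ", nchar(id), " characters; layout [",
         paste(names(widths), collapse = "]["), "] requires ", sum(widths),
         call. = FALSE)
  }
  pos <- cumsum(c(1L, widths))
  parts <- list()
  chars <- character(0)
  for (i in seq_along(widths)) {
    piece <- substr(id, pos[i], pos[i + 1L] - 1L)
    kind <- names(widths)[i]
    if (kind != "X") chars <- c(chars, strsplit(piece, "")[[1]])
    parts[[switch(kind, C = "center", T = "track", N = "number",
                  V = "visit", X = "check")]] <- piece
  }
  if (!is.null(parts$number)) {
    if (!grepl("^[0-9]+$", parts$number)) {
      stop("number block of '", id, "' is not numeric", call. = FALSE)
    }
    parts$number <- as.numeric(parts$number)
  }
  parts$payload_chars <- chars
  parts
}
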