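#' Layer intervals for the unique random numbers
#'
#' The k-digit number range `[10^(k-1), 10^k)` is split into three equal
#' thirds, one per identifier layer: the personal-data layer P owns
#' `[1e(k-1), 4e(k-1))`, the study-data layer S owns `[4e(k-1), 7e(k-1))` and
#' the temporary linkage layer T owns `[7e(k-1), 10e(k-1))`. Because the
#' thirds are disjoint, the layer of any number is recoverable from the number
#' alone, and the three IDs of one participant can never collide. For k = 5
#' this gives P in \[10,000; 40,000), S in \[40,000; 70,000) and T in
#' \[70,000; 100,000).
#'
#' @param k Random-number length in digits (2 to 9).
#' @param layer One of `"P"`, `"S"`, `"T"`.
#' @return A `layer_interval`: list with `layer`, `lower` (inclusive),
#'   `upper` (exclusive).
#' @examples
#' layer_interval(5, "P")
#' layer_interval(9, "T")
#' @export
layer_interval <- function(k, layer = c("P", "S", "T")) {
  check_k(k)
  layer <- match.arg(toupper(layer), c("P", "S", "T"))
  base <- 10^(k - 1)
  bounds <- switch(layer,
    P = c(1, 4),
    S = c(4, 7),
    T = c(7, 10)
  )
  structure(list(layer = layer, lower = bounds[1] * base, upper = bounds[2] * base),
            class = "layer_interval")
}

#' @export
print.layer_interval <- function(x, ...) {
  cat(sprintf("<layer_interval> %s: [%s; %s)\n", x$layer,
              format(x$lower, big.mark = ",", scientific = FALSE),
              format(x$upper, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Per-layer identifier capacity
#'
#' Each layer owns one third of the k-digit numbers, so at most
#' `3 * 10^(k-1)` unique identifiers (equivalently, unique key pairs) can be
#' issued per layer: 30,000 at k = 5 and 300,000,000 at the maximum supported
#' length k = 9. With `strict = FALSE` the formula is evaluated for lengths
#' outside the supported 2..9 range, for capacity-planning arithmetic only
#' (e.g. a hypothetical k = 10 gives 3e9 per layer, 9e9 over three layers).
#'
#' @param k Random-number length in digits.
#' @param strict Enforce the supported range 2..9 (default `TRUE`).
#' @return The capacity as a double (capacities above `.Machine$integer.max`
#'   are representable exactly).
#' @examples
#' id_capacity(5)
#' id_capacity(9)
#' @export
id_capacity <- function(k, strict = TRUE) {
  if (strict) check_k(k) else stopifnot(length(k) == 1L, k == round(k), k >= 1)
  3 * 10^(k - 1)
}

#' External-ID number pool
#'
#' External IDs (ID-E) hand study data to outside partners without exposing
#' the study-internal numbers. Their random part is drawn from the full
#' (k+1)-digit range `[10^k, 10^(k+1))` — one digit longer than the study's
#' internal numbers, so an ID-E random part can never be mistaken for (or
#' collide with) a P/S/T number.
#'
#' @param k The study's random-number length (2 to 8; k = 9 is refused since
#'   a 10-digit external pool would exceed the supported lengths).
#' @return A `layer_interval` with `layer = "E"`.
#' @examples
#' external_interval(5) # 6-digit numbers
#' @export
external_interval <- function(k) {
  stopifnot(length(k) == 1L, !is.na(k), k == round(k))
  if (k < 2 || k > 8) {
    stop("external IDs need k between 2 and 8 (ID-E uses k+1 digits)", call. = FALSE)
  }
  structure(list(layer = "E", lower = 10^k, upper = 10^(k + 1)),
            class = "layer_interval")
}

check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 2 || k > 9) {
    stop("random-number length k must be a whole number between 2 and 9",
         call. = FALSE)
  }
  invisible(k)
}

# layer of a number given k, from the interval bounds alone; NA if outside
# the k-digit range
number_layer <- function(number, k) {
  base <- 10^(k - 1)
  dplyr::case_when(
    number >= base & number < 4 * base ~ "P",
    number >= 4 * base & number < 7 * base ~ "S",
    number >= 7 * base & number < 10 * base ~ "T",
    TRUE ~ NA_character_
  )
}
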