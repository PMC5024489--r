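#' Study configuration
#'
#' Bundles every parameter of one study: the study name (used as the output
#' directory name), the block layout, the study center code, the track codes
#' with their per-track sample sizes, the random-number length `k`, the visit
#' code and the check-digit algorithm. Construction is permissive — invalid
#' values are allowed so that [validate_config()] can report every problem at
#' once, mirroring a pre-flight plausibility check.
#'
#' @param study_name Study name; names the directory identifiers are stored in.
#' @param layout A [block_layout()] or a compact layout string (`"C,T,N,V,X"`).
#' @param k Random-number length in digits (supported range 2 to 9).
#' @param tracks Named integer vector of per-track sample sizes, names are the
#'   track codes (e.g. `c("1" = 5000, "2" = 2000)`). When the layout has no
#'   track block, a single unnamed size gives the implicit track.
#' @param center Study center code rendered into the ID, or `NULL` when the
#'   layout has no center block.
#' @param visit Visit code: one character, a digit 1-9 or a letter other than
#'   `"i"`, `"e"`, `"o"` (case sensitive). The personal-data layer always
#'   renders visit `"0"` regardless of this setting.
#' @param check_algorithm One of `"NONE"`, `"PARITY"`, `"WEIGHTED_PARITY"`,
#'   `"GUMM_1986"`, `"DAMM_2004"`.
#' @param seed Optional non-negative integer seed for reproducible draws.
#' @return A `study_config` object (a named list).
#' @seealso [validate_config()], [create_ids()]
#' @examples
#' cfg <- study_config("DEMO", layout = "T,N,V,X", k = 5,
#'                     tracks = c("1" = 100, "2" = 50),
#'                     visit = "1", check_algorithm = "DAMM_2004")
#' validate_config(cfg)
#' @export
study_config <- function(study_name,
                         layout = "N",
                         k = 5,
                         tracks = c(100),
                         center = NULL,
                         visit = "1",
                         check_algorithm = "NONE",
                         seed = NULL) {
  if (!inherits(layout, "block_layout")) layout <- parse_layout(layout)
  track_codes <- names(tracks)
  if (is.null(track_codes)) track_codes <- rep("", length(tracks))
  tracks <- lapply(seq_along(tracks), function(i) {
    list(code = track_codes[[i]], n = as.numeric(tracks[[i]]))
  })
  structure(
    list(
      study_name = as.character(study_name),
      layout = layout,
      k = as.numeric(k),
      tracks = tracks,
      center = if (is.null(center)) NULL else as.character(center),
      visit = as.character(visit),
      check_algorithm = toupper(as.character(check_algorithm)),
      seed = if (is.null(seed)) NULL else as.numeric(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> ", x$study_name, "\n", sep = "")
  cat("  layout: [", paste(unclass(x$layout), collapse = "]["), "]\n", sep = "")
  cat("  k:", x$k, " check:", x$check_algorithm, " visit:", x$visit, "\n")
  if (!is.null(x$center)) cat("  center:", x$center, "\n")
  cat("  tracks:", paste(vapply(x$tracks, function(t)
    sprintf("%s (n=%s)", if (nzchar(t$code)) t$code else "<implicit>",
            format(t$n, big.mark = ",")), character(1)), collapse = "; "), "\n")
  invisible(x)
}

CHECK_ALGORITHMS <- c("NONE", "PARITY", "WEIGHTED_PARITY", "GUMM_1986", "DAMM_2004")

# codes rendered into IDs must be strictly alphanumeric (no spaces or
# punctuation); study names may additionally use '-' and '_' since they only
# name directories and files
is_code <- function(x) {
  length(x) == 1L && is.character(x) && nzchar(x) && grepl("^[A-Za-z0-9]+$", x)
}
is_name <- function(x) {
  length(x) == 1L && is.character(x) && nzchar(x) && grepl("^[A-Za-z0-9_-]+$", x)
}
is_valid_visit <- function(v) {
  length(v) == 1L && is.character(v) && grepl("^[1-9A-Za-z]$", v) &&
    !v %in% c("i", "e", "o")
}

#' Validate a study configuration
#'
#' The pre-flight plausibility check run before any identifiers are generated.
#' Every violated rule contributes one issue; nothing is generated when the
#' report is not clean. Rules: block codes must be non-empty alphanumeric
#' strings; track codes must be unique and share one width; sample sizes must
#' be positive whole numbers; `k` must lie in 2..9; the visit code must be a
#' single digit 1-9 or letter other than `"i"`, `"e"`, `"o"`; and the total
#' requested sample size per layer must be strictly below the per-layer
#' capacity `3 * 10^(k-1)`.
#'
#' @param config A [study_config()] object.
#' @return A `validation_report`: list with `ok` (logical) and `issues`
#'   (tibble with columns `field`, `message`); `ok` is `TRUE` iff `issues`
#'   has no rows.
#' @examples
#' validate_config(study_config("S", "N", k = 5, tracks = 30001))$issues
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "study_config"))
  issues <- list()
  flag <- function(field, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(field = field, message = message)
  }

  if (!is_name(config$study_name)) {
    flag("study_name", "study name must be non-empty, letters/digits/'-'/'_' only")
  }
  if (length(config$k) != 1L || is.na(config$k) || config$k != round(config$k) ||
      config$k < 2 || config$k > 9) {
    flag("k", "random-number length k must be a whole number between 2 and 9")
  }

  if (has_block(config$layout, "C")) {
    if (is.null(config$center) || !is_code(config$center)) {
      flag("center", "center block selected: center code must be non-empty alphanumeric")
    }
  }

  codes <- vapply(config$tracks, `[[`, character(1), "code")
  sizes <- vapply(config$tracks, `[[`, numeric(1), "n")
  if (has_block(config$layout, "T")) {
    if (length(codes) == 0L) {
      flag("tracks", "track block selected: at least one track code is required")
    }
    if (any(!vapply(codes, is_code, logical(1)))) {
      flag("tracks", "track codes must be non-empty alphanumeric")
    }
    if (anyDuplicated(codes)) {
      flag("tracks", "duplicate track code: track names must be unique")
    }
    if (length(unique(nchar(codes[nzchar(codes)]))) > 1L) {
      flag("tracks", "track codes must all have the same width")
    }
  } else {
    if (length(config$tracks) != 1L) {
      flag("tracks", "without a track block there is exactly one (implicit) track")
    }
    if (any(nzchar(codes))) {
      flag("tracks", "track codes given but layout has no track block")
    }
  }
  if (length(sizes) == 0L || any(is.na(sizes)) || any(sizes != round(sizes)) ||
      any(sizes < 1)) {
    flag("sample_size", "every track needs a positive whole sample size")
  }

  if (has_block(config$layout, "V") && !is_valid_visit(config$visit)) {
    flag("visit", "visit code not allowed: one digit 1-9 or letter, excluding 'i', 'e', 'o'")
  }

  if (!config$check_algorithm %in% CHECK_ALGORITHMS) {
    flag("check_algorithm",
         paste("unknown check algorithm; use one of:",
               paste(CHECK_ALGORITHMS, collapse = ", ")))
  } else if (has_block(config$layout, "X") && config$check_algorithm == "NONE") {
    flag("check_algorithm", "check block selected but no check algorithm chosen")
  }

  # capacity: each layer owns one third of the k-digit range; the total request
  # must stay strictly below it
  if (length(config$k) == 1L && !is.na(config$k) && config$k == round(config$k) &&
      config$k >= 2 && config$k <= 9 && length(sizes) > 0L && !any(is.na(sizes))) {
    if (sum(sizes) >= id_capacity(config$k)) {
      flag("sample_size", sprintf(
        "requested combinations exceed capacity: %s requested, %s available per layer at k=%d",
        format(sum(sizes), big.mark = ","),
        format(id_capacity(config$k), big.mark = ","), config$k))
    }
  }

  if (!is.null(config$seed) &&
      (length(config$seed) != 1L || is.na(config$seed) ||
       config$seed != round(config$seed) || config$seed < 0)) {
    flag("seed", "seed must be a non-negative whole number")
  }

  issues <- if (length(issues) > 0L) {
    dplyr::bind_rows(issues)
  } else {
    tibble::tibble(field = character(), message = character())
  }
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("<validation_report> ok\n")
  } else {
    cat("<validation_report>", nrow(x$issues), "issue(s):\n")
    for (i in seq_len(nrow(x$issues))) {
      cat("  -", x$issues$field[i], ":", x$issues$message[i], "\n")
    }
  }
  invisible(x)
}

# stop with a readable multi-line message when a config fails validation
assert_valid_config <- function(config) {
  report <- validate_config(config)
  if (!report$ok) {
    stop("invalid study configuration:\n",
         paste0("  - ", report$issues$field, ": ", report$issues$message,
                collapse = "\n"),
         call. = FALSE)
  }
  invisible(config)
}
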