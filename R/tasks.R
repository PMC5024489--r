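#' @title Study tasks: create, extend, new visit, new track, external IDs
#' @description
#' The task layer turns validated configurations into key-pair files on disk.
#' One study lives in one directory (named after the study), holding the
#' persisted configuration (`config.xml`), the key-pair files, their barcode
#' companions, archived batches (`.old`) and an audit log. All uniqueness
#' guarantees are scoped to the study directory: every task reconstructs the
#' already-issued numbers from the files present before drawing anything new.
#' @name study_tasks
NULL

CONFIG_FILENAME <- "config.xml"
AUDIT_FILENAME <- "audit.log"

audit_log <- function(dir, task, details, seed = NULL) {
  line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), task, details,
                if (is.null(seed)) "seed=NA" else paste0("seed=", seed),
                sep = "\t")
  cat(line, "\n", sep = "", file = file.path(dir, AUDIT_FILENAME), append = TRUE)
}

# draw one layer number and assemble its ID, redrawing on the Gumm REDRAW
# signal so every emitted ID keeps a one-digit check
assemble_with_redraw <- function(config, pool, rng, track, visit, progress = FALSE) {
  for (attempt in 1:1000) {
    number <- draw_unique(pool, 1, rng)
    id <- tryCatch(
      assemble_id(config, number, track = track, visit = visit),
      cohortid_redraw = function(e) NULL
    )
    if (!is.null(id)) return(list(id = id, number = number))
  }
  stop("could not find a number with a representable check digit after 1000 draws",
       call. = FALSE)
}

# draw n (ID-P, ID-S, ID-T) triples for one track and assemble the IDs
draw_track_batch <- function(config, pools, track, n, rng, progress = FALSE) {
  uses_gumm <- has_block(config$layout, "X") && config$check_algorithm == "GUMM_1986"
  rows <- vector("list", 3L)
  names(rows) <- c("P", "S", "T")
  for (layer in c("P", "S", "T")) {
    visit <- visit_code_for_layer(layer, config$visit)
    if (!uses_gumm) {
      numbers <- draw_unique(pools[[layer]], n, rng, progress = progress)
      ids <- vapply(numbers, function(nr)
        assemble_id(config, nr, track = track, visit = visit), character(1))
    } else {
      numbers <- numeric(n)
      ids <- character(n)
      for (i in seq_len(n)) {
        hit <- assemble_with_redraw(config, pools[[layer]], rng, track, visit)
        numbers[i] <- hit$number
        ids[i] <- hit$id
      }
    }
    rows[[layer]] <- tibble::tibble(number = numbers, id = ids)
  }
  tibble::tibble(
    track = track,
    idp = rows$P$id, np = rows$P$number,
    ids = rows$S$id, ns = rows$S$number,
    idt = rows$T$id, nt = rows$T$number
  )
}

write_pair_with_barcode <- function(dir, filename, pairs) {
  write_keypairs(pairs, file.path(dir, filename))
  barcode_name <- sub("\\.txt$", "_barcode.txt", filename)
  barcode_pairs <- tibble::tibble(
    left = vapply(pairs[[1]], function(x) to_font_string(encode_128b(x)), character(1)),
    right = vapply(pairs[[2]], function(x) to_font_string(encode_128b(x)), character(1))
  )
  write_keypairs(barcode_pairs, file.path(dir, barcode_name))
  c(filename, barcode_name)
}

#' Create the baseline identifier batch of a study
#'
#' Runs the full create workflow: validate the configuration, draw, for each
#' track, `n` guaranteed-unique (ID-P, ID-S, ID-T) number triples from the
#' three disjoint layer intervals, assemble the structured identifiers
#' (ID-P always rendered with visit "0"), and write per track two key-pair
#' files — (ID-P, ID-T) in creation order and (ID-S, ID-T) in randomized row
#' order, so file order alone cannot re-associate personal and study IDs —
#' plus Code 128B barcode companions. The configuration is persisted in the
#' study directory so later tasks are self-describing.
#'
#' @param config A valid [study_config()].
#' @param root Parent directory; the study directory `root/study_name` is
#'   created (it must not already contain key-pair files).
#' @param seed Optional seed overriding `config$seed`.
#' @param progress Print draw progress.
#' @param audit Append an audit-log line (timestamped; disable for
#'   byte-reproducible fixtures).
#' @return Invisibly, a tibble of the generated triples (columns `track`,
#'   `idp`, `np`, `ids`, `ns`, `idt`, `nt`), with the written file names in
#'   attribute `"files"` and the directory in attribute `"dir"`.
#' @examples
#' cfg <- study_config("DEMO", "N,V", k = 3, tracks = 5, seed = 7)
#' res <- create_ids(cfg, root = tempdir())
#' attr(res, "files")
#' @export
create_ids <- function(config, root = ".", seed = config$seed,
                       progress = FALSE, audit = TRUE) {
  assert_valid_config(config)
  dir <- file.path(root, config$study_name)
  if (dir.exists(dir) &&
      length(list.files(dir, pattern = "\\.(txt|old[0-9]*)$")) > 0L) {
    stop("study directory already contains key-pair files: ", dir,
         "; use add_ids() to extend the study", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  rng_draw <- rng_source(seed, "draw")
  rng_shuffle <- rng_source(seed, "shuffle")
  pools <- list(P = number_pool(config$k, "P"),
                S = number_pool(config$k, "S"),
                T = number_pool(config$k, "T"))

  batches <- lapply(config$tracks, function(t)
    draw_track_batch(config, pools, t$code, t$n, rng_draw, progress = progress))
  result <- dplyr::bind_rows(batches)

  files <- character(0)
  for (batch in batches) {
    track <- batch$track[1]
    n <- nrow(batch)
    f_pt <- keypair_filename(config$study_name, "IDP_IDT", track, n)
    files <- c(files, write_pair_with_barcode(
      dir, f_pt, tibble::tibble(left = batch$idp, right = batch$idt)))
    shuffled <- batch[rng_eval(rng_shuffle, sample.int(n)), ]
    f_st <- keypair_filename(config$study_name, "IDS_IDT", track, n)
    files <- c(files, write_pair_with_barcode(
      dir, f_st, tibble::tibble(left = shuffled$ids, right = shuffled$idt)))
  }

  save_config(config, file.path(dir, CONFIG_FILENAME))
  if (audit) {
    audit_log(dir, "create",
              sprintf("layout=%s k=%d n=%s files=%s", format(config$layout),
                      config$k,
                      paste(vapply(config$tracks, function(t)
                        format(t$n, scientific = FALSE), character(1)),
                        collapse = ";"),
                      paste(files, collapse = ",")), seed)
  }
  invisible(structure(result, files = files, dir = dir))
}

#' Reconstruct the state of a study directory
#'
#' Re-reads every key-pair file (current `.txt` and archived `.old*`) of a
#' study directory together with its persisted configuration, reconstructs
#' the per-layer sets of already-issued numbers, and checks internal
#' consistency: IDs parse under the study layout, numbers lie in their layer
#' intervals, no ID is duplicated within a file or across current baseline
#' files, and the ID-T sets of the (ID-P, ID-T) / (ID-S, ID-T) file pair of
#' each track agree. This reconstructed state is what scopes the uniqueness
#' guarantee of every later task.
#'
#' @param dir Study directory.
#' @return A `study_state`: list with `dir`, `config`, `files` (tibble of
#'   parsed file metadata), `used` (named list of per-layer number vectors;
#'   `E` is a list per project), `visits_used`, `projects`, and
#'   `current_n` (named vector: rows per track in the current baseline files).
#' @export
load_study <- function(dir) {
  if (!dir.exists(dir)) stop("study directory not found: ", dir, call. = FALSE)
  config_path <- file.path(dir, CONFIG_FILENAME)
  entries <- list.files(dir)
  metas <- dplyr::bind_rows(lapply(entries, parse_keypair_filename))
  if (nrow(metas) == 0L) {
    metas <- tibble::tibble(
      file = character(), kind = character(), track = character(),
      n = numeric(), visit = character(), project = character(),
      barcode = logical(), archived = logical())
  }
  if (!file.exists(config_path)) {
    if (nrow(metas) == 0L) {
      return(structure(list(dir = dir, config = NULL,
                            files = tibble::tibble(), used = list(),
                            visits_used = character(0),
                            projects = character(0),
                            current_n = numeric(0)),
                       class = "study_state"))
    }
    stop("study directory has key-pair files but no ", CONFIG_FILENAME, ": ",
         dir, call. = FALSE)
  }
  config <- load_config(config_path)
  if (nrow(metas) > 0L) metas <- metas[!metas$barcode, , drop = FALSE]

  used <- list(P = numeric(0), S = numeric(0), T = numeric(0), E = list())
  # numbers in the current (non-archived) baseline files, per layer, for the
  # cross-file duplicate check; .old archives legitimately repeat them
  current <- list(P = numeric(0), S = numeric(0))

  parse_column <- function(ids, file) {
    lapply(ids, function(id) {
      tryCatch(parse_id(id, config), error = function(e) {
        stop("corrupt key-pair file ", file, ": ", conditionMessage(e),
             call. = FALSE)
      })
    })
  }
  check_no_dup <- function(ids, file, side) {
    if (anyDuplicated(ids)) {
      stop("consistency error in ", file, ": duplicated ", side, " IDs",
           call. = FALSE)
    }
  }
  record_layer <- function(numbers, layer, file) {
    bad <- number_layer(numbers, config$k) != layer
    if (any(is.na(bad)) || any(bad)) {
      stop("consistency error in ", file, ": number outside the ", layer,
           " interval", call. = FALSE)
    }
    used[[layer]] <<- union(used[[layer]], numbers)
  }

  for (i in seq_len(nrow(metas))) {
    meta <- metas[i, ]
    rows <- read_keypairs(file.path(dir, meta$file))
    if (nrow(rows) == 0L) next
    check_no_dup(rows$left, meta$file, "left")
    check_no_dup(rows$right, meta$file, "right")
    if (meta$kind %in% c("IDP_IDT", "IDS_IDT")) {
      left_layer <- if (meta$kind == "IDP_IDT") "P" else "S"
      left_n <- vapply(parse_column(rows$left, meta$file), `[[`, numeric(1), "number")
      right_n <- vapply(parse_column(rows$right, meta$file), `[[`, numeric(1), "number")
      record_layer(left_n, left_layer, meta$file)
      record_layer(right_n, "T", meta$file)
      if (!meta$archived) {
        if (any(left_n %in% current[[left_layer]])) {
          stop("consistency error: ", left_layer, "-layer number reused across ",
               "current baseline files (", meta$file, ")", call. = FALSE)
        }
        current[[left_layer]] <- c(current[[left_layer]], left_n)
      }
    } else if (meta$kind == "IDS_IDSVISIT") {
      left_n <- vapply(parse_column(rows$left, meta$file), `[[`, numeric(1), "number")
      record_layer(left_n, "S", meta$file)
      # right column reuses the same S numbers with a new visit: no new numbers
    } else if (meta$kind == "IDS_IDE") {
      e_numbers <- vapply(rows$right, function(id) {
        body <- substr(id, nchar(meta$project) + 1L, nchar(id))
        if (has_block(config$layout, "X")) body <- substr(body, 1L, nchar(body) - 1L)
        if (!grepl("^[0-9]+$", body) || nchar(body) != config$k + 1) {
          stop("corrupt external ID '", id, "' in ", meta$file, call. = FALSE)
        }
        as.numeric(body)
      }, numeric(1), USE.NAMES = FALSE)
      used$E[[meta$project]] <- union(used$E[[meta$project]], e_numbers)
    }
  }

  # ID-T sets of the two current files of one track/batch must agree
  cur <- metas[!metas$archived & metas$kind %in% c("IDP_IDT", "IDS_IDT"), ,
               drop = FALSE]
  for (track in unique(cur$track)) {
    pair <- cur[cur$track == track, , drop = FALSE]
    t_sets <- lapply(seq_len(nrow(pair)), function(j) {
      rows <- read_keypairs(file.path(dir, pair$file[j]))
      sort(vapply(lapply(rows$right, parse_id, config = config), `[[`,
                  numeric(1), "number"))
    })
    if (length(t_sets) == 2L && !identical(t_sets[[1]], t_sets[[2]])) {
      stop("consistency error: ID-T sets differ between ",
           paste(pair$file, collapse = " and "), call. = FALSE)
    }
  }

  current_n <- stats::setNames(cur$n[cur$kind == "IDP_IDT"],
                               cur$track[cur$kind == "IDP_IDT"])
  visits_used <- unique(c(config$visit,
                          metas$visit[metas$kind == "IDS_IDSVISIT"]))
  structure(list(
    dir = dir, config = config, files = metas, used = used,
    visits_used = visits_used[!is.na(visits_used)],
    projects = unique(stats::na.omit(metas$project)),
    current_n = current_n
  ), class = "study_state")
}

#' @export
print.study_state <- function(x, ...) {
  cat("<study_state> ", x$dir, "\n", sep = "")
  if (is.null(x$config)) {
    cat("  empty (no configuration)\n")
    return(invisible(x))
  }
  cat("  layout: [", paste(unclass(x$config$layout), collapse = "]["),
      "], k=", x$config$k, ", check=", x$config$check_algorithm, "\n", sep = "")
  cat("  issued numbers: P=", length(x$used$P), " S=", length(x$used$S),
      " T=", length(x$used$T), "\n", sep = "")
  cat("  visits used:", paste(x$visits_used, collapse = ", "), "\n")
  if (length(x$projects) > 0L)
    cat("  external projects:", paste(x$projects, collapse = ", "), "\n")
  invisible(x)
}

state_pools <- function(state) {
  config <- state$config
  list(
    P = number_pool(config$k, "P", used = state$used$P),
    S = number_pool(config$k, "S", used = state$used$S),
    T = number_pool(config$k, "T", used = state$used$T)
  )
}

#' Extend a study with a new batch of identifiers
#'
#' Draws `n_new` additional (ID-P, ID-S, ID-T) triples per requested track,
#' guaranteed distinct from every number already issued anywhere in the study
#' (all tracks, all batches, archived files included). The previous key-pair
#' files are archived by renaming `.txt` to `.old` and merged files carrying
#' the new total in their `N=` label are written: (ID-P, ID-T) keeps creation
#' order with new rows appended; the merged (ID-S, ID-T) file is re-shuffled.
#'
#' @param dir Study directory (from [create_ids()]).
#' @param n_new Rows to add: a single count (applied to the only track), or a
#'   named vector of counts by track code.
#' @param seed Optional seed for this batch.
#' @param progress,audit As in [create_ids()].
#' @return Invisibly, the tibble of newly generated triples with attribute
#'   `"files"` (the merged files written).
#' @export
add_ids <- function(dir, n_new, seed = NULL, progress = FALSE, audit = TRUE) {
  state <- load_study(dir)
  if (is.null(state$config)) stop("not an initialized study: ", dir, call. = FALSE)
  config <- state$config
  track_codes <- vapply(config$tracks, `[[`, character(1), "code")

  if (is.null(names(n_new))) {
    if (length(n_new) != 1L || length(track_codes) != 1L) {
      stop("with multiple tracks, n_new must be a named vector of counts by track code",
           call. = FALSE)
    }
    target_tracks <- track_codes
  } else {
    target_tracks <- names(n_new)
  }
  counts <- as.numeric(n_new)
  unknown <- setdiff(target_tracks, track_codes)
  if (length(unknown) > 0L) {
    stop("unknown track(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(target_tracks)) {
    stop("each track may appear once in n_new", call. = FALSE)
  }
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("n_new must be positive whole numbers", call. = FALSE)
  }

  total_used <- length(state$used$P)
  if (total_used + sum(counts) > id_capacity(config$k)) {
    stop(sprintf(
      "capacity exhausted: %s issued + %s requested exceeds %s per layer at k=%d",
      format(total_used, big.mark = ","), format(sum(counts), big.mark = ","),
      format(id_capacity(config$k), big.mark = ","), config$k), call. = FALSE)
  }

  rng_draw <- rng_source(seed, "draw")
  rng_shuffle <- rng_source(seed, "shuffle")
  pools <- state_pools(state)
  current_n_of <- function(track) {
    idx <- match(track, names(state$current_n))
    if (is.na(idx)) 0 else unname(state$current_n[idx])
  }

  new_rows <- vector("list", length(target_tracks))
  writes <- vector("list", length(target_tracks)) # executed after all draws succeed
  for (i in seq_along(target_tracks)) {
    track <- target_tracks[i]
    batch <- draw_track_batch(config, pools, track, counts[i], rng_draw,
                              progress = progress)
    new_rows[[i]] <- batch

    old_n <- current_n_of(track)
    f_pt_old <- keypair_filename(config$study_name, "IDP_IDT", track, old_n)
    f_st_old <- keypair_filename(config$study_name, "IDS_IDT", track, old_n)
    prior_pt <- if (file.exists(file.path(dir, f_pt_old))) {
      read_keypairs(file.path(dir, f_pt_old))
    } else tibble::tibble(left = character(), right = character())
    prior_st <- if (file.exists(file.path(dir, f_st_old))) {
      read_keypairs(file.path(dir, f_st_old))
    } else tibble::tibble(left = character(), right = character())

    merged_n <- old_n + counts[i]
    merged_pt <- dplyr::bind_rows(prior_pt,
                                  tibble::tibble(left = batch$idp, right = batch$idt))
    merged_st <- dplyr::bind_rows(prior_st,
                                  tibble::tibble(left = batch$ids, right = batch$idt))
    merged_st <- merged_st[rng_eval(rng_shuffle, sample.int(nrow(merged_st))), ]
    writes[[i]] <- list(
      archive = c(f_pt_old, f_st_old,
                  sub("\\.txt$", "_barcode.txt", c(f_pt_old, f_st_old))),
      pt = list(name = keypair_filename(config$study_name, "IDP_IDT", track, merged_n),
                rows = merged_pt),
      st = list(name = keypair_filename(config$study_name, "IDS_IDT", track, merged_n),
                rows = merged_st)
    )
  }

  files <- character(0)
  for (w in writes) {
    for (f in w$archive) {
      p <- file.path(dir, f)
      if (file.exists(p)) file.rename(p, archive_name(p))
    }
    files <- c(files,
               write_pair_with_barcode(dir, w$pt$name, w$pt$rows),
               write_pair_with_barcode(dir, w$st$name, w$st$rows))
  }

  # keep the persisted per-track sample sizes in step with the files
  for (i in seq_along(config$tracks)) {
    code <- config$tracks[[i]]$code
    idx <- match(code, target_tracks)
    if (!is.na(idx)) {
      config$tracks[[i]]$n <- current_n_of(code) + counts[idx]
    }
  }
  save_config(config, file.path(dir, CONFIG_FILENAME))

  result <- dplyr::bind_rows(new_rows)
  if (audit) {
    audit_log(dir, "add-ids",
              sprintf("n_new=%s files=%s",
                      paste(target_tracks, counts, sep = "=", collapse = ";"),
                      paste(files, collapse = ",")), seed)
  }
  invisible(structure(result, files = files, dir = dir))
}

#' Issue follow-up identifiers for a new visit
#'
#' No new numbers are drawn: the study-data identifier of each participant
#' keeps its random number and only the visit character changes (the check
#' digit, when present, is recomputed over the new rendering). One key-pair
#' file per track maps the baseline ID-S to the new-visit ID-S, in the row
#' order of the current (ID-S, ID-T) file. ID-P and ID-T are never re-issued
#' for later visits.
#'
#' @param dir Study directory.
#' @param new_visit New visit code (single character, digits 1-9 or a letter
#'   other than "i", "e", "o"); must not have been used before in this study.
#' @param audit Append an audit-log line.
#' @return Invisibly, a tibble with columns `track`, `ids_baseline`,
#'   `ids_new`, with attribute `"files"`.
#' @export
add_visit <- function(dir, new_visit, audit = TRUE) {
  state <- load_study(dir)
  if (is.null(state$config)) stop("not an initialized study: ", dir, call. = FALSE)
  config <- state$config
  if (!has_block(config$layout, "V")) {
    stop("layout has no visit block; visits cannot be encoded", call. = FALSE)
  }
  if (!is_valid_visit(new_visit)) {
    stop("visit code not allowed: one digit 1-9 or letter, excluding 'i', 'e', 'o'",
         call. = FALSE)
  }
  if (new_visit %in% state$visits_used) {
    stop("visit '", new_visit, "' has already been used in this study",
         call. = FALSE)
  }

  widths <- block_widths(config)
  visit_pos <- cumsum(widths)[match("V", names(widths))]
  rebuild <- function(id) {
    parts <- parse_id(id, config)
    out <- id
    substr(out, visit_pos - widths[["V"]] + 1L, visit_pos) <- new_visit
    if (has_block(config$layout, "X")) {
      parts_new <- parse_id(out, config)
      digit <- compute_check(paste(parts_new$payload_chars, collapse = ""),
                             config$check_algorithm)
      if (is.na(digit)) {
        stop("check scheme yields no single digit for '", id,
             "' at visit '", new_visit,
             "': choose a different visit code", call. = FALSE)
      }
      xw <- cumsum(widths)[match("X", names(widths))]
      substr(out, xw - widths[["X"]] + 1L, xw) <- as.character(digit)
    }
    out
  }

  cur <- state$files[!state$files$archived & state$files$kind == "IDS_IDT", ,
                     drop = FALSE]
  if (nrow(cur) == 0L) stop("no current (ID-S, ID-T) files in ", dir, call. = FALSE)

  out <- list()
  files <- character(0)
  for (i in seq_len(nrow(cur))) {
    rows <- read_keypairs(file.path(dir, cur$file[i]))
    if (nrow(rows) == 0L) next
    new_ids <- vapply(rows$left, rebuild, character(1), USE.NAMES = FALSE)
    fname <- keypair_filename(config$study_name, "IDS_IDSVISIT", cur$track[i],
                              nrow(rows), visit = new_visit)
    files <- c(files, write_pair_with_barcode(
      dir, fname, tibble::tibble(left = rows$left, right = new_ids)))
    out[[cur$track[i]]] <- tibble::tibble(track = cur$track[i],
                                          ids_baseline = rows$left,
                                          ids_new = new_ids)
  }
  result <- dplyr::bind_rows(out)
  if (audit) {
    audit_log(dir, "add-visit", sprintf("visit=%s files=%s", new_visit,
                                        paste(files, collapse = ",")))
  }
  invisible(structure(result, files = files, dir = dir))
}

#' Register a new recruitment track
#'
#' Creates the empty (ID-P, ID-T) and (ID-S, ID-T) file pair (`N=0`) for a
#' track added after study start, and records the track in the persisted
#' configuration. The files are populated by a subsequent [add_ids()] call;
#' numbers drawn for the new track are unique across the whole study.
#'
#' @param dir Study directory.
#' @param new_track New track code; must have the same width as the existing
#'   track codes and must not already be in use.
#' @param audit Append an audit-log line.
#' @return Invisibly, the created file names.
#' @export
add_track <- function(dir, new_track, audit = TRUE) {
  state <- load_study(dir)
  if (is.null(state$config)) stop("not an initialized study: ", dir, call. = FALSE)
  config <- state$config
  if (!has_block(config$layout, "T")) {
    stop("layout has no track block; tracks cannot be encoded", call. = FALSE)
  }
  if (!is_code(new_track)) {
    stop("track code must be non-empty alphanumeric", call. = FALSE)
  }
  codes <- vapply(config$tracks, `[[`, character(1), "code")
  if (new_track %in% codes) {
    stop("track '", new_track, "' has already been used in this study",
         call. = FALSE)
  }
  if (length(codes) > 0L && nchar(new_track) != nchar(codes[1])) {
    stop("track codes must share one width ('", codes[1], "' is ",
         nchar(codes[1]), " wide)", call. = FALSE)
  }

  files <- character(0)
  empty <- tibble::tibble(left = character(), right = character())
  for (kind in c("IDP_IDT", "IDS_IDT")) {
    fname <- keypair_filename(config$study_name, kind, new_track, 0)
    files <- c(files, write_pair_with_barcode(dir, fname, empty))
  }
  config$tracks <- c(config$tracks, list(list(code = new_track, n = 0)))
  save_config(config, file.path(dir, CONFIG_FILENAME))
  if (audit) {
    audit_log(dir, "add-track", sprintf("track=%s files=%s", new_track,
                                        paste(files, collapse = ",")))
  }
  invisible(structure(files, dir = dir))
}

#' Generate external identifiers for a data-sharing project
#'
#' For every study-data identifier ID-S, an external identifier ID-E is
#' issued: the project code, a unique random number one digit longer than the
#' study's internal numbers (so external numbers can never collide with or be
#' mistaken for internal ones), and — only if ID-S itself carries a check
#' digit — a check digit under the same algorithm. ID-T plays no role.
#' Each project draws from its own independent pool, so two external partners
#' cannot link their records via ID-E. One (ID-S, ID-E) file per track is
#' written, rows in the order of the current (ID-S, ID-T) file.
#'
#' @param dir Study directory.
#' @param project Project code (alphanumeric); one external batch per project
#'   and study.
#' @param seed Optional seed for the external draws.
#' @param audit Append an audit-log line.
#' @return Invisibly, a tibble with columns `track`, `ids`, `ide`, with
#'   attribute `"files"`.
#' @export
generate_external <- function(dir, project, seed = NULL, audit = TRUE) {
  state <- load_study(dir)
  if (is.null(state$config)) stop("not an initialized study: ", dir, call. = FALSE)
  config <- state$config
  if (!is_code(project)) {
    stop("project code must be non-empty alphanumeric", call. = FALSE)
  }
  if (project %in% state$projects) {
    stop("project '", project, "' already has external IDs in this study",
         call. = FALSE)
  }
  cur <- state$files[!state$files$archived & state$files$kind == "IDS_IDT", ,
                     drop = FALSE]
  if (nrow(cur) == 0L) {
    stop("no current (ID-S, ID-T) files in ", dir,
         "; run create_ids() first", call. = FALSE)
  }

  rng <- rng_source(seed, paste0("external:", project))
  pool <- number_pool(config$k, "E",
                      used = if (!is.null(state$used$E[[project]]))
                        state$used$E[[project]] else numeric(0))
  with_check <- has_block(config$layout, "X")
  render_e <- function(number) {
    body <- paste0(project, format(number, scientific = FALSE))
    if (!with_check) return(body)
    digit <- compute_check(body, config$check_algorithm)
    if (is.na(digit)) return(NULL) # REDRAW
    paste0(body, digit)
  }

  out <- list()
  files <- character(0)
  for (i in seq_len(nrow(cur))) {
    rows <- read_keypairs(file.path(dir, cur$file[i]))
    if (nrow(rows) == 0L) next
    ide <- character(nrow(rows))
    for (j in seq_len(nrow(rows))) {
      repeat {
        candidate <- render_e(draw_unique(pool, 1, rng))
        if (!is.null(candidate)) break
      }
      ide[j] <- candidate
    }
    fname <- keypair_filename(config$study_name, "IDS_IDE", cur$track[i],
                              nrow(rows), project = project)
    files <- c(files, write_pair_with_barcode(
      dir, fname, tibble::tibble(left = rows$left, right = ide)))
    out[[cur$track[i]]] <- tibble::tibble(track = cur$track[i],
                                          ids = rows$left, ide = ide)
  }
  result <- dplyr::bind_rows(out)
  if (audit) {
    audit_log(dir, "external", sprintf("project=%s files=%s", project,
                                       paste(files, collapse = ",")), seed)
  }
  invisible(structure(result, files = files, dir = dir))
}
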