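#' Key-pair file names
#'
#' Key-pair files are the exchange format between a study center and its
#' linkage unit: two tab-separated columns, one ID pair per line, no header.
#' File names encode the pair kind, track, sample size and batch label:
#'
#' * `STUDY_IDP_IDT_T=TRACK_N=SIZE_Baseline.txt` — personal/linkage pairs
#' * `STUDY_IDS_IDT_T=TRACK_N=SIZE_Baseline.txt` — study/linkage pairs
#' * `STUDY_IDS_IDSV_T=TRACK_N=SIZE_V=V.txt` — baseline/new-visit study pairs
#' * `STUDY_IDS_IDE_T=TRACK_N=SIZE_Prj=PROJECT.txt` — study/external pairs
#'
#' Barcode companions carry `_barcode` before the extension; archived batches
#' are renamed from `.txt` to `.old` (then `.old1`, `.old2`, ... on collision).
#'
#' @param study Study name.
#' @param kind One of `"IDP_IDT"`, `"IDS_IDT"`, `"IDS_IDSVISIT"`, `"IDS_IDE"`.
#' @param track Track code (may be empty for the implicit track).
#' @param n Row count encoded in the name.
#' @param visit New-visit code (for `"IDS_IDSVISIT"`).
#' @param project Project code (for `"IDS_IDE"`).
#' @param barcode Name the barcode companion instead of the text file.
#' @return The file name (no directory part).
#' @export
keypair_filename <- function(study, kind, track, n, visit = NULL,
                             project = NULL, barcode = FALSE) {
  kind <- match.arg(kind, c("IDP_IDT", "IDS_IDT", "IDS_IDSVISIT", "IDS_IDE"))
  pair <- switch(kind,
    IDP_IDT = "IDP_IDT",
    IDS_IDT = "IDS_IDT",
    IDS_IDSVISIT = paste0("IDS_IDS", visit),
    IDS_IDE = "IDS_IDE"
  )
  tail <- switch(kind,
    IDP_IDT = ,
    IDS_IDT = "Baseline",
    IDS_IDSVISIT = paste0("V=", visit),
    IDS_IDE = paste0("Prj=", project)
  )
  sprintf("%s_%s_T=%s_N=%s_%s%s.txt", study, pair, track,
          format(n, scientific = FALSE), tail,
          if (barcode) "_barcode" else "")
}

KEYFILE_RE <- paste0(
  "^(.+)_",                                  # study
  "(IDP_IDT|IDS_IDT|IDS_IDE|IDS_IDS(.))_",   # pair kind (+ visit for IDS_IDSV)
  "T=(.*?)_",                                # track (may be empty)
  "N=([0-9]+)_",                             # sample size
  "(Baseline|V=.|Prj=[A-Za-z0-9]+)",         # batch label
  "(_barcode)?",
  "\\.(txt|old[0-9]*)$"
)

#' Parse a key-pair file name into its metadata
#'
#' @param filename File name (no directory part).
#' @return One-row tibble with `file`, `kind`, `track`, `n`, `visit`,
#'   `project`, `barcode`, `archived`, or `NULL` when the name is not a
#'   key-pair file.
#' @keywords internal
parse_keypair_filename <- function(filename) {
  m <- regmatches(filename, regexec(KEYFILE_RE, filename))[[1]]
  if (length(m) == 0L) return(NULL)
  pair <- m[3]
  kind <- if (grepl("^IDS_IDS.$", pair)) "IDS_IDSVISIT" else pair
  tibble::tibble(
    file = filename,
    kind = kind,
    track = m[5],
    n = as.numeric(m[6]),
    visit = if (kind == "IDS_IDSVISIT") m[4] else NA_character_,
    project = if (kind == "IDS_IDE") sub("^Prj=", "", m[7]) else NA_character_,
    barcode = nzchar(m[8]),
    archived = grepl("^old", m[9])
  )
}

#' Read / write a key-pair file
#'
#' Plain ASCII text, two tab-separated columns, no header. Writing is atomic:
#' content goes to a temporary file in the target directory which is renamed
#' into place, so a failed run never leaves a truncated key file.
#'
#' @param pairs Tibble or data frame whose first two columns are the left and
#'   right IDs.
#' @param path File path.
#' @return `write_keypairs()` returns `path` invisibly; `read_keypairs()`
#'   returns a tibble with columns `left`, `right`.
#' @export
write_keypairs <- function(pairs, path) {
  pairs <- tibble::as_tibble(pairs)[, 1:2, drop = FALSE]
  names(pairs) <- c("left", "right")
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  readr::write_tsv(pairs, tmp, col_names = FALSE, progress = FALSE)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary file into place for ", path, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_keypairs
#' @export
read_keypairs <- function(path) {
  if (!file.exists(path)) stop("key-pair file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(tibble::tibble(left = character(), right = character()))
  }
  tbl <- readr::read_tsv(path, col_names = c("left", "right"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) != 2L || anyNA(tbl$left) || anyNA(tbl$right)) {
    stop("corrupt key-pair file (expect two tab-separated columns): ", path,
         call. = FALSE)
  }
  tbl
}

# archive path: file.txt -> file.old, or file.old1, file.old2, ... if taken
archive_name <- function(path) {
  base <- sub("\\.txt$", "", path)
  candidate <- paste0(base, ".old")
  i <- 0L
  while (file.exists(candidate)) {
    i <- i + 1L
    candidate <- paste0(base, ".old", i)
  }
  candidate
}
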