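# shared builders for tiny study fixtures, all generated in code at test time

tiny_config <- function(study = "TINY", layout = "N", k = 3, tracks = 5,
                        ...) {
  study_config(study, layout = layout, k = k, tracks = tracks, ...)
}

# a study directory holding exactly the printed worked-example baseline:
# layout [N][V], k = 3, visit "1", no check digit, pairs
# (4511, 8021), (6511, 9071), (5781, 7281)
worked_example_study <- function(root = NULL) {
  if (is.null(root)) root <- withr::local_tempdir(.local_envir = parent.frame())
  config <- study_config("WORKED", layout = "N,V", k = 3, tracks = 3,
                         visit = "1")
  dir <- file.path(root, "WORKED")
  dir.create(dir)
  save_config(config, file.path(dir, "config.xml"))
  ids_idt <- tibble::tibble(left = c("4511", "6511", "5781"),
                            right = c("8021", "9071", "7281"))
  # ID-P rows consistent with the same ID-T set (visit rendered "0" for ID-P)
  idp_idt <- tibble::tibble(left = c("1230", "2340", "3450"),
                            right = c("8021", "9071", "7281"))
  write_keypairs(idp_idt,
                 file.path(dir, keypair_filename("WORKED", "IDP_IDT", "", 3)))
  write_keypairs(ids_idt,
                 file.path(dir, keypair_filename("WORKED", "IDS_IDT", "", 3)))
  dir
}

# numbers of the left/right columns of a key-pair file, parsed by layout widths
file_numbers <- function(dir, filename, config) {
  rows <- read_keypairs(file.path(dir, filename))
  list(
    left = vapply(lapply(rows$left, parse_id, config = config), `[[`,
                  numeric(1), "number"),
    right = vapply(lapply(rows$right, parse_id, config = config), `[[`,
                   numeric(1), "number")
  )
}
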