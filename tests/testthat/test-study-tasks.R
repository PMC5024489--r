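test_that("create_ids draws triples from disjoint intervals and links them via ID-T", {
  root <- withr::local_tempdir()
  config <- tiny_config("CRT", layout = "N", k = 3, tracks = 3, seed = 5)
  res <- create_ids(config, root = root)

  expect_identical(nrow(res), 3L)
  expect_true(all(res$np >= 100 & res$np < 400))
  expect_true(all(res$ns >= 400 & res$ns < 700))
  expect_true(all(res$nt >= 700 & res$nt < 1000))
  expect_identical(anyDuplicated(c(res$np, res$ns, res$nt)), 0L)

  dir <- attr(res, "dir")
  pt <- file_numbers(dir, keypair_filename("CRT", "IDP_IDT", "", 3), config)
  st <- file_numbers(dir, keypair_filename("CRT", "IDS_IDT", "", 3), config)
  expect_setequal(pt$right, st$right) # the ID-T sets of the two files agree
  # Fig.2-style linkage: joining the two files on ID-T pairs every participant
  pt_rows <- read_keypairs(file.path(dir, keypair_filename("CRT", "IDP_IDT", "", 3)))
  st_rows <- read_keypairs(file.path(dir, keypair_filename("CRT", "IDS_IDT", "", 3)))
  joined <- dplyr::inner_join(pt_rows, st_rows, by = "right",
                              suffix = c("_p", "_s"))
  expect_identical(nrow(joined), 3L)
  expect_identical(anyDuplicated(joined$left_p), 0L)
  expect_identical(anyDuplicated(joined$left_s), 0L)
})

test_that("the study file row order is randomized, the personal file is not", {
  root <- withr::local_tempdir()
  config <- tiny_config("SHUF", layout = "N", k = 4, tracks = 500, seed = 21)
  res <- create_ids(config, root = root)
  dir <- attr(res, "dir")
  pt_rows <- read_keypairs(file.path(dir, keypair_filename("SHUF", "IDP_IDT", "", 500)))
  st_rows <- read_keypairs(file.path(dir, keypair_filename("SHUF", "IDS_IDT", "", 500)))
  expect_identical(pt_rows$left, res$idp)           # creation order kept
  expect_false(identical(st_rows$left, res$ids))    # shuffled
  # sorting the study file by ID-T must not reproduce the personal file order
  expect_false(identical(st_rows$right[order(st_rows$right)], pt_rows$right))
})

test_that("create_ids refuses invalid configs and populated directories", {
  root <- withr::local_tempdir()
  over <- tiny_config("OVR", layout = "N", k = 2, tracks = 30)
  expect_error(create_ids(over, root = root), "capacity")
  expect_false(dir.exists(file.path(root, "OVR"))) # nothing written

  ok <- tiny_config("DUP", layout = "N", k = 3, tracks = 2, seed = 1)
  create_ids(ok, root = root)
  expect_error(create_ids(ok, root = root), "already contains")
})

test_that("add_ids extends a study without collisions and archives prior files", {
  root <- withr::local_tempdir()
  config <- tiny_config("EXT", layout = "N", k = 3, tracks = 10, seed = 2)
  create_ids(config, root = root)
  dir <- file.path(root, "EXT")

  added <- add_ids(dir, 5, seed = 3)
  expect_identical(nrow(added), 5L)
  merged <- read_keypairs(file.path(dir, keypair_filename("EXT", "IDP_IDT", "", 15)))
  expect_identical(nrow(merged), 15L)
  expect_identical(anyDuplicated(merged$left), 0L)
  expect_true(file.exists(file.path(
    dir, sub("\\.txt$", ".old", keypair_filename("EXT", "IDP_IDT", "", 10)))))

  state <- load_study(dir)
  expect_length(state$used$P, 15L)
  expect_identical(anyDuplicated(state$used$P), 0L)
})

test_that("add_ids fails cleanly when the pool is exhausted", {
  root <- withr::local_tempdir()
  config <- tiny_config("FULL", layout = "N", k = 2, tracks = 20, seed = 4)
  create_ids(config, root = root)
  dir <- file.path(root, "FULL")
  add_ids(dir, 10, seed = 5) # fills the 30-number pool completely
  before <- list.files(dir)
  expect_error(add_ids(dir, 1, seed = 6), "capacity exhausted")
  expect_identical(list.files(dir), before) # no files touched
})

test_that("study-wide uniqueness holds across create/add/track batches to exhaustion", {
  root <- withr::local_tempdir()
  config <- study_config("UNIQ", layout = "T,N", k = 3,
                         tracks = c("1" = 60, "2" = 40), seed = 8)
  create_ids(config, root = root)
  dir <- file.path(root, "UNIQ")
  add_track(dir, "3")
  add_ids(dir, c("1" = 50, "3" = 50), seed = 9)
  add_ids(dir, c("2" = 70, "3" = 30), seed = 10) # 300 used: exhausted
  state <- load_study(dir)
  for (layer in c("P", "S", "T")) {
    expect_identical(anyDuplicated(state$used[[layer]]), 0L)
    expect_length(state$used[[layer]], 300L)
  }
  expect_setequal(state$used$P, 100:399) # layer recoverable from the number
  expect_setequal(state$used$S, 400:699)
  expect_setequal(state$used$T, 700:999)
  expect_error(add_ids(dir, c("1" = 1), seed = 11), "capacity exhausted")
})

test_that("add_visit reproduces the worked baseline example exactly", {
  dir <- worked_example_study()
  res <- add_visit(dir, "A")
  expect_identical(res$ids_baseline, c("4511", "6511", "5781"))
  expect_identical(res$ids_new, c("451A", "651A", "578A"))
  fname <- keypair_filename("WORKED", "IDS_IDSVISIT", "", 3, visit = "A")
  expect_identical(fname, "WORKED_IDS_IDSA_T=_N=3_V=A.txt")
  rows <- read_keypairs(file.path(dir, fname))
  expect_identical(rows$left, c("4511", "6511", "5781"))
  expect_identical(rows$right, c("451A", "651A", "578A"))
})

test_that("add_visit rejects reused or invalid visits and layouts without V", {
  dir <- worked_example_study()
  expect_error(add_visit(dir, "1"), "already been used")
  expect_error(add_visit(dir, "i"), "not allowed")
  add_visit(dir, "2")
  expect_error(add_visit(dir, "2"), "already been used")

  root <- withr::local_tempdir()
  config <- tiny_config("NOV", layout = "N", k = 3, tracks = 2, seed = 1)
  create_ids(config, root = root)
  expect_error(add_visit(file.path(root, "NOV"), "2"), "no visit block")
})

test_that("add_visit changes only the visit character and the check digit", {
  root <- withr::local_tempdir()
  config <- study_config("VIS", layout = "N,V,X", k = 3, tracks = 20,
                         visit = "1", check_algorithm = "PARITY", seed = 13)
  create_ids(config, root = root)
  res <- add_visit(file.path(root, "VIS"), "2")
  expect_identical(substr(res$ids_baseline, 1, 3), substr(res$ids_new, 1, 3))
  expect_identical(unique(substr(res$ids_new, 4, 4)), "2")
  # parity shifts by exactly the visit-value change (1 -> 2 shifts by 1)
  old_check <- as.integer(substr(res$ids_baseline, 5, 5))
  new_check <- as.integer(substr(res$ids_new, 5, 5))
  expect_true(all((new_check - old_check) %% 10 == 1))
  # and every new ID still verifies
  reload <- load_config(file.path(root, "VIS", "config.xml"))
  expect_true(all(vapply(res$ids_new, verify_id, logical(1), config = reload)))
})

test_that("add_track creates empty N=0 files and later batches stay disjoint", {
  root <- withr::local_tempdir()
  config <- study_config("TRK", layout = "T,N", k = 3,
                         tracks = c("1" = 5, "2" = 5), seed = 3)
  create_ids(config, root = root)
  dir <- file.path(root, "TRK")
  add_track(dir, "3")
  f <- keypair_filename("TRK", "IDS_IDT", "3", 0)
  expect_identical(f, "TRK_IDS_IDT_T=3_N=0_Baseline.txt")
  expect_identical(nrow(read_keypairs(file.path(dir, f))), 0L)
  expect_error(add_track(dir, "1"), "already been used")
  expect_error(add_track(dir, "33"), "share one width")

  add_ids(dir, c("3" = 5), seed = 4)
  state <- load_study(dir)
  expect_length(state$used$P, 15L)
  expect_identical(anyDuplicated(state$used$P), 0L)
})

test_that("generate_external issues project-prefixed (k+1)-digit unique numbers", {
  root <- withr::local_tempdir()
  config <- tiny_config("EXTP", layout = "N,V", k = 3, tracks = 50,
                        visit = "1", seed = 6)
  create_ids(config, root = root)
  dir <- file.path(root, "EXTP")
  res <- generate_external(dir, "EXT", seed = 7)
  expect_identical(nrow(res), 50L)
  expect_true(all(grepl("^EXT[0-9]{4}$", res$ide))) # 4 random digits for k=3
  parts <- as.numeric(substr(res$ide, 4, 7))
  expect_identical(anyDuplicated(parts), 0L)
  expect_error(generate_external(dir, "EXT", seed = 8), "already has external")
  expect_error(generate_external(dir, "E T", seed = 8), "alphanumeric")
})

test_that("distinct projects draw independent pools", {
  root <- withr::local_tempdir()
  config <- tiny_config("IND", layout = "N", k = 4, tracks = 300, seed = 9)
  create_ids(config, root = root)
  dir <- file.path(root, "IND")
  a <- generate_external(dir, "A1", seed = 10)
  b <- generate_external(dir, "B2", seed = 10)
  ra <- as.numeric(substr(a$ide, 3, 7))
  rb <- as.numeric(substr(b$ide, 3, 7))
  # same ID-S order in both files; the random parts must not track each other
  rho <- suppressWarnings(stats::cor(ra, rb, method = "spearman"))
  expect_lt(abs(rho), 0.2)
})

test_that("external IDs reuse the study's check algorithm when ID-S has one", {
  root <- withr::local_tempdir()
  config <- study_config("EXC", layout = "N,X", k = 3, tracks = 20,
                         check_algorithm = "DAMM_2004", seed = 12)
  create_ids(config, root = root)
  res <- generate_external(file.path(root, "EXC"), "P1", seed = 13)
  expect_true(all(grepl("^P1[0-9]{5}$", res$ide))) # 4 digits + check digit
  for (ide in res$ide) {
    payload <- substr(ide, 1, nchar(ide) - 1)
    check <- as.integer(substr(ide, nchar(ide), nchar(ide)))
    expect_identical(check_damm(payload), check)
  }
})

test_that("load_study round-trips state and catches corruption", {
  root <- withr::local_tempdir()
  config <- tiny_config("LOAD", layout = "N", k = 3, tracks = 10, seed = 14)
  create_ids(config, root = root)
  dir <- file.path(root, "LOAD")
  state <- load_study(dir)
  expect_length(state$used$P, 10L)
  expect_length(state$used$S, 10L)
  expect_length(state$used$T, 10L)

  # a hand-duplicated ID-P row is a consistency error naming the file
  f <- file.path(dir, keypair_filename("LOAD", "IDP_IDT", "", 10))
  rows <- read_keypairs(f)
  rows$left[2] <- rows$left[1]
  write_keypairs(rows, f)
  expect_error(load_study(dir), "duplicated left")

  empty <- withr::local_tempdir()
  state <- load_study(empty)
  expect_null(state$config)
  expect_length(state$used, 0L)
})

test_that("fixture studies are deterministic per seed and differ across seeds", {
  root_a <- withr::local_tempdir()
  root_b <- withr::local_tempdir()
  dir_a <- make_fixture_study("small", seed = 3, root = root_a)
  dir_b <- make_fixture_study("small", seed = 3, root = root_b)
  files <- sort(list.files(dir_a))
  expect_identical(files, sort(list.files(dir_b)))
  for (f in files) {
    expect_identical(readLines(file.path(dir_a, f), warn = FALSE),
                     readLines(file.path(dir_b, f), warn = FALSE),
                     label = f)
  }
  root_c <- withr::local_tempdir()
  dir_c <- make_fixture_study("small", seed = 4, root = root_c)
  expect_false(identical(
    readLines(file.path(dir_a, "SMALL_IDP_IDT_T=_N=10_Baseline.txt")),
    readLines(file.path(dir_c, "SMALL_IDP_IDT_T=_N=10_Baseline.txt"))))

  aug <- make_fixture_study("augur_like", seed = 5, root = withr::local_tempdir())
  state <- load_study(aug)
  expect_length(state$used$P, 140L)
  reload <- state$config
  expect_identical(unclass(reload$layout), c("T", "N", "V", "X"))
  # every emitted ID verifies under the configured Damm scheme
  rows <- read_keypairs(file.path(aug, keypair_filename("AUGURLIKE", "IDS_IDT", "1", 100)))
  expect_true(all(vapply(rows$left, verify_id, logical(1), config = reload)))
})

test_that("Gumm REDRAW keeps every emitted identifier at fixed width", {
  root <- withr::local_tempdir()
  config <- study_config("GUM", layout = "N,X", k = 3, tracks = 40,
                         check_algorithm = "GUMM_1986", seed = 16)
  res <- create_ids(config, root = root)
  expect_true(all(nchar(res$idp) == 4L))
  expect_true(all(nchar(res$ids) == 4L))
  reload <- load_config(file.path(root, "GUM", "config.xml"))
  expect_true(all(vapply(res$idp, verify_id, logical(1), config = reload)))
})
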