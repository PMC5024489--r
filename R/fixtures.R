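#' Generate a small demonstration / test study
#'
#' Builds a fully populated study directory in code, deterministically for a
#' given seed (audit logging is disabled so two runs with one seed are
#' byte-identical). Two profiles:
#'
#' * `"small"`: the minimal study — one implicit track, layout `N` only,
#'   3-digit numbers, 10 participants. Runs in well under a second.
#' * `"augur_like"`: shaped like a three-track elderly-cohort recruitment —
#'   layout `T,N,V,X`, 5-digit numbers, baseline visit "1", Damm check
#'   digits, tracks "1" (registry-based, n = 100), "2" (clinic-based,
#'   n = 20) and "3" (volunteers, n = 20); sample sizes are scaled down
#'   about 100-fold from a realistic recruitment campaign so the fixture
#'   stays fast.
#'
#' @param profile `"small"` or `"augur_like"`.
#' @param seed Seed for all draws.
#' @param root Parent directory for the study directory.
#' @return The study directory path, invisibly, with the generated triples in
#'   attribute `"ids"`.
#' @examples
#' dir <- make_fixture_study("small", seed = 1, root = tempdir())
#' list.files(dir)
#' @export
make_fixture_study <- function(profile = c("small", "augur_like"), seed = 1,
                               root = tempdir()) {
  profile <- match.arg(profile)
  config <- switch(profile,
    small = study_config("SMALL", layout = "N", k = 3, tracks = 10,
                         seed = seed),
    augur_like = study_config("AUGURLIKE", layout = "T,N,V,X", k = 5,
                              tracks = c("1" = 100, "2" = 20, "3" = 20),
                              visit = "1", check_algorithm = "DAMM_2004",
                              seed = seed)
  )
  res <- create_ids(config, root = root, seed = seed, audit = FALSE)
  invisible(structure(attr(res, "dir"), ids = res))
}
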