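#' Persist and recall a study configuration
#'
#' Configurations are stored as a small, versioned XML document so that a
#' study directory is self-describing: every later task (extending batches,
#' new visits, new tracks, external IDs) re-reads the layout, widths and
#' algorithm from the file rather than trusting command-line flags to be
#' retyped consistently. `save_config()` rewrites known elements in place and
#' leaves any unknown elements of an existing file untouched; `load_config()`
#' is its lossless inverse.
#'
#' @param config A [study_config()].
#' @param path File path of the XML configuration.
#' @return `save_config()` returns `path` invisibly; `load_config()` returns
#'   the `study_config`.
#' @examples
#' p <- tempfile(fileext = ".xml")
#' save_config(study_config("DEMO", "N,V", k = 3, tracks = 5), p)
#' load_config(p)
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  doc <- if (file.exists(path)) {
    xml2::read_xml(path)
  } else {
    xml2::read_xml("<cohortid_config version='1'/>")
  }
  root <- xml2::xml_root(doc)

  set_node <- function(name, value) {
    node <- xml2::xml_find_first(root, name)
    if (is.null(value)) {
      if (!inherits(node, "xml_missing")) xml2::xml_remove(node)
      return(invisible())
    }
    if (inherits(node, "xml_missing")) {
      xml2::xml_add_child(root, name)
      node <- xml2::xml_find_first(root, name)
    }
    xml2::xml_text(node) <- as.character(value)
  }

  set_node("study_name", config$study_name)
  set_node("layout", format(config$layout))
  set_node("k", format(config$k, scientific = FALSE))
  set_node("center", config$center)
  set_node("visit", config$visit)
  set_node("check_algorithm", config$check_algorithm)
  set_node("seed", if (is.null(config$seed)) NULL else
    format(config$seed, scientific = FALSE))

  tracks_node <- xml2::xml_find_first(root, "tracks")
  if (!inherits(tracks_node, "xml_missing")) xml2::xml_remove(tracks_node)
  xml2::xml_add_child(root, "tracks")
  tracks_node <- xml2::xml_find_first(root, "tracks")
  for (t in config$tracks) {
    xml2::xml_add_child(tracks_node, "track", code = t$code,
                        n = format(t$n, scientific = FALSE))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed configuration file ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  root <- xml2::xml_root(doc)
  get_text <- function(name) {
    node <- xml2::xml_find_first(root, name)
    if (inherits(node, "xml_missing")) NULL else xml2::xml_text(node)
  }
  get_number <- function(name) {
    txt <- get_text(name)
    if (is.null(txt)) return(NULL)
    val <- suppressWarnings(as.numeric(txt))
    if (is.na(val)) {
      stop("configuration field <", name, "> must be numeric, got '", txt,
           "' (", path, ")", call. = FALSE)
    }
    val
  }

  track_nodes <- xml2::xml_find_all(root, "tracks/track")
  codes <- xml2::xml_attr(track_nodes, "code")
  ns <- suppressWarnings(as.numeric(xml2::xml_attr(track_nodes, "n")))
  if (any(is.na(ns))) {
    stop("track sample sizes must be numeric (", path, ")", call. = FALSE)
  }
  tracks <- stats::setNames(ns, codes)
  if (all(!nzchar(codes))) names(tracks) <- NULL

  k <- get_number("k")
  if (is.null(k)) stop("configuration field <k> is required (", path, ")",
                       call. = FALSE)
  study_config(
    study_name = get_text("study_name"),
    layout = parse_layout(get_text("layout")),
    k = k,
    tracks = tracks,
    center = get_text("center"),
    visit = if (is.null(get_text("visit"))) "1" else get_text("visit"),
    check_algorithm = if (is.null(get_text("check_algorithm"))) "NONE" else
      get_text("check_algorithm"),
    seed = get_number("seed")
  )
}
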