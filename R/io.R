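#' Read a bark-gauge measurement table
#'
#' Reads a delimited text file of per-reading field measurements and validates
#' it, reporting every offending line at once. The delimiter is auto-detected
#' among comma, semicolon and tab; the decimal separator is always `"."` and
#' the file must have a header row.
#'
#' Required columns: `tree_id`, `dob_cm`, `reading_cm`. Optional: `species`,
#' `angle_deg`, `quadrant`, `reading_kind` (`"gauge"` or `"ridge"`). Checks:
#' numeric cells parse, `reading_cm >= 0`, `dob_cm > 0` and constant within
#' each `tree_id`, `angle_deg` in `[0, 360)`.
#'
#' @param path Path to the file.
#' @return A validated tibble, one row per reading.
#' @seealso [write_measurements()], [bark_gauge_summary()]
#' @export
read_measurements <- function(path) {
  raw <- read_delim_auto(path)
  problems <- character()
  line <- seq_len(nrow(raw)) + 1L # header is line 1

  missing_cols <- setdiff(c("tree_id", "dob_cm", "reading_cm"), names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(raw) == 0) {
    rlang::abort("no measurements")
  }

  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]]) & raw[[col]] != ""
    if (any(bad)) {
      problems <<- c(problems, sprintf(
        "line %d: non-numeric %s '%s'", line[bad], col, raw[[col]][bad]
      ))
    }
    v
  }
  dob <- num("dob_cm")
  reading <- num("reading_cm")
  angle <- if ("angle_deg" %in% names(raw)) num("angle_deg") else NA_real_
  quadrant <- if ("quadrant" %in% names(raw)) num("quadrant") else NA_real_

  bad <- !is.na(reading) & reading < 0
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: negative reading_cm %s", line[bad], reading[bad]
    ))
  }
  bad <- !is.na(dob) & dob <= 0
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: non-positive dob_cm %s", line[bad], dob[bad]
    ))
  }
  bad <- !is.na(angle) & (angle < 0 | angle >= 360)
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: angle_deg outside [0, 360)", line[bad]
    ))
  }
  kind <- if ("reading_kind" %in% names(raw)) raw$reading_kind else "gauge"
  bad <- !kind %in% c("gauge", "ridge")
  if (any(bad)) {
    problems <- c(problems, sprintf(
      "line %d: reading_kind must be 'gauge' or 'ridge'", line[bad]
    ))
  }
  for (id in unique(raw$tree_id)) {
    rows <- raw$tree_id == id & !is.na(dob)
    if (!any(rows)) next
    first <- dob[rows][1]
    bad <- rows & dob != first
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "line %d: dob_cm %s inconsistent within tree '%s' (first value %s)",
        line[bad], dob[bad], id, first
      ))
    }
  }
  if (length(problems)) {
    rlang::abort(c("Malformed measurement file:", problems))
  }
  tibble::tibble(
    tree_id = as.character(raw$tree_id),
    species = if ("species" %in% names(raw)) as.character(raw$species) else NA_character_,
    dob_cm = dob,
    reading_cm = reading,
    angle_deg = angle,
    quadrant = quadrant,
    reading_kind = rep_len(kind, nrow(raw))
  )
}

# delimiter auto-detection limited to comma / semicolon / tab
read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path))
  }
  header <- readLines(path, n = 1, warn = FALSE)
  if (!length(header)) rlang::abort("no measurements")
  counts <- c(
    "," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
    ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))),
    "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  )
  delim <- names(counts)[which.max(counts)]
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, progress = FALSE
  )
}

#' Write a measurement table to CSV
#'
#' Plain UTF-8 CSV with header and `"."` decimals; round-trips through
#' [read_measurements()] without loss.
#'
#' @param data Measurement tibble (see [read_measurements()]).
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

#' Read digitized cross-section contours
#'
#' Reads a delimited file of polygon vertices with columns `section_id`,
#' `contour` (`"outer"` or `"wood"`), `vertex_index`, `x_cm`, `y_cm` and
#' returns them ordered by vertex index, ready to split by section and pass to
#' [bfi_dm()].
#'
#' @param path Path to the file.
#' @return Tibble with columns `section_id`, `contour`, `x`, `y`.
#' @export
read_contours <- function(path) {
  raw <- read_delim_auto(path)
  need <- c("section_id", "contour", "vertex_index", "x_cm", "y_cm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  bad <- !raw$contour %in% c("outer", "wood")
  if (any(bad)) {
    rlang::abort(sprintf(
      "line %d: contour must be 'outer' or 'wood'",
      which(bad)[1] + 1L
    ))
  }
  out <- tibble::tibble(
    section_id = as.character(raw$section_id),
    contour = raw$contour,
    vertex_index = as.integer(raw$vertex_index),
    x = as.numeric(raw$x_cm),
    y = as.numeric(raw$y_cm)
  )
  if (any(is.na(out$x)) || any(is.na(out$y)) || any(is.na(out$vertex_index))) {
    rlang::abort("Non-numeric vertex coordinates or indices in contour file.")
  }
  dplyr::arrange(out, .data$section_id, .data$contour, .data$vertex_index)
}

#' Run configuration with defaults
#'
#' Flat key-value configuration shared by the command-line subcommands. Any
#' subset of keys may be supplied; the rest take defaults.
#'
#' @param confidence Confidence level for error formulas, `(0, 1)`.
#' @param bt_max_rule `"smooth_top3"` or `"ridge"`.
#' @param bias_cm Constant gauge bias subtracted from readings, cm.
#' @param clamp Clamp BFI values above 1?
#' @param decimals Decimals for percent columns in outputs.
#' @param seed Integer seed for stochastic subcommands.
#' @param ... Further keys (e.g. `bark_density`, `carbon_fraction`, `mode`,
#'   `volume`) consumed by specific subcommands.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(confidence = 0.95, bt_max_rule = "smooth_top3",
                       bias_cm = 0, clamp = TRUE, decimals = 1,
                       seed = 20210114, ...) {
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    rlang::abort("`confidence` must lie in (0, 1).")
  }
  bt_max_rule <- match.arg(bt_max_rule, c("smooth_top3", "ridge"))
  structure(
    list(
      confidence = confidence, bt_max_rule = bt_max_rule, bias_cm = bias_cm,
      clamp = isTRUE(clamp), decimals = decimals, seed = as.integer(seed), ...
    ),
    class = "run_config"
  )
}

#' Read a run configuration file
#'
#' Reads a flat key-value YAML file and merges it over the defaults of
#' [run_config()]. Unknown keys are kept (subcommand-specific parameters such
#' as `bark_density` travel this way).
#'
#' @param path Path to the YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path))
  }
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) {
    rlang::abort("Config file must be a flat key: value mapping.")
  }
  do.call(run_config, vals)
}
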