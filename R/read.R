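#' Read a fossil occurrence table
#'
#' Reads a delimited text file (comma or tab, auto-detected; header required;
#' UTF-8) of fossil occurrences, one row per occurrence of a genus in a
#' stratigraphic interval at a locality, validates each row against the stage
#' sequence, and returns a tibble. Column names are remapped through
#' `column_map`, so PBDB-style exports can be read by supplying the
#' appropriate mapping.
#'
#' Validation rules: `genus` and `clade` must be non-empty; `interval` must be
#' a member of `stages`; paleocoordinates, when present, must lie in
#' \[-90, 90\] latitude and \[-180, 180\] longitude. In permissive mode
#' (default) invalid rows are dropped and reported via the `"rejects"`
#' attribute (a tibble of line numbers and reasons) plus a message; in strict
#' mode any invalid row is an error.
#'
#' @param path Path to a CSV/TSV file.
#' @param stages A [stage_sequence()].
#' @param column_map Named character vector mapping canonical field names
#'   (`genus`, `clade`, `interval`, `locality`, `paleolat`, `paleolng`) to the
#'   file's column names. Defaults to `genus`, `clade`, `stage`, `locality`,
#'   `paleolat`, `paleolng`.
#' @param strict If `TRUE`, any invalid row aborts the read.
#'
#' @return A tibble with columns `genus`, `clade`, `interval`, `locality` and,
#'   when mapped columns exist, `paleolat`/`paleolng`, in file order, with a
#'   `"rejects"` attribute tibble (`line`, `reason`).
#' @seealso [read_sizes()], [rejects()]
#' @export
read_occurrences <- function(path, stages,
                             column_map = NULL,
                             strict = FALSE) {
  raw <- read_delimited(path)
  cmap <- resolve_column_map(
    column_map,
    defaults = c(genus = "genus", clade = "clade", interval = "stage",
                 locality = "locality", paleolat = "paleolat",
                 paleolng = "paleolng"),
    required = c("genus", "clade", "interval"),
    header = names(raw), path = path
  )

  dat <- tibble(
    genus    = as.character(raw[[cmap[["genus"]]]]),
    clade    = as.character(raw[[cmap[["clade"]]]]),
    interval = as.character(raw[[cmap[["interval"]]]])
  )
  dat$locality <- if (!is.na(cmap["locality"])) {
    as.character(raw[[cmap[["locality"]]]])
  } else NA_character_
  has_coords <- !is.na(cmap["paleolat"]) && !is.na(cmap["paleolng"])
  if (has_coords) {
    dat$paleolat <- suppressWarnings(as.numeric(raw[[cmap[["paleolat"]]]]))
    dat$paleolng <- suppressWarnings(as.numeric(raw[[cmap[["paleolng"]]]]))
  }

  reason <- rep(NA_character_, nrow(dat))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(dat$genus) | dat$genus == "", "empty genus")
  reason <- bad(is.na(dat$clade) | dat$clade == "", "empty clade")
  reason <- bad(!dat$interval %in% stage_names(stages),
                paste0("interval not in stage sequence"))
  if (has_coords) {
    coord_given <- !(is.na(raw[[cmap[["paleolat"]]]]) | raw[[cmap[["paleolat"]]]] == "")
    reason <- bad(coord_given & (is.na(dat$paleolat) | abs(dat$paleolat) > 90),
                  "paleolat outside [-90, 90]")
    reason <- bad(coord_given & (is.na(dat$paleolng) | abs(dat$paleolng) > 180),
                  "paleolng outside [-180, 180]")
  }

  finalize_read(dat, reason, strict, path, what = "occurrence")
}

#' Read a body-size table
#'
#' Reads a delimited text file of taxon body sizes (one row per species per
#' interval, maximum length in mm) with the same delimiter detection,
#' column-mapping and strict/permissive semantics as [read_occurrences()].
#' `max_length` must additionally parse as a strictly positive real.
#'
#' @inheritParams read_occurrences
#' @param column_map Named character vector mapping `species`, `genus`,
#'   `clade`, `interval`, `max_length` to file columns (defaults: `species`,
#'   `genus`, `clade`, `stage`, `max_length_mm`).
#'
#' @return A tibble (`species`, `genus`, `clade`, `interval`, `max_length`)
#'   with a `"rejects"` attribute.
#' @export
read_sizes <- function(path, stages, column_map = NULL, strict = FALSE) {
  raw <- read_delimited(path)
  cmap <- resolve_column_map(
    column_map,
    defaults = c(species = "species", genus = "genus", clade = "clade",
                 interval = "stage", max_length = "max_length_mm"),
    required = c("species", "genus", "clade", "interval", "max_length"),
    header = names(raw), path = path
  )

  dat <- tibble(
    species    = as.character(raw[[cmap[["species"]]]]),
    genus      = as.character(raw[[cmap[["genus"]]]]),
    clade      = as.character(raw[[cmap[["clade"]]]]),
    interval   = as.character(raw[[cmap[["interval"]]]]),
    max_length = suppressWarnings(as.numeric(raw[[cmap[["max_length"]]]]))
  )

  reason <- rep(NA_character_, nrow(dat))
  bad <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- bad(is.na(dat$species) | dat$species == "", "empty species")
  reason <- bad(is.na(dat$genus) | dat$genus == "", "empty genus")
  reason <- bad(is.na(dat$clade) | dat$clade == "", "empty clade")
  reason <- bad(!dat$interval %in% stage_names(stages),
                "interval not in stage sequence")
  reason <- bad(is.na(dat$max_length) | dat$max_length <= 0,
                "max_length not a positive number")

  finalize_read(dat, reason, strict, path, what = "size")
}

#' Reject report of a permissive read
#'
#' @param x A tibble returned by [read_occurrences()] or [read_sizes()].
#' @return A tibble with columns `line` (1-based data line number, excluding
#'   the header) and `reason`; zero rows if nothing was rejected.
#' @export
rejects <- function(x) {
  attr(x, "rejects") %||% tibble(line = integer(), reason = character())
}

#' Write occurrence or size tables
#'
#' Writes a validated table back to CSV so that a write/read round trip is the
#' identity on the validated columns.
#'
#' @param x A tibble of occurrences or sizes.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  out <- x
  if ("interval" %in% names(out)) {
    out <- rename(out, stage = "interval")
  }
  if ("max_length" %in% names(out)) {
    out <- rename(out, max_length_mm = "max_length")
  }
  readr::write_csv(out, path)
  invisible(path)
}

# -- internals ---------------------------------------------------------------

read_delimited <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (length(first) == 0L) abort(sprintf("File is empty: %s", path))
  delim <- if (stringr::str_count(first, "\t") >
               stringr::str_count(first, ",")) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE)
}

resolve_column_map <- function(column_map, defaults, required, header, path) {
  cmap <- defaults
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(defaults))
    if (length(unknown)) {
      abort(sprintf("Unknown column_map fields: %s", paste(unknown, collapse = ", ")))
    }
    cmap[names(column_map)] <- column_map
  }
  missing_req <- required[!cmap[required] %in% header]
  if (length(missing_req)) {
    abort(sprintf(
      "Missing required column(s) in %s: %s (mapped as %s)",
      path, paste(cmap[missing_req], collapse = ", "),
      paste(missing_req, collapse = ", ")
    ))
  }
  # optional columns absent from the header are dropped from the map
  cmap[!cmap %in% header] <- NA_character_
  cmap
}

finalize_read <- function(dat, reason, strict, path, what) {
  rej <- which(!is.na(reason))
  if (length(rej) && strict) {
    abort(sprintf(
      "%d invalid %s row(s) in %s (strict mode); first: line %d (%s)",
      length(rej), what, path, rej[1], reason[rej[1]]
    ))
  }
  reject_report <- tibble(line = rej, reason = reason[rej])
  if (length(rej)) {
    inform(sprintf("Rejected %d of %d %s row(s) from %s; see rejects().",
                   length(rej), nrow(dat), what, basename(path)))
  }
  out <- dat[is.na(reason), , drop = FALSE]
  attr(out, "rejects") <- reject_report
  out
}
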