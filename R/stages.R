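#' Ordered stage sequence with an extinction boundary
#'
#' A `stage_sequence` is an ordered vector of stratigraphic interval names
#' (oldest to youngest) together with the position of the focal extinction
#' boundary. The boundary lies *between* interval `boundary` and interval
#' `boundary + 1`, so for the minimal Permian-Triassic case
#' `stage_sequence(c("Changhsingian", "Induan"), boundary = 1)` places the
#' boundary between the two stages.
#'
#' At least two intervals are required; the sampling-standardized rate
#' estimators (three-timer, gap-filler) need four or more.
#'
#' @param names Character vector of unique interval names, oldest first.
#' @param boundary Integer index of the last pre-boundary interval, or the
#'   name of that interval. Must satisfy `1 <= boundary < length(names)`.
#'
#' @return An object of class `stage_sequence`.
#' @examples
#' stages <- stage_sequence(c("Changhsingian", "Induan"), boundary = "Changhsingian")
#' boundary_index(stages)
#' @export
stage_sequence <- function(names, boundary = 1L) {
  if (!is.character(names) || length(names) < 2L) {
    abort("`names` must be a character vector of at least 2 interval names.")
  }
  if (anyDuplicated(names)) {
    abort("Interval names must be unique.")
  }
  if (is.character(boundary)) {
    idx <- match(boundary, names)
    if (is.na(idx)) abort(sprintf("Boundary interval '%s' not in sequence.", boundary))
    boundary <- idx
  }
  boundary <- as.integer(boundary)
  if (is.na(boundary) || boundary < 1L || boundary >= length(names)) {
    abort("`boundary` must satisfy 1 <= boundary < length(names).")
  }
  structure(names, boundary = boundary, class = "stage_sequence")
}

#' @rdname stage_sequence
#' @param x A `stage_sequence`.
#' @export
boundary_index <- function(x) {
  stopifnot(inherits(x, "stage_sequence"))
  attr(x, "boundary")
}

#' @rdname stage_sequence
#' @export
stage_names <- function(x) {
  stopifnot(inherits(x, "stage_sequence"))
  as.character(unclass(x))
}

#' @export
print.stage_sequence <- function(x, ...) {
  nm <- stage_names(x)
  b <- boundary_index(x)
  marked <- c(nm[seq_len(b)], "| <boundary> |", nm[(b + 1L):length(nm)])
  cat("<stage_sequence> ", paste(marked, collapse = " -> "), "\n")
  invisible(x)
}

# index of an interval name within a stage sequence (NA if absent)
stage_index <- function(interval, stages) {
  match(interval, stage_names(stages))
}
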