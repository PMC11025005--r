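#' Summarize occurrences per genus and score boundary survival
#'
#' Collapses an occurrence table to one row per genus: clade, set of intervals
#' present, occurrence and locality counts, and extinction status at the focal
#' boundary.
#'
#' `extinct_at_boundary` is `TRUE` when the genus occurs in an interval at or
#' before the boundary and in none after it, `FALSE` when it occurs on both
#' sides, and `NA` (excluded from extinction tallies) when it first occurs
#' after the boundary.
#'
#' `in_cohort` marks the genera forming the denominator of boundary extinction
#' proportions. With `cohort = "boundary_interval"` (default) a genus is in
#' the cohort iff it is sampled in the boundary interval itself — the cohort
#' of last-pre-boundary-stage genera. With `cohort = "range_through"` a genus
#' is in the cohort iff its sampled range spans the boundary interval
#' (first appearance at or before it, last appearance at or after it), the
#' standard range-through alternative.
#'
#' @param occurrences Tibble from [read_occurrences()] (or equivalent) with
#'   columns `genus`, `clade`, `interval`, and optionally `locality`.
#' @param stages A [stage_sequence()].
#' @param cohort Cohort rule, `"boundary_interval"` or `"range_through"`.
#'
#' @return A tibble with one row per genus: `genus`, `clade`,
#'   `intervals_present` (list column of interval names), `first_index`,
#'   `last_index`, `n_occurrences`, `n_localities`, `extinct_at_boundary`,
#'   `in_cohort`.
#' @examples
#' stages <- stage_sequence(c("Changhsingian", "Induan"), boundary = 1)
#' occ <- tibble::tibble(
#'   genus = c("A", "B", "B", "C"), clade = "brachiopod",
#'   interval = c("Changhsingian", "Changhsingian", "Induan", "Induan"),
#'   locality = "L1"
#' )
#' build_genus_summaries(occ, stages)
#' @export
build_genus_summaries <- function(occurrences, stages,
                                  cohort = c("boundary_interval", "range_through")) {
  cohort <- match.arg(cohort)
  if (nrow(occurrences) == 0L) abort("Occurrence table is empty.")
  multi <- occurrences |>
    distinct(.data$genus, .data$clade) |>
    count(.data$genus) |>
    filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(sprintf("Genera assigned to more than one clade: %s",
                  paste(multi$genus, collapse = ", ")))
  }
  b <- boundary_index(stages)

  occurrences |>
    mutate(.idx = stage_index(.data$interval, stages)) |>
    group_by(.data$genus, .data$clade) |>
    summarise(
      intervals_present = list(sort(unique(.data$interval[order(.data$.idx)]))),
      first_index = min(.data$.idx),
      last_index = max(.data$.idx),
      n_occurrences = dplyr::n(),
      n_localities = n_distinct(.data$locality[!is.na(.data$locality)]),
      .in_boundary = any(.data$.idx == b),
      .groups = "drop"
    ) |>
    mutate(
      extinct_at_boundary = case_when(
        .data$first_index > b ~ NA,
        .data$last_index > b ~ FALSE,
        TRUE ~ TRUE
      ),
      in_cohort = if (cohort == "boundary_interval") {
        .data$.in_boundary
      } else {
        .data$first_index <= b & (.data$last_index >= b)
      }
    ) |>
    select(-".in_boundary") |>
    arrange(.data$genus)
}

#' Geographic range of a genus
#'
#' Computes a geographic-range measure from the occurrence records of one or
#' more genera. Two methods are available: `"n_localities"` counts distinct
#' locality identifiers (works without coordinates; a single locality gives
#' 1), and `"max_gcd"` returns the maximum great-circle distance in km over
#' all pairs of occurrence coordinates on a spherical Earth of radius 6371 km
#' (a single point gives 0).
#'
#' @param occurrences Occurrence tibble (any number of genera).
#' @param method `"n_localities"` (default) or `"max_gcd"`.
#' @return A tibble `genus`, `geo_range`.
#' @export
compute_geographic_range <- function(occurrences,
                                     method = c("n_localities", "max_gcd")) {
  method <- match.arg(method)
  if (nrow(occurrences) == 0L) abort("No occurrence records supplied.")
  if (method == "n_localities") {
    occurrences |>
      group_by(.data$genus) |>
      summarise(geo_range = n_distinct(.data$locality[!is.na(.data$locality)]),
                .groups = "drop")
  } else {
    if (!all(c("paleolat", "paleolng") %in% names(occurrences))) {
      abort("max_gcd requires paleolat/paleolng columns.")
    }
    occurrences |>
      group_by(.data$genus) |>
      summarise(geo_range = max_gcd_km(.data$paleolng, .data$paleolat),
                .groups = "drop")
  }
}

# maximum pairwise great-circle distance (km), spherical Earth R = 6371 km
max_gcd_km <- function(lng, lat) {
  ok <- !is.na(lng) & !is.na(lat)
  pts <- unique(cbind(lng[ok], lat[ok]))
  if (nrow(pts) == 0L) abort("max_gcd requested but no coordinates present.")
  if (nrow(pts) == 1L) return(0)
  d <- geosphere::distm(pts, fun = geosphere::distHaversine) / 6378137 * 6371
  max(d)
}
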