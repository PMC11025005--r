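#' Default clade-to-trait table
#'
#' Ships the clade-level physiological covariates used throughout the package:
#' respiratory-protein group, ordinal O2-carrying capacity, circulatory
#' system, skeletal mineralogy, motility and physiological buffering.
#'
#' The respiratory-protein classification follows the standard reading of
#' modern reference physiology, bracketed onto extinct members of each clade:
#' the diffusion group (no carrier protein) holds protozoans (foraminifera,
#' radiolarians), sponges and corals; hemerythrin holds brachiopods and
#' bryozoans; hemocyanin holds ostracods, gastropods, cephalopods and
#' protobranch bivalves; hemoglobin holds non-protobranch bivalves,
#' echinoderms, conodonts and fish. Cephalopods carry a closed circulatory
#' system; the other shelled invertebrates are open; the diffusion group has
#' none. O2 capacity defaults to the ordinal ranks of [capacity_values()].
#'
#' Motility and buffering are coded at clade level following the usual
#' physiological-buffering scheme for Permian-Triassic selectivity work
#' (heavily calcified, low-metabolism taxa unbuffered; motile taxa with
#' active gas exchange buffered). The table is plain data: edit it, or supply
#' your own CSV with the same columns, to change any coding.
#'
#' @return A tibble with columns `clade`, `protein_group`, `o2_capacity`,
#'   `circulatory`, `mineralogy`, `motility`, `buffered`.
#' @seealso [assign_traits()], [capacity_values()], [read_trait_table()]
#' @export
default_trait_table <- function() {
  tbl <- tibble::tribble(
    ~clade,                    ~protein_group, ~circulatory, ~mineralogy,     ~motility,    ~buffered,
    "foraminifera",            "diffusion",    "none",       "carbonate",     "non_motile", "unbuffered",
    "radiolarian",             "diffusion",    "none",       "siliceous",     "non_motile", "unbuffered",
    "sponge",                  "diffusion",    "none",       "carbonate",     "non_motile", "unbuffered",
    "coral",                   "diffusion",    "none",       "carbonate",     "non_motile", "unbuffered",
    "brachiopod",              "hemerythrin",  "open",       "carbonate",     "non_motile", "unbuffered",
    "bryozoan",                "hemerythrin",  "open",       "carbonate",     "non_motile", "unbuffered",
    "ostracod",                "hemocyanin",   "open",       "carbonate",     "motile",     "buffered",
    "gastropod",               "hemocyanin",   "open",       "carbonate",     "motile",     "buffered",
    "cephalopod",              "hemocyanin",   "closed",     "carbonate",     "motile",     "buffered",
    "bivalve_protobranch",     "hemocyanin",   "open",       "carbonate",     "motile",     "buffered",
    "bivalve_non_protobranch", "hemoglobin",   "open",       "carbonate",     "motile",     "buffered",
    "echinoderm",              "hemoglobin",   "open",       "carbonate",     "motile",     "unbuffered",
    "conodont",                "hemoglobin",   "closed",     "phosphatic",    "motile",     "buffered",
    "fish",                    "hemoglobin",   "closed",     "phosphatic",    "motile",     "buffered"
  )
  caps <- capacity_values("ordinal")
  tbl |>
    mutate(o2_capacity = unname(caps[.data$protein_group])) |>
    select("clade", "protein_group", "o2_capacity", "circulatory",
           "mineralogy", "motility", "buffered")
}

#' Numeric O2-carrying capacity per respiratory-protein group
#'
#' The four protein groups have a fixed capacity ranking:
#' diffusion < hemerythrin < hemocyanin < hemoglobin. The default `"ordinal"`
#' mode encodes that ranking as 0, 1, 2, 3. `"custom"` mode accepts a
#' user-supplied quantitative mapping (for example, one derived from protein
#' concentrations and Hill coefficients) but rejects any mapping that breaks
#' the ranking.
#'
#' @param mode `"ordinal"` or `"custom"`.
#' @param custom Named numeric vector over all four groups (custom mode only).
#' @return Named numeric vector `diffusion`, `hemerythrin`, `hemocyanin`,
#'   `hemoglobin`.
#' @examples
#' capacity_values()
#' capacity_values("custom", c(diffusion = 0, hemerythrin = 0.5,
#'                             hemocyanin = 5, hemoglobin = 10))
#' @export
capacity_values <- function(mode = c("ordinal", "custom"), custom = NULL) {
  mode <- match.arg(mode)
  groups <- protein_groups()
  if (mode == "ordinal") {
    return(setNames(as.numeric(0:3), groups))
  }
  if (is.null(custom) || !all(groups %in% names(custom))) {
    abort("Custom capacities must name all four protein groups.")
  }
  vals <- as.numeric(custom[groups])
  if (any(diff(vals) <= 0)) {
    abort(paste("Custom capacities must be strictly increasing over",
                "diffusion < hemerythrin < hemocyanin < hemoglobin."))
  }
  setNames(vals, groups)
}

#' @rdname capacity_values
#' @export
protein_groups <- function() {
  c("diffusion", "hemerythrin", "hemocyanin", "hemoglobin")
}

#' Annotate genus summaries with clade-level traits
#'
#' Joins each genus summary to its clade's trait assignment. Unknown clades
#' are a hard error in strict mode; in permissive mode they are dropped with a
#' message and counted in the `"n_dropped"` attribute.
#'
#' @param summaries Tibble from [build_genus_summaries()].
#' @param table Trait table (default [default_trait_table()]).
#' @param strict Error on unmapped clades?
#' @return The summaries with trait columns appended.
#' @export
assign_traits <- function(summaries, table = default_trait_table(),
                          strict = FALSE) {
  validate_trait_table(table)
  unknown <- setdiff(unique(summaries$clade), table$clade)
  if (length(unknown)) {
    if (strict) {
      abort(sprintf("Clades missing from trait table: %s",
                    paste(unknown, collapse = ", ")))
    }
    n_drop <- sum(summaries$clade %in% unknown)
    inform(sprintf("Dropping %d genus/genera from unmapped clade(s): %s",
                   n_drop, paste(unknown, collapse = ", ")))
  } else {
    n_drop <- 0L
  }
  out <- summaries |>
    inner_join(table, by = "clade")
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read a trait table from CSV
#'
#' @param path CSV with columns `clade`, `protein_group`, `o2_capacity`,
#'   `circulatory`, `mineralogy`, `motility`, `buffered`.
#' @return A validated trait tibble.
#' @export
read_trait_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tbl$o2_capacity <- as.numeric(tbl$o2_capacity)
  validate_trait_table(tbl)
  as_tibble(tbl)
}

validate_trait_table <- function(table) {
  need <- c("clade", "protein_group", "o2_capacity", "circulatory",
            "mineralogy", "motility", "buffered")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    abort(sprintf("Trait table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(table$clade)) abort("Trait table has duplicated clades.")
  bad_group <- setdiff(unique(table$protein_group), protein_groups())
  if (length(bad_group)) {
    abort(sprintf("Unknown protein group(s): %s", paste(bad_group, collapse = ", ")))
  }
  no_circ <- table$protein_group == "diffusion" & table$circulatory != "none"
  if (any(no_circ)) {
    abort("Diffusion-group clades cannot have a circulatory system.")
  }
  invisible(table)
}
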