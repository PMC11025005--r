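#' Configuration for the synthetic fossil-data generator
#'
#' Bundles everything the generator needs: the stage sequence, per-clade genus
#' counts, per-protein-group boundary extinction probabilities, background
#' per-boundary turnover, per-interval sampling probability, the locality
#' pool, and the log-normal size model with per-group post-boundary median
#' multipliers.
#'
#' @param stages A [stage_sequence()] (default: six Permian-Triassic stages
#'   with the focal boundary after the Changhsingian).
#' @param clades Tibble with columns `clade`, `n_genera`; clades must appear
#'   in `trait_table`.
#' @param trait_table Trait table mapping clades to protein groups.
#' @param group_extinction Named numeric vector of boundary extinction
#'   probabilities per protein group (all in \[0, 1\]).
#' @param sampling_prob Per-(genus, interval) Bernoulli sampling probability
#'   `r` in (0, 1].
#' @param bg_extinction Probability that a living genus dies at any non-focal
#'   interval boundary (background turnover).
#' @param post_origin_frac Fraction of genera originating after the boundary
#'   (these have undefined extinction status, exercising cohort exclusion).
#' @param n_localities Size of the shared locality pool (localities carry
#'   paleocoordinates).
#' @param sizes Tibble with columns `clade`, `n_species_pre`, `n_species_post`,
#'   `meanlog`, `sdlog` for the log-normal size model, or `NULL` to derive a
#'   default from `clades`.
#' @param group_size_multiplier Named numeric vector: post-boundary median
#'   size multiplier `m` per protein group (0.5 = 50% median reduction).
#' @param seed Integer master seed; all generator randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_occurrences()], [generate_sizes()], [scenario_study_scale()]
#' @export
sim_config <- function(stages = stage_sequence(
                         c("Wordian", "Capitanian", "Wuchiapingian",
                           "Changhsingian", "Induan", "Olenekian"),
                         boundary = "Changhsingian"),
                       clades = tibble(clade = c("brachiopod", "gastropod"),
                                       n_genera = c(50L, 50L)),
                       trait_table = default_trait_table(),
                       group_extinction = c(diffusion = 0.9,
                                            hemerythrin = 0.85,
                                            hemocyanin = 0.75,
                                            hemoglobin = 0.6),
                       sampling_prob = 0.8,
                       bg_extinction = 0.1,
                       post_origin_frac = 0.08,
                       n_localities = 120L,
                       sizes = NULL,
                       group_size_multiplier = c(diffusion = 0.5,
                                                 hemerythrin = 0.6,
                                                 hemocyanin = 0.9,
                                                 hemoglobin = 1.0),
                       seed = 1L) {
  stopifnot(inherits(stages, "stage_sequence"))
  validate_trait_table(trait_table)
  if (!all(clades$clade %in% trait_table$clade)) {
    abort("Every simulated clade must appear in the trait table.")
  }
  if (any(clades$n_genera < 1L)) abort("Genus counts must be >= 1.")
  groups <- protein_groups()
  if (!all(groups %in% names(group_extinction)) ||
      any(group_extinction < 0 | group_extinction > 1)) {
    abort("group_extinction must cover all four groups with probabilities in [0, 1].")
  }
  if (sampling_prob <= 0 || sampling_prob > 1) abort("sampling_prob must lie in (0, 1].")
  if (bg_extinction < 0 || bg_extinction >= 1) abort("bg_extinction must lie in [0, 1).")
  if (is.null(sizes)) {
    sizes <- tibble(clade = clades$clade,
                    n_species_pre = pmax(2L, clades$n_genera),
                    n_species_post = pmax(2L, clades$n_genera),
                    meanlog = log(10), sdlog = 0.5)
  }
  if (!all(groups %in% names(group_size_multiplier))) {
    abort("group_size_multiplier must cover all four protein groups.")
  }
  structure(list(
    stages = stages, clades = clades, trait_table = trait_table,
    group_extinction = group_extinction[groups],
    sampling_prob = sampling_prob, bg_extinction = bg_extinction,
    post_origin_frac = post_origin_frac, n_localities = as.integer(n_localities),
    sizes = sizes, group_size_multiplier = group_size_multiplier[groups],
    seed = as.integer(seed)
  ), class = "sim_config")
}

# deterministic sub-seed per generator phase, kept below 2^31
derive_seed <- function(seed, phase) {
  as.integer((as.numeric(seed) * 48271 + phase * 16807) %% 2147483647L)
}

#' Generate a synthetic occurrence dataset with known ground truth
#'
#' Simulates genus ranges and incomplete sampling. Each genus gets a true
#' stratigraphic range: an origin interval (uniform over pre-boundary
#' intervals, or post-boundary for a `post_origin_frac` fraction), survival
#' across each background interval boundary with probability
#' `1 - bg_extinction`, and survival across the focal boundary with
#' probability `1 - pi_g` where `pi_g` is its protein group's extinction
#' probability. True presences are then thinned by the per-interval sampling
#' probability `r`; sampled presences receive 1-3 localities from a shared
#' coordinate-bearing pool. The sampling uniforms are drawn on the full true
#' presence grid before thinning, so lowering `r` under the same seed can only
#' remove occurrences, never add them.
#'
#' @param config A [sim_config()].
#' @return A list with `occurrences` (tibble in the [read_occurrences()]
#'   layout) and `truth` (one row per genus: `genus`, `clade`,
#'   `protein_group`, `origin_index`, `last_index`, `alive_at_boundary`,
#'   `true_extinct_at_boundary`).
#' @export
generate_occurrences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stages <- config$stages
  nm <- stage_names(stages)
  n_int <- length(nm)
  b <- boundary_index(stages)
  traits <- config$trait_table

  genera <- config$clades |>
    inner_join(select(traits, "clade", "protein_group"), by = "clade") |>
    purrr::pmap_dfr(function(clade, n_genera, protein_group, ...) {
      tibble(genus = sprintf("%s_g%03d", clade, seq_len(n_genera)),
             clade = clade, protein_group = protein_group)
    })
  n_gen <- nrow(genera)
  pi_g <- unname(config$group_extinction[genera$protein_group])

  # phase 1: true ranges
  truth <- withr::with_seed(derive_seed(config$seed, 1L), {
    post_origin <- runif(n_gen) < config$post_origin_frac
    origin <- ifelse(post_origin,
                     sample_int_vec(n_gen, (b + 1L):n_int),
                     sample_int_vec(n_gen, 1L:b))
    death_u <- matrix(runif(n_gen * (n_int - 1L)), nrow = n_gen)
    last <- vapply(seq_len(n_gen), function(g) {
      j <- origin[g]
      while (j < n_int) {
        p_die <- if (j == b) pi_g[g] else config$bg_extinction
        if (death_u[g, j] < p_die) return(j)
        j <- j + 1L
      }
      n_int
    }, integer(1))
    tibble(
      genus = genera$genus, clade = genera$clade,
      protein_group = genera$protein_group,
      origin_index = as.integer(origin), last_index = last,
      alive_at_boundary = origin <= b & last >= b,
      true_extinct_at_boundary = ifelse(origin <= b & last >= b, last == b, NA)
    )
  })

  true_pres <- tidyr::crossing(g = seq_len(n_gen), i = seq_len(n_int)) |>
    filter(.data$i >= truth$origin_index[.data$g],
           .data$i <= truth$last_index[.data$g])

  # phase 2: sampling uniforms on the full true presence grid (r-independent)
  sample_u <- withr::with_seed(derive_seed(config$seed, 2L),
                               runif(nrow(true_pres)))

  # phase 3: locality pool and per-presence locality structure (r-independent)
  loc <- withr::with_seed(derive_seed(config$seed, 3L), {
    pool <- tibble(
      locality = sprintf("L%04d", seq_len(config$n_localities)),
      paleolat = runif(config$n_localities, -60, 60),
      paleolng = runif(config$n_localities, -180, 180)
    )
    k <- 1L + findInterval(runif(nrow(true_pres)), c(0.5, 0.85))
    ids <- matrix(sample.int(config$n_localities, nrow(true_pres) * 3L,
                             replace = TRUE), ncol = 3L)
    list(pool = pool, k = k, ids = ids)
  })

  keep <- sample_u < config$sampling_prob
  if (!any(keep)) {
    abort("No genus was sampled under this configuration; raise sampling_prob.")
  }
  rows <- true_pres[keep, , drop = FALSE]
  k <- loc$k[keep]
  ids <- loc$ids[keep, , drop = FALSE]
  loc_list <- lapply(seq_along(k), function(r) unique(ids[r, seq_len(k[r])]))
  len <- lengths(loc_list)
  occ <- tibble(
    g = rep(rows$g, len),
    i = rep(rows$i, len),
    loc_id = unlist(loc_list)
  )
  occ <- tibble(
    genus = genera$genus[occ$g],
    clade = genera$clade[occ$g],
    interval = nm[occ$i],
    locality = loc$pool$locality[occ$loc_id],
    paleolat = loc$pool$paleolat[occ$loc_id],
    paleolng = loc$pool$paleolng[occ$loc_id]
  )
  list(occurrences = occ, truth = truth)
}

# vectorized sample-from-set with independent draws per element
sample_int_vec <- function(n, set) {
  if (length(set) == 1L) rep(set, n) else set[sample.int(length(set), n, replace = TRUE)]
}

#' Generate a synthetic body-size dataset with known ground truth
#'
#' Draws species maximum lengths log-normally per clade: the pre-boundary
#' cohort from `lognormal(meanlog, sdlog)` and the post-boundary cohort from
#' `lognormal(meanlog + log(m), sdlog)` where `m` is the clade's protein
#' group's median multiplier, so the true expected median reduction is
#' `(1 - m) * 100` percent. Species are grouped into genera of 1-4 species.
#' Pre-boundary species are recorded in the boundary interval, post-boundary
#' species in the following interval.
#'
#' @param config A [sim_config()].
#' @return A list with `sizes` (tibble in the [read_sizes()] layout) and
#'   `truth` (per clade: realized cohort medians, true multiplier).
#' @export
generate_sizes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stages <- config$stages
  nm <- stage_names(stages)
  b <- boundary_index(stages)
  traits <- config$trait_table

  spec <- config$sizes |>
    inner_join(select(traits, "clade", "protein_group"), by = "clade") |>
    mutate(multiplier = unname(config$group_size_multiplier[.data$protein_group]))

  withr::with_seed(derive_seed(config$seed, 4L), {
    res <- purrr::pmap(spec, function(clade, n_species_pre, n_species_post,
                                      meanlog, sdlog, protein_group, multiplier) {
      draw <- function(n, cohort, mu) {
        tibble(
          species = sprintf("%s_%s_sp%04d", clade, cohort, seq_len(n)),
          genus = sprintf("%s_%s_gen%03d", clade, cohort,
                          cumsum(c(1L, runif(n - 1L) < 0.4))),
          clade = clade,
          interval = if (cohort == "pre") nm[b] else nm[b + 1L],
          max_length = rlnorm(n, meanlog = mu, sdlog = sdlog)
        )
      }
      pre <- draw(n_species_pre, "pre", meanlog)
      post <- draw(n_species_post, "post", meanlog + log(multiplier))
      list(
        sizes = bind_rows(pre, post),
        truth = tibble(
          clade = clade, protein_group = protein_group,
          multiplier = multiplier,
          true_reduction_pct = (1 - multiplier) * 100,
          realized_median_pre = median(pre$max_length),
          realized_median_post = median(post$max_length),
          n_pre = n_species_pre, n_post = n_species_post
        )
      )
    })
    list(sizes = purrr::map_dfr(res, "sizes"),
         truth = purrr::map_dfr(res, "truth"))
  })
}

#' Study-scale synthetic scenario
#'
#' A ready-made [sim_config()] emulating the scale of the Permian-Triassic
#' study system: 13 marine clades totalling about 1,100 genera across the four
#' respiratory-protein groups, and a body-size table of about 1,495 species in
#' eight common clades. The boundary extinction probabilities are ordered
#' diffusion > hemerythrin > hemocyanin > hemoglobin, which produces a
#' negative capacity-extinction slope; the probabilities and size multipliers
#' are illustrative ground truths for validation, not estimates from the
#' fossil record.
#'
#' @param seed Master seed.
#' @return A `sim_config`.
#' @export
scenario_study_scale <- function(seed = 1L) {
  clades <- tibble::tribble(
    ~clade,                    ~n_genera,
    "foraminifera",            150L,
    "radiolarian",             55L,
    "sponge",                  60L,
    "coral",                   80L,
    "brachiopod",              200L,
    "bryozoan",                60L,
    "ostracod",                80L,
    "gastropod",               120L,
    "cephalopod",              70L,
    "bivalve_protobranch",     20L,
    "bivalve_non_protobranch", 130L,
    "conodont",                35L,
    "fish",                    45L
  )
  sizes <- tibble::tribble(
    ~clade,                    ~n_species_pre, ~n_species_post, ~meanlog, ~sdlog,
    "foraminifera",            180L,           90L,             log(1.5), 0.6,
    "brachiopod",              200L,           80L,             log(25),  0.5,
    "ostracod",                90L,            70L,             log(1.2), 0.4,
    "gastropod",               120L,           100L,            log(20),  0.6,
    "cephalopod",              80L,            70L,             log(60),  0.5,
    "bivalve_non_protobranch", 120L,           110L,            log(30),  0.5,
    "conodont",                40L,            35L,             log(1.0), 0.4,
    "fish",                    60L,            50L,             log(150), 0.6
  )
  sim_config(
    clades = clades,
    group_extinction = c(diffusion = 0.93, hemerythrin = 0.90,
                         hemocyanin = 0.80, hemoglobin = 0.65),
    sampling_prob = 0.8,
    bg_extinction = 0.1,
    post_origin_frac = 0.08,
    sizes = sizes,
    group_size_multiplier = c(diffusion = 0.5, hemerythrin = 0.55,
                              hemocyanin = 0.9, hemoglobin = 0.97),
    seed = seed
  )
}
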