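#' Median body-size reduction across the boundary
#'
#' Percentage reduction of the median maximum length from the pre-boundary to
#' the post-boundary cohort, computed on the raw mm scale (midpoint rule for
#' even sample sizes): `(1 - median(post) / median(pre)) * 100`. Negative
#' values indicate a size increase.
#'
#' @param pre,post Numeric vectors of maximum lengths (mm), all positive.
#' @return Reduction in percent (at most 100).
#' @examples
#' median_size_reduction(c(3, 1, 4, 1, 5), c(2, 7, 1)) # (1 - 2/3) * 100
#' @export
median_size_reduction <- function(pre, post) {
  check_sizes(pre, "pre")
  check_sizes(post, "post")
  (1 - median(post) / median(pre)) * 100
}

check_sizes <- function(x, label) {
  if (length(x) == 0L) abort(sprintf("Empty %s-boundary size sample.", label))
  if (any(is.na(x)) || any(x <= 0)) {
    abort(sprintf("All %s-boundary sizes must be positive numbers.", label))
  }
}

#' Bootstrap standard deviation of the median size reduction
#'
#' Resamples the pre- and post-boundary cohorts independently with
#' replacement at their own sizes (the cohorts are distinct faunas, so the
#' resampling is unpaired), recomputes the median size reduction per
#' replicate, and returns the sample standard deviation over `B` replicates.
#' Deterministic given `seed`.
#'
#' @inheritParams median_size_reduction
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the resampling stream.
#' @return The bootstrap standard deviation of the reduction (percent).
#' @export
bootstrap_sd <- function(pre, post, B = 1000L, seed = 1L) {
  check_sizes(pre, "pre")
  check_sizes(post, "post")
  if (B < 2L) abort("B must be at least 2.")
  reps <- withr::with_seed(seed, {
    pre_meds <- matrixStats_median(matrix(
      sample(pre, length(pre) * B, replace = TRUE), nrow = B))
    post_meds <- matrixStats_median(matrix(
      sample(post, length(post) * B, replace = TRUE), nrow = B))
    (1 - post_meds / pre_meds) * 100
  })
  sd(reps)
}

# row medians of a matrix (no matrixStats dependency)
matrixStats_median <- function(m) apply(m, 1L, median)

#' Mann-Whitney U test for a size shift
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a location shift
#' between the pre- and post-boundary cohorts. U is computed from rank sums
#' with midranks for ties. The p-value is exact (full distribution of U) when
#' `length(pre) * length(post) <= 400` and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @inheritParams median_size_reduction
#' @return A list with elements `U` (pairs where `pre > post`, ties counted
#'   half) and `p`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(pre, post) {
  if (length(pre) < 1L || length(post) < 1L) abort("Both samples must be non-empty.")
  has_ties <- anyDuplicated(c(pre, post)) > 0L
  use_exact <- !has_ties && length(pre) * length(post) <= 400
  ht <- suppressWarnings(
    wilcox.test(pre, post, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Per-group size-reduction table
#'
#' Splits a size table into pre- and post-boundary cohorts, takes the maximum
#' length per species within each cohort (species are the sampling unit; the
#' `unit = "genus"` option collapses further to the maximum per genus), and
#' reports per group: pre/post medians, percent median reduction, bootstrap
#' standard deviation, cohort sizes and the Mann-Whitney test. Groups missing
#' either cohort are omitted with a message.
#'
#' A single pipeline `seed` deterministically spawns an independent
#' substream per group (keyed by the group label), so adding or removing a
#' group never perturbs the others' bootstrap results.
#'
#' @param sizes Size tibble from [read_sizes()] or [generate_sizes()].
#' @param stages A [stage_sequence()].
#' @param traits Trait table used when grouping by a trait column; ignored for
#'   `group_by = "clade"`.
#' @param group_by Grouping column: `"clade"` (default), `"protein_group"`,
#'   `"circulatory"`, ...
#' @param subset_col,subset_val Optional subset (e.g. carbonate-shelled only).
#' @param B,seed Bootstrap replicates and pipeline seed.
#' @param unit Sampling unit, `"species"` (default) or `"genus"`.
#' @return A tibble of class `size_reduction_table`: `group`, `median_pre`,
#'   `median_post`, `log10_median_pre`, `log10_median_post`, `reduction_pct`,
#'   `boot_sd`, `n_pre`, `n_post`, `mwu_statistic`, `mwu_p`.
#' @export
size_selectivity_table <- function(sizes, stages,
                                   traits = default_trait_table(),
                                   group_by = "clade",
                                   subset_col = NULL, subset_val = NULL,
                                   B = 1000L, seed = 1L,
                                   unit = c("species", "genus")) {
  unit <- match.arg(unit)
  b <- boundary_index(stages)
  dat <- sizes |>
    mutate(.idx = stage_index(.data$interval, stages),
           cohort = ifelse(.data$.idx <= b, "pre", "post"))
  if (group_by != "clade" || !is.null(subset_col)) {
    dat <- inner_join(dat, traits, by = "clade")
  }
  if (!is.null(subset_col)) {
    dat <- filter(dat, .data[[subset_col]] == subset_val)
  }
  unit_col <- if (unit == "species") "species" else "genus"
  dat <- dat |>
    group_by(group = as.character(.data[[group_by]]), .data$cohort,
             unit = .data[[unit_col]]) |>
    summarise(max_length = max(.data$max_length), .groups = "drop")

  out <- dat |>
    tidyr::nest(.by = "group") |>
    mutate(res = purrr::map2(.data$data, .data$group, function(d, g) {
      pre <- d$max_length[d$cohort == "pre"]
      post <- d$max_length[d$cohort == "post"]
      if (length(pre) == 0L || length(post) == 0L) {
        inform(sprintf("Group '%s' lacks a pre- or post-boundary cohort; omitted.", g))
        return(NULL)
      }
      mwu <- mann_whitney_u(pre, post)
      tibble(
        median_pre = median(pre), median_post = median(post),
        log10_median_pre = log10(median(pre)),
        log10_median_post = log10(median(post)),
        reduction_pct = median_size_reduction(pre, post),
        boot_sd = bootstrap_sd(pre, post, B = B, seed = group_seed(seed, g)),
        n_pre = length(pre), n_post = length(post),
        mwu_statistic = mwu$U, mwu_p = mwu$p
      )
    })) |>
    select("group", "res") |>
    tidyr::unnest("res") |>
    arrange(.data$group)
  class(out) <- c("size_reduction_table", class(out))
  out
}

# deterministic per-group substream seed (independent of group order)
group_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}
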