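#' Binomial confidence interval
#'
#' Confidence interval for a binomial proportion by the exact Clopper-Pearson
#' method (Beta-distribution quantiles; the conservative default for
#' extinction-magnitude error bars) or the Wilson score interval.
#'
#' @param k Number of successes (e.g. extinct genera), `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`. `k` and `n` may be vectors.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"clopper_pearson"` (default) or `"wilson"`.
#' @return A tibble with columns `low`, `high`.
#' @examples
#' binomial_ci(0, 10)            # high = 1 - 0.025^(1/10)
#' binomial_ci(7, 20, method = "wilson")
#' @export
binomial_ci <- function(k, n, level = 0.95,
                        method = c("clopper_pearson", "wilson")) {
  method <- match.arg(method)
  if (any(n < 1)) abort("n must be >= 1.")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n.")
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1).")
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
    high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  } else {
    z <- qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    low <- pmax(0, centre - half)
    high <- pmin(1, centre + half)
  }
  tibble(low = low, high = high)
}

#' Proportional extinction by group
#'
#' Fraction of cohort genera with no occurrences after the boundary, per
#' group, with a binomial confidence interval. Only genera with a defined
#' extinction status that belong to the boundary cohort (see
#' [build_genus_summaries()]) enter the tallies; groups with an empty cohort
#' are omitted with a message.
#'
#' @param annotated Genus summaries annotated by [assign_traits()] (or any
#'   tibble with `extinct_at_boundary`, `in_cohort` and the grouping column).
#' @param group_by Column to group by: `"clade"`, `"protein_group"`,
#'   `"circulatory"`, ... Use `NULL` for a single pooled estimate.
#' @param level Confidence level.
#' @param ci_method Passed to [binomial_ci()].
#' @return A tibble of class `extinction_estimates`: `group`, `estimator`,
#'   `value`, `ci_low`, `ci_high`, `n_extinct`, `n_total`.
#' @export
proportional_extinction <- function(annotated, group_by = "clade",
                                    level = 0.95,
                                    ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  dat <- filter(annotated, .data$in_cohort, !is.na(.data$extinct_at_boundary))
  if (is.null(group_by)) {
    dat$.group <- "all"
  } else {
    if (!group_by %in% names(dat)) {
      abort(sprintf("Grouping column '%s' not present.", group_by))
    }
    dat$.group <- as.character(dat[[group_by]])
  }
  empty <- setdiff(unique(as.character(annotated[[group_by %||% "clade"]])),
                   unique(dat$.group))
  if (length(empty) && !is.null(group_by)) {
    inform(sprintf("Group(s) with no cohort genera omitted: %s",
                   paste(empty, collapse = ", ")))
  }
  out <- dat |>
    group_by(group = .data$.group) |>
    summarise(n_extinct = sum(.data$extinct_at_boundary),
              n_total = dplyr::n(), .groups = "drop") |>
    mutate(
      estimator = "proportional",
      value = .data$n_extinct / .data$n_total,
      binomial_ci(.data$n_extinct, .data$n_total, level, ci_method) |>
        rename(ci_low = "low", ci_high = "high")
    ) |>
    select("group", "estimator", "value", "ci_low", "ci_high",
           "n_extinct", "n_total")
  class(out) <- c("extinction_estimates", class(out))
  out
}

#' Average extinction over groups
#'
#' Multi-group summaries can be reported as the unweighted mean of group
#' proportions (the convention behind statements like "94.4% on average") or
#' as the pooled proportion over all genera in the groups.
#'
#' @param estimates An `extinction_estimates` tibble.
#' @param groups Character vector of group labels to average.
#' @param mode `"unweighted"` (default) or `"pooled"`.
#' @return A single proportion.
#' @export
group_mean_extinction <- function(estimates, groups,
                                  mode = c("unweighted", "pooled")) {
  mode <- match.arg(mode)
  sub <- filter(estimates, .data$group %in% groups)
  if (nrow(sub) == 0L) abort("No matching groups.")
  if (mode == "unweighted") mean(sub$value) else
    sum(sub$n_extinct) / sum(sub$n_total)
}

#' Stratified extinction comparison
#'
#' Pooled proportional extinction with confidence intervals across strata
#' within a subset of genera — the design behind the circulatory-system
#' comparisons: open vs closed circulation within the hemocyanin group, and
#' hemerythrin/hemocyanin/hemoglobin bins within the open-circulatory group.
#' Empty strata are omitted with a message.
#'
#' @param annotated Trait-annotated genus summaries.
#' @param subset_col,subset_val Column/value pair selecting the subset (e.g.
#'   `protein_group == "hemocyanin"`). Use `subset_col = NULL` for no subset.
#' @param strata_col Column defining the strata to compare.
#' @inheritParams proportional_extinction
#' @return An `extinction_estimates` tibble, one row per non-empty stratum.
#' @examples
#' \dontrun{
#' # open vs closed circulation within hemocyanin carriers:
#' stratified_comparison(ann, "protein_group", "hemocyanin", "circulatory")
#' # protein bins within open-circulatory animals:
#' stratified_comparison(ann, "circulatory", "open", "protein_group")
#' }
#' @export
stratified_comparison <- function(annotated, subset_col, subset_val,
                                  strata_col, level = 0.95,
                                  ci_method = c("clopper_pearson", "wilson")) {
  ci_method <- match.arg(ci_method)
  dat <- annotated
  if (!is.null(subset_col)) {
    dat <- filter(dat, .data[[subset_col]] == subset_val)
  }
  if (nrow(dat) == 0L) abort("Subset selects no genera.")
  proportional_extinction(dat, group_by = strata_col, level = level,
                          ci_method = ci_method)
}
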