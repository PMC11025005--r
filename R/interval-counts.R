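#' Occurrence-pattern counts for one interval
#'
#' Tallies, for interval `i` of the stage sequence, the sliding-window
#' occurrence-pattern counts that feed the sampling-standardized extinction
#' estimators, from the sampled presence sets of the genus summaries:
#'
#' * `two_timer_prev` (2t_i): taxa sampled in intervals i-1 and i;
#' * `three_timer` (3t): taxa sampled in i-1, i and i+1;
#' * `part_timer` (pt): taxa sampled in i-1 and i+1 but not i;
#' * `gap_filler` (gf): taxa sampled in i-1 and i+2 but not in i+1;
#' * `n_bt`: range-through bottom-boundary crossers that also cross the top
#'   of i (first appearance before i, last appearance after i);
#' * `n_bL`: bottom-boundary crossers whose last appearance is in i;
#' * `sampled_in_bin`: taxa sampled in i.
#'
#' Counts whose window extends outside the sequence are an error when a single
#' interval is requested (except the gap-filler window, whose shortfall leaves
#' only `gap_filler` as `NA`, with a message), and `NA` when tabulating all
#' intervals.
#'
#' @param summaries Genus summaries from [build_genus_summaries()].
#' @param stages A [stage_sequence()].
#' @param interval Interval name or index; `NULL` (default) tabulates every
#'   interval.
#' @return A tibble, one row per interval, with the seven counts above.
#' @export
tabulate_interval_counts <- function(summaries, stages, interval = NULL) {
  nm <- stage_names(stages)
  n_int <- length(nm)
  pres <- presence_matrix(summaries, stages)
  first <- apply(pres, 1L, function(r) min(which(r)))
  last <- apply(pres, 1L, function(r) max(which(r)))

  one <- function(i, strict) {
    need <- function(js, what, fatal) {
      out_of_range <- js[js < 1L | js > n_int]
      if (length(out_of_range) && strict) {
        msg <- sprintf(
          "Counting %s for interval '%s' needs interval position %d, outside the sequence.",
          what, nm[i], out_of_range[1])
        if (fatal) abort(msg) else inform(msg)
      }
      length(out_of_range) == 0L
    }
    tt <- if (need(i - 1L, "two-timers", TRUE)) sum(pres[, i - 1L] & pres[, i]) else NA_integer_
    t3 <- if (need(c(i - 1L, i + 1L), "three-timers", TRUE)) {
      sum(pres[, i - 1L] & pres[, i] & pres[, i + 1L])
    } else NA_integer_
    pt <- if (need(c(i - 1L, i + 1L), "part-timers", TRUE)) {
      sum(pres[, i - 1L] & !pres[, i] & pres[, i + 1L])
    } else NA_integer_
    # the gap-filler window alone being short is not fatal: the other counts
    # for this interval are still well defined
    gf <- if (need(c(i - 1L, i + 1L, i + 2L), "gap-fillers", FALSE)) {
      sum(pres[, i - 1L] & pres[, i + 2L] & !pres[, i + 1L])
    } else NA_integer_
    bottom <- first < i & last >= i
    tibble(
      interval = nm[i],
      two_timer_prev = tt, three_timer = t3, part_timer = pt, gap_filler = gf,
      n_bt = sum(bottom & last > i),
      n_bL = sum(bottom & last == i),
      sampled_in_bin = sum(pres[, i])
    )
  }

  if (!is.null(interval)) {
    i <- if (is.character(interval)) stage_index(interval, stages) else as.integer(interval)
    if (is.na(i) || i < 1L || i > n_int) abort("Unknown interval.")
    one(i, strict = TRUE)
  } else {
    purrr::map_dfr(seq_len(n_int), one, strict = FALSE)
  }
}

# genus x interval logical presence matrix from sampled interval sets
presence_matrix <- function(summaries, stages) {
  nm <- stage_names(stages)
  m <- matrix(FALSE, nrow = nrow(summaries), ncol = length(nm),
              dimnames = list(summaries$genus, nm))
  for (r in seq_len(nrow(summaries))) {
    m[r, match(summaries$intervals_present[[r]], nm)] <- TRUE
  }
  m
}

#' Per-capita extinction rate
#'
#' Foote's boundary-crosser rate for one interval:
#' `q = -ln(n_bt / (n_bt + n_bL))`, from the counts of taxa crossing both of
#' the interval's boundaries (`n_bt`) versus crossing the bottom boundary and
#' last appearing within the interval (`n_bL`). Undefined (`NA`, with a
#' message) when `n_bt = 0`.
#'
#' @param counts One row of [tabulate_interval_counts()].
#' @return A non-negative rate, or `NA` when undefined.
#' @export
per_capita_extinction <- function(counts) {
  n_bt <- counts$n_bt
  n_bL <- counts$n_bL
  if (is.na(n_bt) || is.na(n_bL)) return(NA_real_)
  if (n_bt == 0) {
    inform("Per-capita rate undefined: no taxa range through the interval (n_bt = 0).")
    return(NA_real_)
  }
  -log(n_bt / (n_bt + n_bL))
}

#' Pooled sampling completeness
#'
#' Estimated probability that a taxon extant in an interval is sampled in it:
#' `p_s = sum(3t) / (sum(3t) + sum(pt))`, pooled over every interval where the
#' three-timer window fits the sequence.
#'
#' @param counts Tibble from [tabulate_interval_counts()] (all intervals).
#' @return `p_s` in (0, 1].
#' @export
sampling_completeness <- function(counts) {
  ok <- !is.na(counts$three_timer) & !is.na(counts$part_timer)
  t3 <- sum(counts$three_timer[ok])
  pt <- sum(counts$part_timer[ok])
  if (t3 == 0) abort("Sampling completeness undefined: no three-timers.")
  t3 / (t3 + pt)
}

#' Three-timer extinction rate
#'
#' Alroy's completeness-corrected three-timer rate for one interval:
#' `mu = ln(2t_i / 3t) + ln(p_s)`. Sampling noise can drive the estimate
#' negative; negative values are floored at 0 and flagged via the `"floored"`
#' attribute rather than dropped.
#'
#' @param counts One row of [tabulate_interval_counts()].
#' @param p_s Pooled sampling completeness from [sampling_completeness()].
#' @return A non-negative rate with attribute `floored`, or `NA` when the
#'   window does not fit.
#' @export
three_timer_extinction <- function(counts, p_s) {
  if (p_s <= 0 || p_s > 1) abort("p_s must lie in (0, 1].")
  t2 <- counts$two_timer_prev
  t3 <- counts$three_timer
  if (is.na(t2) || is.na(t3)) return(NA_real_)
  if (t3 < 1) {
    inform("Three-timer rate undefined: no three-timers in this window.")
    return(NA_real_)
  }
  floor_rate(log(t2 / t3) + log(p_s))
}

#' Gap-filler extinction rate
#'
#' Alroy's gap-filler rate for one interval:
#' `mu = ln((2t_i + pt) / (3t + pt + gf))`. Negative values are floored at 0
#' and flagged via the `"floored"` attribute.
#'
#' @inheritParams three_timer_extinction
#' @return A non-negative rate with attribute `floored`, or `NA`.
#' @export
gap_filler_extinction <- function(counts) {
  t2 <- counts$two_timer_prev
  t3 <- counts$three_timer
  pt <- counts$part_timer
  gf <- counts$gap_filler
  if (any(is.na(c(t2, t3, pt, gf)))) return(NA_real_)
  denom <- t3 + pt + gf
  if (denom < 1) {
    inform("Gap-filler rate undefined: empty denominator.")
    return(NA_real_)
  }
  floor_rate(log((t2 + pt) / denom))
}

floor_rate <- function(x) {
  if (x < 0) structure(0, floored = TRUE) else structure(x, floored = FALSE)
}

#' Sampling-standardized extinction rates per group
#'
#' Convenience wrapper computing, for one focal interval (default: the
#' boundary interval), the per-capita, three-timer and gap-filler extinction
#' rates within each group of genera. Requires a stage sequence long enough
#' for the requested windows (three-timer: i-1..i+1; gap-filler: i-1..i+2).
#'
#' @param annotated Trait-annotated genus summaries.
#' @param stages A [stage_sequence()].
#' @param group_by Grouping column, or `NULL` for all genera pooled.
#' @param interval Focal interval (name or index); defaults to the boundary
#'   interval.
#' @param estimators Subset of `c("per_capita", "three_timer", "gap_filler")`.
#' @return A tibble `group`, `estimator`, `value`, `floored`.
#' @export
extinction_rates <- function(annotated, stages, group_by = "protein_group",
                             interval = NULL,
                             estimators = c("per_capita", "three_timer",
                                            "gap_filler")) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  i <- if (is.null(interval)) boundary_index(stages)
       else if (is.character(interval)) stage_index(interval, stages)
       else as.integer(interval)
  groups <- if (is.null(group_by)) list(all = annotated) else
    split(annotated, as.character(annotated[[group_by]]))
  purrr::imap_dfr(groups, function(dat, label) {
    all_counts <- tabulate_interval_counts(dat, stages)
    counts_i <- all_counts[i, ]
    p_s <- tryCatch(sampling_completeness(all_counts), error = function(e) NA_real_)
    vals <- list(
      per_capita = function() per_capita_extinction(counts_i),
      three_timer = function() if (is.na(p_s)) NA_real_ else
        three_timer_extinction(counts_i, p_s),
      gap_filler = function() gap_filler_extinction(counts_i)
    )
    purrr::map_dfr(estimators, function(est) {
      v <- vals[[est]]()
      tibble(group = label, estimator = est, value = as.numeric(v),
             floored = isTRUE(attr(v, "floored")))
    })
  })
}
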