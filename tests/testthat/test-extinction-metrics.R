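test_that("Clopper-Pearson bounds hit the closed-form and Beta-quantile values", {
  # k = 0: high = 1 - (alpha/2)^(1/n)
  ci0 <- binomial_ci(0, 10)
  expect_equal(ci0$low, 0)
  expect_equal(ci0$high, 1 - 0.025^(1 / 10), tolerance = 1e-12)
  # k = n: high = 1
  cin <- binomial_ci(10, 10)
  expect_equal(cin$high, 1)
  expect_equal(cin$low, 0.025^(1 / 10), tolerance = 1e-12)
  # interior case against a direct Beta-quantile evaluation
  ci <- binomial_ci(7, 20)
  expect_equal(ci$low, qbeta(0.025, 7, 14), tolerance = 1e-12)
  expect_equal(ci$high, qbeta(0.975, 8, 13), tolerance = 1e-12)
  # and against stats::binom.test's exact interval
  bt <- binom.test(7, 20)$conf.int
  expect_equal(c(ci$low, ci$high), as.numeric(bt), tolerance = 1e-10)
})

test_that("Wilson intervals bracket the point estimate and match score inversion", {
  ci <- binomial_ci(7, 20, method = "wilson")
  expect_true(ci$low <= 7 / 20 && 7 / 20 <= ci$high)
  # prop.test without continuity correction is the Wilson score interval
  pt_ci <- prop.test(7, 20, correct = FALSE)$conf.int
  expect_equal(c(ci$low, ci$high), as.numeric(pt_ci), tolerance = 1e-10)
  expect_error(binomial_ci(3, 0), "n must be")
  expect_error(binomial_ci(5, 3), "0 <= k <= n")
})

test_that("proportional extinction handles complete, zero and simulated groups", {
  s <- two_stage()
  mk <- function(clade, n, n_ext) {
    tibble::tibble(
      genus = paste0(clade, seq_len(n)), clade = clade,
      extinct_at_boundary = rep(c(TRUE, FALSE), c(n_ext, n - n_ext)),
      in_cohort = TRUE
    )
  }
  est <- proportional_extinction(
    dplyr::bind_rows(mk("coral", 10, 10), mk("fish", 4, 0)), "clade")
  expect_equal(est$value[est$group == "coral"], 1)
  expect_equal(est$value[est$group == "fish"], 0)
  expect_equal(est$ci_high[est$group == "coral"], 1)

  # simulation: estimate of a 0.9 extinction probability is inside its own CI
  set.seed(2024)
  ext <- rbinom(200, 1, 0.9)
  ann <- tibble::tibble(genus = paste0("g", 1:200), clade = "sponge",
                        extinct_at_boundary = ext == 1, in_cohort = TRUE)
  est <- proportional_extinction(ann, "clade")
  expect_true(est$ci_low <= 0.9 && 0.9 <= est$ci_high)
})

test_that("adding an extinct genus never decreases proportional extinction", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:30, 1)
    ext <- runif(n) < runif(1)
    ann <- tibble::tibble(genus = paste0("g", 1:n), clade = "x",
                          extinct_at_boundary = ext, in_cohort = TRUE)
    v0 <- proportional_extinction(ann, "clade")$value
    ann2 <- dplyr::bind_rows(ann, tibble::tibble(
      genus = "extra", clade = "x", extinct_at_boundary = TRUE, in_cohort = TRUE))
    v1 <- proportional_extinction(ann2, "clade")$value
    expect_gte(v1, v0)
  }
})

test_that("interval counts follow the window definitions on canonical patterns", {
  s <- five_stage()
  # taxon in (i-1, i, i+1) only: a three-timer and a two-timer at i = 3
  pres <- matrix(FALSE, 2, 5)
  pres[1, 2:4] <- TRUE              # three-timer
  pres[2, c(2, 4)] <- TRUE          # part-timer at i = 3
  sm <- pres_to_summaries(pres, s)
  cc <- tabulate_interval_counts(sm, s, interval = 3)
  expect_equal(cc$three_timer, 1L)
  expect_equal(cc$two_timer_prev, 1L)
  expect_equal(cc$part_timer, 1L)
  expect_equal(cc$gap_filler, 0L)
  # window errors name the problem when a single interval is requested
  expect_error(tabulate_interval_counts(sm, s, interval = 1), "outside the sequence")
  expect_error(tabulate_interval_counts(sm, s, interval = 5), "outside the sequence")
})

test_that("all six counts equal the brute-force per-taxon scan on seeded matrices", {
  s <- five_stage()
  set.seed(1234)
  for (rep in 1:10) {
    pres <- random_presence(20, 5, p = 0.45)
    sm <- pres_to_summaries(pres, s)
    all_counts <- tabulate_interval_counts(sm, s)
    for (i in 2:4) {
      got <- suppressMessages(tabulate_interval_counts(sm, s, interval = i))
      want <- oracle_counts(pres, i)
      for (f in c("two_timer_prev", "three_timer", "part_timer",
                  "n_bt", "n_bL", "sampled_in_bin")) {
        expect_equal(got[[f]], as.integer(want[[f]]), label = f)
        expect_equal(all_counts[[f]][i], as.integer(want[[f]]))
      }
      if (i + 2 <= 5) {
        expect_equal(got$gap_filler, as.integer(want$gap_filler))
      } else {
        expect_true(is.na(got$gap_filler))
      }
    }
  }
})

test_that("rate estimators reproduce their analytic special cases", {
  counts <- tibble::tibble(two_timer_prev = 10L, three_timer = 10L,
                           part_timer = 0L, gap_filler = 0L,
                           n_bt = 10L, n_bL = 0L, sampled_in_bin = 10L)
  # no extinction: everything zero
  expect_equal(per_capita_extinction(counts), 0)
  expect_equal(as.numeric(three_timer_extinction(counts, 1)), 0)
  expect_equal(as.numeric(gap_filler_extinction(counts)), 0)
  # n_bt = n_bL: q = ln 2
  counts2 <- dplyr::mutate(counts, n_bL = 10L)
  expect_equal(per_capita_extinction(counts2), log(2), tolerance = 1e-12)
  # 2t = 2 * 3t, perfect sampling: three-timer rate = ln 2
  counts3 <- dplyr::mutate(counts, two_timer_prev = 20L)
  expect_equal(as.numeric(three_timer_extinction(counts3, 1)), log(2),
               tolerance = 1e-12)
  # gap-filler reduces to ln(2t/3t) when pt = gf = 0
  expect_equal(as.numeric(gap_filler_extinction(counts3)), log(2),
               tolerance = 1e-12)
  # negative estimates are floored and flagged
  counts4 <- dplyr::mutate(counts, two_timer_prev = 10L, three_timer = 12L)
  v <- gap_filler_extinction(counts4)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "floored"))
  # n_bt = 0 is undefined, not infinite
  counts5 <- dplyr::mutate(counts, n_bt = 0L)
  expect_message(q <- per_capita_extinction(counts5), "undefined")
  expect_true(is.na(q))
})

test_that("sampling completeness pools three- and part-timers", {
  s <- five_stage()
  set.seed(77)
  pres <- random_presence(25, 5, p = 0.5)
  sm <- pres_to_summaries(pres, s)
  all_counts <- tabulate_interval_counts(sm, s)
  expect_equal(sampling_completeness(all_counts), oracle_ps(pres),
               tolerance = 1e-12)
  # no part-timers anywhere -> p_s = 1
  full <- matrix(TRUE, 5, 5)
  expect_equal(sampling_completeness(
    tabulate_interval_counts(pres_to_summaries(full, s), s)), 1)
})

test_that("rates computed from a seeded matrix match the hand formulas", {
  s <- five_stage()
  set.seed(4321)
  # draw until the focal window has at least one three-timer (rates defined)
  repeat {
    pres <- random_presence(20, 5, p = 0.5)
    if (oracle_counts(pres, 3)$three_timer >= 1) break
  }
  sm <- pres_to_summaries(pres, s)
  cc <- tabulate_interval_counts(sm, s, interval = 3)
  oc <- oracle_counts(pres, 3)
  ps <- oracle_ps(pres)
  expect_equal(per_capita_extinction(cc),
               -log(oc$n_bt / (oc$n_bt + oc$n_bL)), tolerance = 1e-12)
  expect_equal(as.numeric(three_timer_extinction(cc, sampling_completeness(
    tabulate_interval_counts(sm, s)))),
    max(0, log(oc$two_timer_prev / oc$three_timer) + log(ps)),
    tolerance = 1e-12)
  expect_equal(as.numeric(gap_filler_extinction(cc)),
               max(0, log((oc$two_timer_prev + oc$part_timer) /
                          (oc$three_timer + oc$part_timer + oc$gap_filler))),
               tolerance = 1e-12)
})

test_that("estimators are invariant to genus relabeling and row order", {
  s <- five_stage()
  set.seed(8)
  cfg <- sim_config(stages = s, seed = 15L)
  occ <- generate_occurrences(cfg)$occurrences
  ann <- assign_traits(build_genus_summaries(occ, s))
  r1 <- extinction_rates(ann, s, group_by = NULL)
  # shuffle rows and relabel genera
  occ2 <- occ[sample(nrow(occ)), ]
  occ2$genus <- paste0("taxon_", match(occ2$genus, sort(unique(occ2$genus))))
  ann2 <- assign_traits(build_genus_summaries(occ2, s))
  r2 <- extinction_rates(ann2, s, group_by = NULL)
  expect_equal(r1$value, r2$value, tolerance = 1e-12)
})

test_that("stratified comparisons pool hand-countable fixtures and omit empty strata", {
  # 12 genera: 8 open (5 extinct), 4 closed (1 extinct), all hemocyanin
  ann <- tibble::tibble(
    genus = paste0("g", 1:12),
    clade = "gastropod",
    protein_group = "hemocyanin",
    circulatory = rep(c("open", "closed"), c(8, 4)),
    extinct_at_boundary = c(rep(TRUE, 5), rep(FALSE, 3), TRUE, rep(FALSE, 3)),
    in_cohort = TRUE
  )
  cmp <- stratified_comparison(ann, "protein_group", "hemocyanin", "circulatory")
  expect_equal(cmp$value[cmp$group == "open"], 5 / 8)
  expect_equal(cmp$value[cmp$group == "closed"], 1 / 4)
  expect_equal(cmp$n_total, c(4L, 8L)[order(c("closed", "open"))])

  # a stratum with no defined-status genera is omitted with a message
  ann$extinct_at_boundary[ann$circulatory == "closed"] <- NA
  expect_message(cmp2 <- stratified_comparison(ann, "protein_group",
                                               "hemocyanin", "circulatory"),
                 "omitted")
  expect_equal(cmp2$group, "open")
})

test_that("equal true extinction gives overlapping stratum CIs in most replicates", {
  set.seed(505)
  overlaps <- vapply(1:100, function(r) {
    ann <- tibble::tibble(
      genus = paste0("g", 1:80),
      clade = "gastropod",
      protein_group = "hemocyanin",
      circulatory = rep(c("open", "closed"), each = 40),
      extinct_at_boundary = rbinom(80, 1, 0.7) == 1,
      in_cohort = TRUE
    )
    cmp <- stratified_comparison(ann, "protein_group", "hemocyanin", "circulatory")
    cmp$ci_low[1] <= cmp$ci_high[2] && cmp$ci_low[2] <= cmp$ci_high[1]
  }, logical(1))
  expect_gte(mean(overlaps), 0.90)
})

test_that("multi-group averages support unweighted and pooled modes", {
  est <- tibble::tibble(group = c("a", "b"), estimator = "proportional",
                        value = c(0.9, 0.5), ci_low = 0, ci_high = 1,
                        n_extinct = c(9L, 50L), n_total = c(10L, 100L))
  expect_equal(group_mean_extinction(est, c("a", "b")), 0.7)
  expect_equal(group_mean_extinction(est, c("a", "b"), "pooled"), 59 / 110)
})
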