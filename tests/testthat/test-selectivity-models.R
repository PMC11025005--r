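test_that("OLS recovers an exact line and matches the normal equations", {
  df <- tibble::tibble(x = c(0, 1, 2, 3), y = 2 * c(0, 1, 2, 3) + 1)
  fit <- suppressWarnings(ols_fit(df, "x", "y"))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$p_slope, 0.01)

  set.seed(61)
  df5 <- tibble::tibble(x = rnorm(5), y = rnorm(5))
  fit5 <- ols_fit(df5, "x", "y")
  want <- oracle_ols(df5$x, df5$y)
  expect_equal(fit5$slope, want$slope, tolerance = 1e-12)
  expect_equal(fit5$intercept, want$intercept, tolerance = 1e-12)
  expect_equal(fit5$r_squared, want$r_squared, tolerance = 1e-12)

  expect_error(ols_fit(tibble::tibble(x = c(1, 1, 1), y = 1:3), "x", "y"),
               "constant")
  expect_error(ols_fit(tibble::tibble(x = 1:2, y = 1:2), "x", "y"), "3 points")
})

test_that("independent noise yields near-zero R squared", {
  set.seed(300)
  df <- tibble::tibble(x = rnorm(100), y = sample(rnorm(100)))
  expect_lt(ols_fit(df, "x", "y")$r_squared, 0.05)
})

test_that("on standardized data the OLS slope is the Pearson correlation", {
  set.seed(17)
  for (rep in 1:5) {
    x <- rnorm(30)
    y <- 0.6 * x + rnorm(30)
    zx <- (x - mean(x)) / sd(x)
    zy <- (y - mean(y)) / sd(y)
    fit <- ols_fit(tibble::tibble(x = zx, y = zy), "x", "y")
    expect_equal(fit$slope, cor(x, y), tolerance = 1e-12)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
  }
})

test_that("tidy and glance expose the broom-style fit summaries", {
  df <- tibble::tibble(x = 1:6, y = c(2, 4, 5, 8, 9, 13))
  fit <- ols_fit(df, "x", "y")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$nobs, 6L)
})

make_annotated <- function(n = 60, seed = 1) {
  withr::with_seed(seed, {
    grp <- sample(protein_groups(), n, replace = TRUE)
    caps <- capacity_values()
    tibble::tibble(
      genus = paste0("g", seq_len(n)),
      clade = "mixed",
      protein_group = grp,
      o2_capacity = unname(caps[grp]),
      geo_range = sample(1:20, n, replace = TRUE),
      n_occurrences = sample(1:50, n, replace = TRUE),
      motility = sample(c("motile", "non_motile"), n, replace = TRUE),
      buffered = sample(c("buffered", "unbuffered"), n, replace = TRUE),
      mineralogy = sample(c("carbonate", "siliceous"), n, replace = TRUE),
      extinct_at_boundary = runif(n) < 0.5,
      in_cohort = TRUE
    )
  })
}

test_that("encode_design shapes, codes and standardizes covariates", {
  ann <- make_annotated(6)
  d <- encode_design(ann, covariates = c("o2_capacity", "motility"))
  expect_equal(dim(d$x), c(6L, 3L)) # intercept + 2 covariates
  expect_equal(colnames(d$x), c("(Intercept)", "o2_capacity", "motile"))
  expect_true(all(d$y %in% 0:1))
  # z-scored continuous column
  expect_equal(mean(d$x[, "o2_capacity"]), 0, tolerance = 1e-12)
  expect_equal(sd(d$x[, "o2_capacity"]), 1, tolerance = 1e-12)
  # binary coding is 0/1
  expect_true(all(d$x[, "motile"] %in% 0:1))

  # categorical capacity: 3 dummies, diffusion as reference
  dc <- encode_design(ann, covariates = "o2_capacity",
                      capacity_mode = "categorical")
  expect_equal(colnames(dc$x),
               c("(Intercept)", "occ_hemerythrin", "occ_hemocyanin",
                 "occ_hemoglobin"))
  expect_equal(unname(dc$reference["o2_capacity"]), "diffusion")
  ref_rows <- ann$protein_group == "diffusion"
  expect_true(all(dc$x[ref_rows, -1] == 0))

  # single-level covariates are dropped with a warning
  ann2 <- make_annotated(10)
  ann2$motility <- "motile"
  expect_warning(d2 <- encode_design(ann2, covariates = c("o2_capacity", "motility")),
                 "single-level")
  expect_false("motile" %in% colnames(d2$x))
  # genera with undefined status are excluded
  ann3 <- make_annotated(10)
  ann3$extinct_at_boundary[1:3] <- NA
  d3 <- encode_design(ann3, covariates = "o2_capacity")
  expect_equal(nrow(d3$x), 7L)
})

test_that("a single 2x2 binary covariate recovers the log odds ratio", {
  # a = 20 extinct/exposed, b = 10 surviving/exposed,
  # c = 15 extinct/unexposed, d = 30 surviving/unexposed
  a <- 20; b <- 10; cc <- 15; d <- 30
  x <- cbind(1, rep(c(1, 0), c(a + b, cc + d)))
  y <- c(rep(1, a), rep(0, b), rep(1, cc), rep(0, d))
  fit <- logistic_fit(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[2]), log(a * d / (b * cc)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[1]), log(cc / d), tolerance = 1e-8)
})

test_that("the fitted log-likelihood matches a coordinate-search oracle", {
  set.seed(90)
  n <- 80
  x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5), rnorm(n))
  colnames(x) <- c("(Intercept)", "x1", "x2", "x3")
  eta <- -0.3 + 0.8 * x[, 2] - 0.5 * x[, 3] + 0.2 * x[, 4]
  y <- rbinom(n, 1, plogis(eta))
  fit <- logistic_fit(x, y)
  oracle <- oracle_logistic_max(x, y)
  expect_equal(fit$log_lik, oracle$loglik, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), oracle$beta, tolerance = 1e-3)
})

test_that("a noise covariate rarely produces large z scores", {
  set.seed(404)
  big_z <- replicate(100, {
    n <- 500
    x <- cbind(1, rnorm(n))
    y <- rbinom(n, 1, 0.5)
    fit <- logistic_fit(x, y)
    abs(fit$z[2]) >= 3
  })
  expect_gte(mean(!big_z), 0.99)
})

test_that("separation is flagged instead of silently reported", {
  x <- cbind(1, c(rep(0, 10), rep(1, 10)))
  y <- c(rep(0, 10), rep(1, 10)) # perfectly separated
  expect_warning(fit <- logistic_fit(x, y), "converge|separation")
  expect_false(fit$converged)
  expect_error(tidy(fit), "non-converged")
  expect_equal(nrow(tidy(fit, check_convergence = FALSE)), 2L)
})

test_that("the fit is invariant to the dummy reference level", {
  ann <- make_annotated(200, seed = 55)
  d <- encode_design(ann, covariates = "o2_capacity",
                     capacity_mode = "categorical")
  fit <- logistic_fit(d)
  # re-parameterize with hemoglobin as reference instead of diffusion
  grp <- ann$protein_group[!is.na(ann$extinct_at_boundary)]
  x2 <- cbind(1, sapply(c("diffusion", "hemerythrin", "hemocyanin"),
                        function(g) as.numeric(grp == g)))
  fit2 <- logistic_fit(x2, d$y)
  expect_equal(fit$log_lik, fit2$log_lik, tolerance = 1e-8)
})

test_that("coefficient recovery: true effects fall within two standard errors", {
  set.seed(7117)
  hits <- unlist(lapply(1:100, function(r) {
    n <- 2000
    cap <- sample(0:3, n, replace = TRUE)
    lrange <- rnorm(n)
    eta <- 2 - 1.2 * cap - 0.8 * lrange
    y <- rbinom(n, 1, plogis(eta))
    fit <- logistic_fit(cbind(1, cap = cap, lrange = lrange), y)
    c(abs(fit$coefficients["cap"] - (-1.2)) <= 2 * fit$se["cap"],
      abs(fit$coefficients["lrange"] - (-0.8)) <= 2 * fit$se["lrange"])
  }))
  expect_gte(mean(hits), 0.93)
})

test_that("selectivity reports carry the conventional significance marks", {
  expect_equal(nrow(selectivity_report(list())), 0L)
  df <- tibble::tibble(x = 1:10, y = 3 * (1:10) + rnorm(10, sd = 0.01))
  fit <- ols_fit(df, "x", "y")
  rep1 <- selectivity_report(list(trend = fit))
  expect_equal(unique(rep1$model), "trend")
  expect_equal(rep1$signif[rep1$p.value < 0.001], rep("***", sum(rep1$p.value < 0.001)))
  # thresholding
  expect_equal(respsel:::signif_stars(c(0.0005, 0.005, 0.5)),
               c("***", "**", "NS"))
})
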