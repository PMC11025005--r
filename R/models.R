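#' Group-level least-squares selectivity fit
#'
#' Ordinary (or weighted) least squares of a group-level outcome — proportional
#' extinction or percent size reduction — on the groups' O2-carrying
#' capacities. This is the fit behind capacity-versus-extinction and
#' capacity-versus-size-reduction scatter regressions. Unweighted by default
#' (each group is one point); pass group sizes as `weights` for weighted LS.
#'
#' @param data A data frame containing `x` and `y`.
#' @param x,y Column names (strings) of predictor and outcome.
#' @param weights Optional column name of non-negative weights.
#' @return An object of class `ols_fit` with fields `slope`, `intercept`,
#'   `r_squared`, `p_slope` (two-sided t, n - 2 df), `n`, `residuals` and the
#'   underlying `lm` fit. Supports [tidy()], [glance()] and [autoplot()].
#' @export
ols_fit <- function(data, x = "o2_capacity", y = "value", weights = NULL) {
  xv <- data[[x]]
  yv <- data[[y]]
  if (length(xv) < 3L) abort("At least 3 points are required.")
  if (length(unique(xv)) < 2L) abort("Predictor is constant; no slope is identifiable.")
  df <- tibble(.x = xv, .y = yv)
  fit <- if (is.null(weights)) {
    lm(.y ~ .x, data = df)
  } else {
    lm(.y ~ .x, data = df, weights = data[[weights]])
  }
  sm <- summary(fit)
  structure(list(
    slope = unname(coef(fit)[".x"]),
    intercept = unname(coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    p_slope = sm$coefficients[".x", "Pr(>|t|)"],
    n = length(xv),
    residuals = unname(stats::residuals(fit)),
    x = xv, y = yv,
    xlab = x, ylab = y,
    fit = fit
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "<ols_fit> n = %d | slope = %.4g, intercept = %.4g | R^2 = %.3f, p = %.4g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p_slope))
  invisible(x)
}

#' @rdname ols_fit
#' @param x An `ols_fit`.
#' @param ... Unused.
#' @export
tidy.ols_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", x$xlab),
    estimate = unname(sm[, "Estimate"]),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname ols_fit
#' @export
glance.ols_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_slope, nobs = x$n)
}

#' Build the design matrix for the genus-level logistic regression
#'
#' Encodes trait-annotated genus summaries into a numeric design matrix (with
#' intercept) and a 0/1 outcome vector (`extinct_at_boundary`). Genera with
#' undefined extinction status are excluded. Continuous covariates —
#' `o2_capacity`, `geo_range` (log10), `n_occurrences` (log10(n + 1)) — are
#' z-scored; binary covariates are coded 0/1 (`motility`: motile = 1;
#' `buffered`: buffered = 1; `mineralogy` enters as a carbonate-shell flag).
#' With `capacity_mode = "categorical"` the O2 class enters as three dummy
#' columns with the diffusion group as reference level. Covariates with a
#' single observed level are dropped with a warning.
#'
#' @param annotated Trait-annotated genus summaries (must include `geo_range`
#'   when requested as a covariate; see [compute_geographic_range()]).
#' @param covariates Character vector drawn from `o2_capacity`, `geo_range`,
#'   `motility`, `buffered`, `mineralogy`, `n_occurrences`.
#' @param capacity_mode `"continuous"` (default) or `"categorical"`.
#' @param scale Z-score the continuous covariates? Default `TRUE`.
#' @return A list: `x` (design matrix incl. intercept), `y` (0/1 outcome),
#'   `terms` (column names), `reference` (named reference levels).
#' @export
encode_design <- function(annotated,
                          covariates = c("o2_capacity", "geo_range",
                                         "motility", "buffered",
                                         "mineralogy", "n_occurrences"),
                          capacity_mode = c("continuous", "categorical"),
                          scale = TRUE) {
  capacity_mode <- match.arg(capacity_mode)
  allowed <- c("o2_capacity", "geo_range", "motility", "buffered",
               "mineralogy", "n_occurrences")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) abort(sprintf("Unknown covariate(s): %s", paste(bad, collapse = ", ")))

  dat <- filter(annotated, .data$in_cohort, !is.na(.data$extinct_at_boundary))
  if (nrow(dat) == 0L) abort("No genera with a defined extinction status.")
  y <- as.integer(dat$extinct_at_boundary)

  zscore <- function(v) if (scale) (v - mean(v)) / sd(v) else v
  cols <- list()
  reference <- character()
  for (cv in covariates) {
    new <- switch(cv,
      o2_capacity = if (capacity_mode == "continuous") {
        list(o2_capacity = zscore(dat$o2_capacity))
      } else {
        grp <- factor(dat$protein_group, levels = protein_groups())
        reference <- c(reference, o2_capacity = "diffusion")
        dummies <- lapply(protein_groups()[-1], function(g) as.numeric(grp == g))
        setNames(dummies, paste0("occ_", protein_groups()[-1]))
      },
      geo_range = {
        if (!"geo_range" %in% names(dat)) abort("geo_range column missing; join compute_geographic_range() first.")
        list(log10_geo_range = zscore(log10(dat$geo_range)))
      },
      n_occurrences = list(log10_occurrences = zscore(log10(dat$n_occurrences + 1))),
      motility = list(motile = as.numeric(dat$motility == "motile")),
      buffered = list(buffered = as.numeric(dat$buffered == "buffered")),
      mineralogy = list(carbonate = as.numeric(dat$mineralogy == "carbonate"))
    )
    cols <- c(cols, new)
  }
  constant <- purrr::map_lgl(cols, ~ length(unique(.x)) < 2L || sd(.x) == 0)
  if (any(constant)) {
    warn(sprintf("Dropping single-level covariate(s): %s",
                 paste(names(cols)[constant], collapse = ", ")))
    cols <- cols[!constant]
  }
  if (!length(cols)) abort("No usable covariates remain.")
  x <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  list(x = x, y = y, terms = colnames(x), reference = reference)
}

#' Genus-level multiple logistic selectivity regression
#'
#' Maximum-likelihood logistic regression of genus extinction status on the
#' encoded covariates, fitted by iteratively reweighted least squares (a
#' Newton-type iteration on the binomial log-likelihood). Standard errors are
#' taken from the inverse observed information; each coefficient gets a Wald z
#' and a two-sided p. Complete or quasi-complete separation (diverging
#' coefficients / degenerate fitted probabilities) sets `converged = FALSE`
#' and the estimates are withheld from `tidy()` with an error rather than
#' reported silently.
#'
#' @param design Design list from [encode_design()], or a numeric matrix with
#'   intercept column.
#' @param outcome 0/1 outcome vector (ignored when `design` is an
#'   `encode_design()` list).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance.
#' @return An object of class `logistic_fit`: `coefficients`, `se`, `z`, `p`,
#'   `log_lik`, `n`, `converged`, `reference`, and the underlying `glm`.
#' @export
logistic_fit <- function(design, outcome = NULL, max_iter = 100L, tol = 1e-10) {
  if (is.list(design) && !is.data.frame(design)) {
    x <- design$x
    y <- design$y
    reference <- design$reference
  } else {
    x <- as.matrix(design)
    y <- outcome
    reference <- character()
  }
  if (is.null(y)) abort("Outcome vector required.")
  if (length(unique(y)) < 2L) abort("Need at least one event and one non-event.")

  has_intercept <- all(x[, 1] == 1)
  xx <- if (has_intercept) x[, -1, drop = FALSE] else x
  df <- as.data.frame(xx)
  df$.y <- y
  sep_warn <- FALSE
  do_fit <- function(d) withCallingHandlers(
    glm(.y ~ ., data = d, family = binomial(),
        control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  fit <- do_fit(df)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  if (length(aliased)) {
    # perfectly collinear columns (e.g. trait codings that coincide at clade
    # level): drop them and refit rather than reporting NA coefficients
    warn(sprintf("Dropping aliased covariate(s): %s",
                 paste(aliased, collapse = ", ")))
    xx <- xx[, setdiff(colnames(xx), aliased), drop = FALSE]
    df <- as.data.frame(xx)
    df$.y <- y
    fit <- do_fit(df)
  }
  separated <- sep_warn || any(abs(coef(fit)[-1]) > 15)
  converged <- isTRUE(fit$converged) && !separated
  if (!converged) {
    warn("Logistic fit did not converge cleanly (possible separation); estimates flagged.")
  }
  sm <- summary(fit)$coefficients
  nm <- c(if (has_intercept) "(Intercept)", colnames(xx))
  structure(list(
    coefficients = setNames(sm[, "Estimate"], nm),
    se = setNames(sm[, "Std. Error"], nm),
    z = setNames(sm[, "z value"], nm),
    p = setNames(sm[, "Pr(>|z|)"], nm),
    log_lik = as.numeric(logLik(fit)),
    n = length(y),
    converged = converged,
    reference = reference,
    fit = fit
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> n = %d | logLik = %.3f | converged: %s\n",
              x$n, x$log_lik, x$converged))
  print(tidy(x, check_convergence = FALSE), n = Inf)
  invisible(x)
}

#' @rdname logistic_fit
#' @param x A `logistic_fit`.
#' @param check_convergence Error on a non-converged fit (default `TRUE`)?
#' @param ... Unused.
#' @export
tidy.logistic_fit <- function(x, check_convergence = TRUE, ...) {
  if (check_convergence && !x$converged) {
    abort("Fit flagged as non-converged/separated; inspect with tidy(x, check_convergence = FALSE).")
  }
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(x$z),
         p.value = unname(x$p))
}

#' @rdname logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble(logLik = x$log_lik, nobs = x$n, converged = x$converged)
}

#' Coefficient report with significance stars
#'
#' Formats one or more fitted selectivity models into a single coefficient
#' table with the conventional significance marks: `***` for p < 0.001, `**`
#' for p < 0.01, and `NS` otherwise. No multiple-testing correction is applied
#' across coefficients (per-coefficient Wald/t p-values are reported as-is).
#'
#' @param fits A named list of `logistic_fit` and/or `ols_fit` objects.
#' @return A tibble `model`, `term`, `estimate`, `std.error`, `p.value`,
#'   `signif`.
#' @export
selectivity_report <- function(fits) {
  if (length(fits) == 0L) {
    return(tibble(model = character(), term = character(),
                  estimate = double(), std.error = double(),
                  p.value = double(), signif = character()))
  }
  if (is.null(names(fits))) names(fits) <- paste0("model_", seq_along(fits))
  purrr::imap_dfr(fits, function(f, nm) {
    td <- if (inherits(f, "logistic_fit")) tidy(f, check_convergence = FALSE) else tidy(f)
    td |>
      mutate(model = nm, signif = signif_stars(.data$p.value)) |>
      select("model", "term", "estimate", "std.error", "p.value", "signif")
  })
}

signif_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", TRUE ~ "NS")
}
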