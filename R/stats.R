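new_burial_fit <- function(model, coefficients, r_squared, p_value, n, fit) {
  structure(list(model = model, coefficients = coefficients,
                 r_squared = r_squared, p_value = p_value, n = n, fit = fit),
            class = "burial_fit")
}

#' @export
print.burial_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<burial_fit> %s model, n = %d, r2 = %.3f, p = %.3g\n",
              x$model, x$n, x$r_squared, x$p_value))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Evaluate a fitted burial model at new covariate values
#'
#' @param object a `burial_fit`.
#' @param x covariate values (temperature in degrees C for the linear and
#'   quadratic models, % non-flooded forest for the exponential model).
#' @param ... unused.
#' @return predicted burial / accumulation rates, g C m^-2 yr^-1.
#' @export
predict.burial_fit <- function(object, x, ...) {
  co <- object$coefficients[, "estimate"]
  switch(object$model,
         linear = co[["intercept"]] + co[["slope"]] * x,
         quadratic = co[["intercept"]] + co[["x"]] * x + co[["x2"]] * x^2,
         exponential = co[["a"]] * exp(co[["b"]] * x),
         stop("unknown model type"))
}

ols_fit <- function(x, y, degree, model_name, coef_names) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < degree + 2L)
    stop("need at least ", degree + 2L, " points for the ", model_name, " model")
  fit <- if (degree == 1L) stats::lm(y ~ x) else stats::lm(y ~ x + I(x^2))
  sm <- summary(fit)
  if (any(is.na(stats::coef(fit))))
    stop("collinear design; cannot fit the ", model_name, " model")
  coefs <- cbind(estimate = stats::coef(fit), se = sm$coefficients[, "Std. Error"])
  rownames(coefs) <- coef_names
  pval <- if (sm$fstatistic[["value"]] >= 0 && is.finite(sm$fstatistic[["value"]]))
    stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
              sm$fstatistic[["dendf"]], lower.tail = FALSE) else NA_real_
  new_burial_fit(model_name, coefs, max(0, sm$r.squared), unname(pval),
                 length(x), fit)
}

#' Temperature control models: lakes (linear) and forests (quadratic)
#'
#' Ordinary least squares on untransformed rates. The lake model regresses
#' natural-biome whole-lake burial on annual air temperature (linear); the
#' forest model regresses forest OC accumulation on temperature
#' (second-order polynomial).
#'
#' @param natural_lakes data.frame with columns `temp` (degrees C) and
#'   `burial` (g C m^-2 yr^-1), natural-biome lakes only.
#' @param forest_table optional data.frame with columns `temp` and
#'   `oc_accum` (forest OC accumulation, g C m^-2 yr^-1).
#' @return list with elements `lake_linear` and (when `forest_table` is
#'   given) `forest_quadratic`, each a `burial_fit`.
#' @export
fit_temperature_models <- function(natural_lakes, forest_table = NULL) {
  out <- list(lake_linear = ols_fit(natural_lakes$temp, natural_lakes$burial,
                                    1L, "linear", c("intercept", "slope")))
  if (!is.null(forest_table))
    out$forest_quadratic <- ols_fit(forest_table$temp, forest_table$oc_accum,
                                    2L, "quadratic", c("intercept", "x", "x2"))
  out
}

#' Exponential forest-cover model of Amazon lake burial
#'
#' Fits `burial = a * exp(b * forest%)` by nonlinear least squares so that
#' the coefficient standard errors refer to the original scale; the fit is
#' initialized from the log-linear OLS estimate (which is exact when the
#' data are noiseless).
#'
#' @param forest_pct % non-flooded forest in the chosen buffer.
#' @param burial whole-lake burial rates, g C m^-2 yr^-1; must be positive.
#' @return a `burial_fit` with coefficients `a` and `b`.
#' @export
fit_forest_exponential <- function(forest_pct, burial) {
  keep <- is.finite(forest_pct) & is.finite(burial)
  x <- forest_pct[keep]; y <- burial[keep]
  if (length(x) < 3L) stop("need at least 3 points")
  if (any(y <= 0)) stop("burial rates must be positive for the exponential model")
  if (stats::var(log(y)) < 1e-20) {
    # constant response: the model degenerates to b = 0, a = mean
    coefs <- cbind(estimate = c(a = mean(y), b = 0), se = c(0, 0))
    return(new_burial_fit("exponential", coefs, 0, NA_real_, length(x), NULL))
  }
  loglin <- stats::lm(log(y) ~ x)
  start <- list(a = exp(unname(stats::coef(loglin)[1L])),
                b = unname(stats::coef(loglin)[2L]))
  fit <- tryCatch(
    stats::nls(y ~ a * exp(b * x), start = start,
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) {
      if (requireNamespace("minpack.lm", quietly = TRUE))
        minpack.lm::nlsLM(y ~ a * exp(b * x), start = start)
      else stop(e)
    })
  sm <- summary(fit)
  coefs <- cbind(estimate = stats::coef(fit), se = sm$coefficients[, "Std. Error"])
  rownames(coefs) <- c("a", "b")
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) max(0, 1 - rss / tss) else 0
  new_burial_fit("exponential", coefs, r2,
                 unname(sm$coefficients["b", "Pr(>|t|)"]), length(x), fit)
}

#' Compare burial rates among lake classes
#'
#' One-way ANOVA with Tukey's post-hoc test on natural-log burial rates,
#' summarised as a compact letter display (classes sharing a letter do not
#' differ at the family-wise 0.05 level). Distributional diagnostics
#' (Kolmogorov-Smirnov normality on the raw rates, Bartlett homogeneity) and
#' the rank-based Kruskal-Wallis test are reported alongside.
#'
#' @param rates_by_class named list of numeric burial-rate vectors (one per
#'   class), or a data.frame with columns `class` and `burial`. Groups with
#'   fewer than 2 observations are excluded with a warning; rates must be
#'   positive (natural-log transform).
#' @param alpha family-wise significance level for the letter display.
#' @param letters compute the compact letter display (default TRUE; set
#'   FALSE to skip it, e.g. in large simulation loops).
#' @return list with `anova` (the aov summary table), `p_value` (the ANOVA
#'   F-test p), `tukey` (TukeyHSD result), `letters` (named character
#'   vector, or NULL), `kruskal`, `ks`, `bartlett` (htest objects), and
#'   `excluded` (names of dropped groups).
#' @export
group_comparison <- function(rates_by_class, alpha = 0.05, letters = TRUE) {
  if (is.data.frame(rates_by_class)) {
    stopifnot(all(c("class", "burial") %in% names(rates_by_class)))
    rates_by_class <- split(rates_by_class$burial, rates_by_class$class)
  }
  sizes <- vapply(rates_by_class, length, 1L)
  excluded <- names(rates_by_class)[sizes < 2L]
  if (length(excluded))
    warning("group(s) with n < 2 excluded: ", paste(excluded, collapse = ", "))
  rates_by_class <- rates_by_class[sizes >= 2L]
  if (length(rates_by_class) < 2L) stop("need at least 2 groups with n >= 2")
  if (any(unlist(rates_by_class) <= 0))
    stop("rates must be positive for the log transform")
  df <- data.frame(
    log_rate = log(unlist(rates_by_class, use.names = FALSE)),
    class = factor(rep(names(rates_by_class),
                       vapply(rates_by_class, length, 1L))))
  raw <- unlist(rates_by_class, use.names = FALSE)
  fit <- stats::aov(log_rate ~ class, data = df)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)
  letter_disp <- if (!letters) NULL
  else if (stats::var(stats::resid(fit)) < 1e-12) {
    stats::setNames(rep("a", nlevels(df$class)), levels(df$class))
  } else {
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(class = "Tukey"))
    multcomp::cld(glht, level = alpha)$mcletters$Letters
  }
  list(anova = summary(fit),
       p_value = summary(fit)[[1L]][["Pr(>F)"]][1L],
       tukey = tuk,
       letters = letter_disp,
       kruskal = stats::kruskal.test(df$log_rate, df$class),
       ks = suppressWarnings(
         stats::ks.test(raw, "pnorm", mean(raw), stats::sd(raw))),
       bartlett = stats::bartlett.test(split(df$log_rate, df$class)),
       excluded = excluded)
}

#' Select the buffer size whose forest-cover model fits best
#'
#' Returns the buffer with the highest r-squared; ties are broken toward the
#' smaller buffer (the more local predictor).
#'
#' @param per_buffer_fits named list mapping buffer size (km^2, as names) to
#'   `burial_fit` objects (or any list with an `r_squared` element).
#' @return numeric buffer size (km^2).
#' @export
select_buffer <- function(per_buffer_fits) {
  if (!length(per_buffer_fits)) stop("no buffer fits supplied")
  buf <- as.numeric(names(per_buffer_fits))
  r2 <- vapply(per_buffer_fits, function(f) f$r_squared, numeric(1))
  best <- which(r2 == max(r2))
  buf[best[which.min(buf[best])]]
}

#' Variance of burial rates vs number of measurements
#'
#' For each subsample size n, draws `reps` random subsamples without
#' replacement and averages their sample variances; a flattening curve
#' indicates the dataset is large enough for stable variance estimates.
#'
#' @param rates numeric vector of rates.
#' @param n_grid subsample sizes (each >= 2 and <= `length(rates)`).
#' @param reps number of random subsamples per size.
#' @param seed integer seed; the curve is deterministic given the seed.
#' @return data.frame with columns `n` and `mean_variance`.
#' @export
variance_curve <- function(rates, n_grid, reps = 100, seed = 1) {
  if (any(n_grid > length(rates)))
    stop("subsample size exceeds the number of measurements")
  if (any(n_grid < 2L)) stop("subsample sizes must be >= 2")
  if (reps < 1L) stop("reps must be >= 1")
  set.seed(seed)
  data.frame(n = n_grid, mean_variance = vapply(n_grid, function(n)
    mean(replicate(reps, stats::var(sample(rates, n)))), numeric(1)))
}
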