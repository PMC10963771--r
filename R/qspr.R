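#' Ordinary least squares for structure-property regressions
#'
#' Thin wrapper around [stats::lm()] that carries the summary statistics
#' used in QSPR work: the multiple correlation coefficient
#' \eqn{R = \sqrt{1 - RSS/TSS}}, the adjusted coefficient of determination
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-p-1)}, the standard error of
#' estimate \eqn{SEE = \sqrt{RSS/(n-p-1)}} and the Fisher ratio
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))}.
#'
#' @param data a data frame with one row per compound.
#' @param response column name (string) of the response.
#' @param predictors character vector of predictor column names.
#' @return an object of class `qspr_fit`; see [tidy.qspr_fit()] and
#'   [glance.qspr_fit()].
#' @examples
#' d <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
#' fit <- ols(d, "y", "x")
#' glance(fit)$R        # 1: exact fit
#' @export
ols <- function(data, response, predictors) {
  data <- as.data.frame(data)
  stopifnot(is.character(response), length(response) == 1L,
            is.character(predictors), length(predictors) >= 1L)
  missing_cols <- setdiff(c(response, predictors), names(data))
  if (length(missing_cols)) {
    stop("columns not in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(data)
  p <- length(predictors)
  if (n <= p + 1L) {
    stop(sprintf("need more observations (%d) than predictors + 1 (%d)", n, p + 1L),
         call. = FALSE)
  }
  y <- data[[response]]
  if (stats::var(y) == 0) {
    stop("response is constant (zero total sum of squares)", call. = FALSE)
  }
  f <- stats::reformulate(predictors, response)
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: predictors are linearly dependent", call. = FALSE)
  }
  s <- summary(fit)
  r2 <- s$r.squared
  structure(
    list(
      fit = fit, formula = f, n = n, p = p,
      response = response, predictors = predictors,
      R = sqrt(r2), r.squared = r2, adj.r.squared = s$adj.r.squared,
      SEE = s$sigma,
      F = (r2 / p) / ((1 - r2) / (n - p - 1))
    ),
    class = "qspr_fit"
  )
}

#' @export
print.qspr_fit <- function(x, ...) {
  cat("QSPR OLS fit:", deparse(x$formula), "\n")
  co <- summary(x$fit)$coefficients
  terms <- rownames(co)
  eq <- paste(sprintf("%.3f(±%.3f)%s", co[, 1], co[, 2],
                      ifelse(terms == "(Intercept)", "", terms)),
              collapse = " + ")
  cat(" ", x$response, "=", eq, "\n")
  cat(sprintf("  R = %.4f; R2(adjusted) = %.4f; SEE = %.4f; F = %.3f; n = %d\n",
              x$R, x$adj.r.squared, x$SEE, x$F, x$n))
  invisible(x)
}

#' Tidiers for QSPR fits
#'
#' `tidy()` returns the coefficient table (term, estimate, standard error);
#' `glance()` the one-row model summary (R, R squared, adjusted R squared,
#' SEE, F, n, p).
#'
#' @param x a [ols()] fit.
#' @param ... unused.
#' @return a tibble.
#' @importFrom generics tidy glance
#' @exportS3Method generics::tidy
tidy.qspr_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1], std.error = co[, 2])
}

#' @rdname tidy.qspr_fit
#' @exportS3Method generics::glance
glance.qspr_fit <- function(x, ...) {
  tibble::tibble(R = x$R, r.squared = x$r.squared,
                 adj.r.squared = x$adj.r.squared, SEE = x$SEE, F = x$F,
                 n = x$n, p = x$p)
}

#' @export
generics::tidy

#' @export
generics::glance

#' Scatter plot of a QSPR fit
#'
#' Simple regressions are drawn as response versus the predictor with the
#' fitted line; multivariate fits as observed versus fitted values.
#'
#' @param object a [ols()] fit.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qspr_fit <- function(object, ...) {
  d <- stats::model.frame(object$fit)
  if (object$p == 1L) {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[object$predictors]],
                                         y = .data[[object$response]])) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           linewidth = 0.4, colour = "grey40")
  } else {
    d$.fitted <- stats::fitted(object$fit)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$.fitted,
                                         y = .data[[object$response]])) +
      ggplot2::geom_point() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey40") +
      ggplot2::labs(x = "fitted")
  }
  p + ggplot2::theme_minimal()
}

# printed statistics of the six published regression models, exactly as
# printed (values compared at their printed number of decimals)
published_models <- local({
  row <- function(model, stat, printed, digits, note = NA_character_) {
    tibble::tibble(model = model, stat = stat, printed = printed,
                   digits = digits, note = note)
  }
  dplyr::bind_rows(
    # Model 1: RI ~ NFI
    row("RI~NFI", "slope_nfi", 0.025, 3),
    row("RI~NFI", "intercept", 2.288, 3),
    row("RI~NFI", "R", 0.986, 3),
    row("RI~NFI", "R2_adj", 0.970, 3),
    row("RI~NFI", "SEE", 0.3982, 4),
    row("RI~NFI", "F", 695.844, 3,
        "printed F inconsistent with printed R at n = 21"),
    # Model 2: ECI ~ NFI
    row("ECI~NFI", "slope_nfi", 0.034, 3),
    row("ECI~NFI", "intercept", 1.729, 3),
    row("ECI~NFI", "R", 0.994, 3),
    row("ECI~NFI", "R2_adj", 0.987, 3),
    row("ECI~NFI", "SEE", 0.3438, 4),
    row("ECI~NFI", "F", 1538.095, 3),
    # Model 3: E ~ NFI
    row("E~NFI", "slope_nfi", 0.076, 3),
    row("E~NFI", "intercept", 5.435, 3),
    row("E~NFI", "R", 0.990, 3),
    row("E~NFI", "R2_adj", 0.980, 3),
    row("E~NFI", "SEE", 0.9741, 4),
    row("E~NFI", "F", 987.512, 3,
        "computed value is the printed one with transposed digits"),
    # Model 4: E ~ NFI + RI + ECI
    row("E~NFI+RI+ECI", "slope_nfi", 0.001, 3),
    row("E~NFI+RI+ECI", "slope_ri", 1.503, 3),
    row("E~NFI+RI+ECI", "slope_eci", 1.085, 3),
    row("E~NFI+RI+ECI", "intercept", 0.120, 3),
    row("E~NFI+RI+ECI", "R", 1.000, 3),
    row("E~NFI+RI+ECI", "R2_adj", 0.999, 3),
    row("E~NFI+RI+ECI", "SEE", 0.2015, 4),
    row("E~NFI+RI+ECI", "F", 7714.178, 3),
    # Model 5: BP ~ NFI
    row("BP~NFI", "slope_nfi", 1.427, 3),
    row("BP~NFI", "intercept", 61.88, 2),
    row("BP~NFI", "R", 0.9994, 4,
        "printed R inconsistent with printed adjusted R2 = 0.969 and F"),
    row("BP~NFI", "R2_adj", 0.969, 3),
    row("BP~NFI", "SEE", 22.5524, 4),
    row("BP~NFI", "F", 631.678, 3),
    # Model 6: BP ~ NFI + RI + ECI
    row("BP~NFI+RI+ECI", "slope_nfi", -0.232, 3),
    row("BP~NFI+RI+ECI", "slope_ri", 20.871, 3),
    row("BP~NFI+RI+ECI", "slope_eci", 33.201, 3),
    row("BP~NFI+RI+ECI", "intercept", -43.263, 3),
    row("BP~NFI+RI+ECI", "R", 0.996, 3),
    row("BP~NFI+RI+ECI", "R2_adj", 0.991, 3),
    row("BP~NFI+RI+ECI", "SEE", 12.303, 3),
    row("BP~NFI+RI+ECI", "F", 723.172, 3)
  )
})

#' Refit the six published regression models on the catalog data
#'
#' Fits the four simple and two multivariate OLS models relating the
#' catalog's printed NFI, Randic index and edge-connectivity index to each
#' other, to pi-electron energy (E) and to boiling point (BP), and compares
#' every computed statistic to its printed value at the printed number of
#' decimals (half-away-from-zero rounding). Known print inconsistencies
#' (for instance the BP model's printed R = 0.9994, which contradicts its
#' own printed adjusted R squared and F) are annotated in the `note`
#' column, never silently dropped.
#'
#' @param catalog a catalog tibble, by default [benzenoid_catalog()].
#' @return a list with `fits` (named list of [ols()] fits) and `report`
#'   (tibble: model, stat, computed, printed, digits, match, note).
#' @examples
#' rep <- reproduce_models()$report
#' subset(rep, stat == "R")
#' @export
reproduce_models <- function(catalog = benzenoid_catalog()) {
  d <- data.frame(NFI = catalog$nfi_ref, RI = catalog$randic_ref,
                  ECI = catalog$eci_ref, E = catalog$pi_energy,
                  BP = catalog$boiling_point)
  fits <- list(
    "RI~NFI" = ols(d, "RI", "NFI"),
    "ECI~NFI" = ols(d, "ECI", "NFI"),
    "E~NFI" = ols(d, "E", "NFI"),
    "E~NFI+RI+ECI" = ols(d, "E", c("NFI", "RI", "ECI")),
    "BP~NFI" = ols(d, "BP", "NFI"),
    "BP~NFI+RI+ECI" = ols(d, "BP", c("NFI", "RI", "ECI"))
  )
  computed_stat <- function(fit, stat) {
    co <- stats::coef(fit$fit)
    switch(stat,
      slope_nfi = unname(co["NFI"]),
      slope_ri = unname(co["RI"]),
      slope_eci = unname(co["ECI"]),
      intercept = unname(co["(Intercept)"]),
      R = fit$R,
      R2_adj = fit$adj.r.squared,
      SEE = fit$SEE,
      F = fit$F
    )
  }
  report <- published_models
  report$computed <- vapply(seq_len(nrow(report)), function(i) {
    computed_stat(fits[[report$model[i]]], report$stat[i])
  }, numeric(1))
  report$match <- round_half_up(report$computed, report$digits) == report$printed
  report <- report[, c("model", "stat", "computed", "printed", "digits",
                       "match", "note")]
  list(fits = fits, report = report)
}
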