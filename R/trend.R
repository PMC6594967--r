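#' Trend-line fits for latitude and depth profiles
#'
#' Ordinary least-squares trend curves used on the aggregated profiles: an
#' order-`degree` polynomial in the predictor (default 6, as used for
#' latitude profiles) or a logarithmic trend `y = a + b ln(x)` (as used for
#' depth profiles).
#'
#' @param x,y Numeric vectors.
#' @param kind `"polynomial"` or `"logarithmic"`.
#' @param degree Polynomial degree (ignored for logarithmic trends).
#' @return A `trend_fit` object with `coefficients`, `r_squared`,
#'   `fitted`, and a `predict(newx)` closure.
#' @export
fit_trend <- function(x, y, kind = c("polynomial", "logarithmic"),
                      degree = 6) {
  kind <- match.arg(kind)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (kind == "polynomial") {
    if (degree < 1) stop_hexrich("degree must be >= 1", "domain_error")
    if (length(unique(x)) < degree + 1) {
      stop_hexrich(
        sprintf("need at least %d distinct x values", degree + 1),
        "domain_error"
      )
    }
    fit <- lm(y ~ poly(x, degree, raw = TRUE))
    predict_fun <- function(newx) {
      as.numeric(predict(fit, newdata = data.frame(x = newx)))
    }
  } else {
    if (any(x <= 0)) {
      stop_hexrich("logarithmic trend requires x > 0", "domain_error")
    }
    if (length(unique(x)) < 2) {
      stop_hexrich("need at least 2 distinct x values", "domain_error")
    }
    fit <- lm(y ~ log(x))
    predict_fun <- function(newx) {
      as.numeric(predict(fit, newdata = data.frame(x = newx)))
    }
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      kind = kind,
      degree = if (kind == "polynomial") degree else 1L,
      coefficients = coef(fit),
      r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
      fitted = as.numeric(stats::fitted(fit)),
      residuals = as.numeric(stats::residuals(fit)),
      predict = predict_fun,
      n = length(x)
    ),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s (degree %d), n = %d, R^2 = %.3f\n",
    x$kind, x$degree, x$n, x$r_squared
  ))
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A [fit_trend()] result.
#' @param ... Unused.
#' @return One row per coefficient: `term`, `estimate`.
#' @export
tidy.trend_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients)
  )
}

#' @rdname tidy.trend_fit
#' @return `glance()`: a one-row summary with `kind`, `degree`,
#'   `r.squared`, `nobs`.
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::tibble(
    kind = x$kind, degree = x$degree,
    r.squared = x$r_squared, nobs = x$n
  )
}

#' Tidy / summarise fitted richness models
#'
#' Broom-style accessors for `model_fit` objects (from [fit_nb_smooth()] or
#' [fit_poisson_glm()]) and AICc [selection_table()]s.
#'
#' @param x A `model_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient; `glance()`: a one-row model
#'   summary.
#' @export
tidy.model_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients)
  )
}

#' @rdname tidy.model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$label,
    family = x$family,
    theta = x$theta,
    logLik = x$loglik,
    edf = x$edf,
    k = x$k,
    nobs = x$n,
    AICc = x$aicc,
    deviance = x$deviance,
    null.deviance = x$null_deviance,
    deviance.explained = x$deviance_explained,
    converged = x$converged
  )
}
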