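#' Fit growth models to a field-size series
#'
#' Two simple growth models of field size over time:
#' * **linear** — ordinary least squares of the count on calendar year
#'   (slope in authors/year);
#' * **exponential** — OLS of the natural-log count on year, so the slope
#'   is a continuous growth rate and `exp(slope) - 1` the annual growth
#'   rate. Non-positive counts are outside the log's domain and are
#'   dropped before fitting (never offset-shifted: an arbitrary +1 moves
#'   small-field fits materially); the number dropped is recorded.
#'
#' Reported statistics are those of the simple regression: slope,
#' intercept (on the raw year scale; computation centres the year
#' internally for numerical stability), adjusted R², residual standard
#' error sigma, and the overall F statistic on (1, n - 2) degrees of
#' freedom.
#'
#' @param data a census tibble (see [census()]) or any data frame with a
#'   `year` column and the measure column.
#' @param measure which count to model: `"unique_authors"` or `"papers"`.
#' @return A `growth_fit` object; see [tidy.growth_fit()] and
#'   [glance.growth_fit()] for tibble views.
#' @export
#' @examples
#' s <- data.frame(year = 2000:2009, unique_authors = round(100 * exp(0.05 * (0:9))))
#' fit_exponential(s)$annual_growth_rate
#' glance(fit_linear(s))
fit_linear <- function(data, measure = c("unique_authors", "papers")) {
  measure <- match.arg(measure)
  fit_growth_impl(data, measure, model = "linear")
}

#' @rdname fit_linear
#' @export
fit_exponential <- function(data, measure = c("unique_authors", "papers")) {
  measure <- match.arg(measure)
  fit_growth_impl(data, measure, model = "exponential")
}

fit_growth_impl <- function(data, measure, model) {
  if (!all(c("year", measure) %in% names(data))) {
    abort(glue::glue("data must have columns 'year' and '{measure}'"))
  }
  d <- tibble::tibble(year = as.numeric(data$year), y = as.numeric(data[[measure]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n_dropped <- 0L
  if (model == "exponential") {
    pos <- d$y > 0
    n_dropped <- sum(!pos)
    d <- d[pos, , drop = FALSE]
    d$y <- log(d$y)
  }
  if (nrow(d) < 3) abort("growth fits need at least 3 usable points")
  if (stats::var(d$year) == 0) abort("zero variance in year: cannot fit a trend")

  yc <- d$year - mean(d$year)
  fit <- stats::lm(y ~ yc, data = d)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1]) - slope * mean(d$year)
  n <- nrow(d)
  # statistics from the sums of squares directly: summary.lm()'s R^2 is
  # numerical noise when the response is constant
  sse <- sum(stats::residuals(fit)^2)
  syy <- sum((d$y - mean(d$y))^2)
  r2 <- if (syy == 0) 0 else max(0, 1 - sse / syy)
  sigma <- sqrt(sse / (n - 2))
  out <- structure(
    list(
      model = model,
      measure = measure,
      label = if ("label" %in% names(data)) as.character(data$label[1]) else NA_character_,
      slope = slope,
      intercept = intercept,
      r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
      sigma = sigma,
      f_stat = if (r2 < 1) r2 / (1 - r2) * (n - 2) else Inf,
      df = c(1L, n - 2L),
      n = n,
      n_dropped = n_dropped,
      annual_growth_rate = if (model == "exponential") exp(slope) - 1 else NA_real_,
      fit = fit,
      year_mean = mean(d$year)
    ),
    class = "growth_fit"
  )
  out
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "<growth_fit: %s model of %s%s>\n  slope %.6g, adj R^2 %.4f, sigma %.4g, F %.4g on (1, %d), n = %d\n",
    x$model, x$measure,
    if (!is.na(x$label)) paste0(" [", x$label, "]") else "",
    x$slope, x$adj_r2, x$sigma, x$f_stat, x$df[2], x$n
  ))
  if (x$model == "exponential") {
    cat(sprintf("  annual growth rate %.2f%%", 100 * x$annual_growth_rate))
    if (x$n_dropped > 0) cat(sprintf(" (%d non-positive point(s) dropped)", x$n_dropped))
    cat("\n")
  }
  invisible(x)
}

#' Tidy views of growth fits
#'
#' `tidy()` returns one row per coefficient; `glance()` one row of model
#' summary statistics.
#'
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "year"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    label = x$label, model = x$model, measure = x$measure,
    slope = x$slope, adj_r2 = x$adj_r2, sigma = x$sigma,
    f_stat = x$f_stat, n = x$n,
    annual_growth_rate = x$annual_growth_rate
  )
}

#' Compare linear and exponential growth on the same series
#'
#' Fits both models on an identical year set (the linear fit is restricted
#' to the exponential fit's positive-count years so the adjusted R² values
#' are comparable) and prefers the one with the larger adjusted R².
#' Ties (within 1e-9) go to the simpler linear model. When both adjusted
#' R² values fall below 0.5 the note flags that neither monotone model
#' describes the series (rise-then-fall fields behave this way).
#'
#' @inheritParams fit_linear
#' @return A `growth_comparison`: list with elements `linear`,
#'   `exponential`, `preferred`, `note`.
#' @export
compare_growth <- function(data, measure = c("unique_authors", "papers")) {
  measure <- match.arg(measure)
  d <- tibble::as_tibble(data)
  pos <- !is.na(d[[measure]]) & d[[measure]] > 0 & !is.na(d$year)
  exp_fit <- fit_exponential(d[pos, , drop = FALSE], measure)
  lin_fit <- fit_linear(d[pos, , drop = FALSE], measure)
  preferred <- if (exp_fit$adj_r2 > lin_fit$adj_r2 + 1e-9) "exponential" else "linear"
  note <- if (max(lin_fit$adj_r2, exp_fit$adj_r2) < 0.5) {
    "poor fit: both adjusted R^2 below 0.5; neither monotone growth model describes this series"
  } else {
    ""
  }
  if (sum(!pos) > 0) {
    note <- stringr::str_trim(paste(
      note, glue::glue("{sum(!pos)} non-positive/missing point(s) excluded from both fits")
    ))
  }
  structure(
    list(linear = lin_fit, exponential = exp_fit, preferred = preferred, note = note),
    class = "growth_comparison"
  )
}

#' @export
print.growth_comparison <- function(x, ...) {
  cat(sprintf(
    "<growth_comparison: preferred %s (adj R^2 linear %.4f vs exponential %.4f)>\n",
    x$preferred, x$linear$adj_r2, x$exponential$adj_r2
  ))
  if (nzchar(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' @rdname tidy.growth_fit
#' @export
tidy.growth_comparison <- function(x, ...) {
  dplyr::bind_rows(glance(x$linear), glance(x$exponential))
}

#' @rdname tidy.growth_fit
#' @export
glance.growth_comparison <- function(x, ...) {
  tibble::tibble(
    label = x$linear$label,
    preferred = x$preferred,
    adj_r2_linear = x$linear$adj_r2,
    adj_r2_exponential = x$exponential$adj_r2,
    annual_growth_rate = x$exponential$annual_growth_rate,
    n = x$linear$n,
    note = x$note
  )
}

#' Fit table for several fields
#'
#' Runs [compare_growth()] per field label and stacks the per-model
#' statistics into one table (columns `label`, `model`, `measure`,
#' `slope`, `adj_r2`, `sigma`, `f_stat`, `n`, `annual_growth_rate`).
#'
#' @param data census tibble with a `label` column covering several fields.
#' @inheritParams fit_linear
#' @return A tibble with two rows (linear, exponential) per field.
#' @export
growth_fit_table <- function(data, measure = c("unique_authors", "papers")) {
  measure <- match.arg(measure)
  tibble::as_tibble(data) |>
    dplyr::group_split(.data$label) |>
    purrr::map(~ tidy(compare_growth(.x, measure))) |>
    dplyr::bind_rows()
}

#' Plot a growth-model comparison
#'
#' Observed counts with the fitted linear trend and exponential curve
#' overlaid.
#'
#' @param object a `growth_comparison` from [compare_growth()].
#' @param data the series the comparison was fitted to.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.growth_comparison <- function(object, data, ...) {
  measure <- object$linear$measure
  d <- tibble::as_tibble(data)
  d <- d[!is.na(d[[measure]]) & d[[measure]] > 0, , drop = FALSE]
  grid <- tibble::tibble(year = seq(min(d$year), max(d$year), length.out = 200))
  grid$linear <- object$linear$intercept + object$linear$slope * grid$year
  grid$exponential <- exp(object$exponential$intercept + object$exponential$slope * grid$year)
  fits <- tidyr::pivot_longer(grid, c("linear", "exponential"),
    names_to = "model", values_to = "fitted"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$year, .data[[measure]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = fits,
      ggplot2::aes(.data$year, .data$fitted, colour = .data$model)
    ) +
    ggplot2::labs(
      y = measure, colour = "model",
      subtitle = sprintf("preferred: %s", object$preferred)
    ) +
    ggplot2::theme_minimal()
}
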