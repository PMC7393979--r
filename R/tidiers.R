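#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a diversity-function regression
#'
#' @param x A `bef_fit` from [bef_regression()].
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @method tidy bef_fit
#' @export
tidy.bef_fit <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("(Intercept)", x$metric),
    estimate = unname(cf[, "Estimate"]),
    std_error = unname(cf[, "Std. Error"]),
    statistic = unname(cf[, "t value"]),
    p_value = unname(cf[, "Pr(>|t|)"])
  )
}

#' @rdname tidy.bef_fit
#' @return `glance()`: one row with `metric`, `response`, `slope`,
#'   `intercept`, `r_squared`, `statistic` (the F on 1 and `df_residual`
#'   df), `df_residual`, `p_value`, `n`, `n_dropped`.
#' @method glance bef_fit
#' @export
glance.bef_fit <- function(x, ...) {
  s <- summary(x$fit)
  fstat <- s$fstatistic
  # a constant response has zero total variance: no variance explained
  if (is.null(fstat) || is.nan(s$r.squared)) {
    fstat <- c(value = 0, numdf = 1, dendf = x$n - 2)
    s$r.squared <- 0
  }
  tibble::tibble(
    metric = x$metric,
    response = x$response,
    slope = coef(x$fit)[[2]],
    intercept = coef(x$fit)[[1]],
    r_squared = s$r.squared,
    statistic = unname(fstat["value"]),
    df_residual = as.integer(fstat["dendf"]),
    p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                               fstat["dendf"], lower.tail = FALSE)),
    n = x$n,
    n_dropped = x$n_dropped
  )
}

#' Tidy a main-effects screen
#'
#' @param x A `bef_screen` from [main_effects_screen()].
#' @param ... Unused.
#' @return The per-species tibble (`species`, `estimate`, `std_error`,
#'   `t_ratio`, `p_value`).
#' @method tidy bef_screen
#' @export
tidy.bef_screen <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidy.bef_screen
#' @return `glance()`: one row with `response`, `n`, `df_residual`, `t_crit`,
#'   `alpha`, `n_significant`.
#' @method glance bef_screen
#' @export
glance.bef_screen <- function(x, ...) {
  tibble::tibble(
    response = attr(x, "response"),
    n = attr(x, "n"),
    df_residual = attr(x, "df_residual"),
    t_crit = attr(x, "t_crit"),
    alpha = attr(x, "alpha"),
    n_significant = sum(abs(x$t_ratio) > attr(x, "t_crit"))
  )
}
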