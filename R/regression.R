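#' Simple diversity-function regression
#'
#' Ordinary least-squares regression of an ecosystem-function response on a
#' single diversity metric. Rows where the metric is undefined (e.g. MPD or
#' FDis on monocultures) are dropped first and counted.
#'
#' @param data Data frame with the metric and response columns.
#' @param metric,response Columns (tidy-eval) giving the diversity metric and
#'   the function response.
#' @return A `bef_fit`: the underlying [lm()] fit plus metadata. Use
#'   [tidy()][generics::tidy()] / [glance()][generics::glance()] /
#'   [ggplot2::autoplot()] on it.
#' @examples
#' d <- data.frame(sr = c(1, 3, 5, 6), fun = c(0.26, 0.54, 0.74, 0.82))
#' glance(bef_regression(d, sr, fun))$r_squared
#' @export
bef_regression <- function(data, metric, response) {
  mq <- enquo(metric)
  rq <- enquo(response)
  x <- dplyr::pull(data, !!mq)
  y <- dplyr::pull(data, !!rq)
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need >= 3 paired finite observations.")
  if (var(x) == 0) abort("Zero variance in the diversity metric.")
  fit <- lm(y ~ x)
  structure(
    list(fit = fit, metric = as_name(mq), response = as_name(rq),
         n = length(x), n_dropped = n_dropped,
         data = tibble::tibble(metric = x, response = y)),
    class = "bef_fit"
  )
}

#' @export
print.bef_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "BEF regression: %s ~ %s  (n = %d, dropped %d undefined)\n",
    x$response, x$metric, x$n, x$n_dropped))
  cat(sprintf(
    "  slope = %.4g, R2 = %.3f, F(1,%d) = %.2f, p = %.3g\n",
    coef(x$fit)[2], g$r_squared, g$df_residual, g$statistic, g$p_value))
  invisible(x)
}

#' Main-effects screen over a two-level community design
#'
#' Multiple linear regression of a response on the `-1`/`+1` presence columns
#' of every species (plus intercept). The per-species t-ratio — the main
#' effect estimate divided by its standard error — measures how strongly that
#' species' presence drives the response; `|t| > t_crit` flags a significant
#' species-identity (selection) effect. On an orthogonal fraction the
#' estimates are the usual half-difference-of-means effects.
#'
#' @param data Data frame holding the `-1`/`+1` species columns and the
#'   response column (e.g. a design joined to [response_table()] output). If
#'   a `role` column is present only `design_run` rows are used.
#' @param response Response column (tidy-eval).
#' @param species Character vector of species columns; defaults to
#'   [design_species()] applied after removing known non-design columns.
#' @param alpha Significance level for the reported threshold (default 0.05).
#' @return A `bef_screen`: tibble of `species`, `estimate`, `std_error`,
#'   `t_ratio`, `p_value`, with attributes `df_residual`, `t_crit`, `alpha`,
#'   `n`. Supports [tidy()][generics::tidy()], [glance()][generics::glance()]
#'   and [ggplot2::autoplot()].
#' @export
main_effects_screen <- function(data, response, species = NULL, alpha = 0.05) {
  rq <- enquo(response)
  resp_name <- as_name(rq)
  if ("role" %in% names(data)) {
    data <- dplyr::filter(data, .data$role == "design_run")
  }
  if (is.null(species)) {
    species <- setdiff(names(data),
                       c("run_id", "ecosystem_id", "role", "replicate",
                         "richness", resp_name, .bef_responses))
  }
  y <- dplyr::pull(data, !!rq)
  X <- as.matrix(data[species])
  keep <- is.finite(y) & !apply(is.na(X), 1, any)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= length(species) + 1) {
    abort("Need more observations than species + 1.")
  }
  M <- cbind(`(Intercept)` = 1, X)
  qr_M <- qr(M)
  if (qr_M$rank < ncol(M)) {
    bad <- colnames(M)[setdiff(seq_len(ncol(M)), qr_M$pivot[seq_len(qr_M$rank)])]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  # fit under safe temporary names so arbitrary species labels survive
  df_mod <- as.data.frame(X)
  names(df_mod) <- paste0("..x", seq_along(species))
  df_mod$..y <- y
  fit <- lm(..y ~ ., data = df_mod)
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  df_res <- fit$df.residual
  out <- tibble::tibble(
    species = species,
    estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"],
    t_ratio = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
  structure(out, class = c("bef_screen", class(out)),
            response = resp_name, df_residual = df_res,
            t_crit = qt(1 - alpha / 2, df_res), alpha = alpha, n = n)
}

#' Spearman correlation between two diversity metrics
#'
#' Rank correlation with average-rank tie handling, used to check how
#' decorrelated two diversity axes are across the assembled communities.
#'
#' @param data Data frame.
#' @param a,b Metric columns (tidy-eval). Pairs with a non-finite entry are
#'   dropped.
#' @return Spearman's rho, or `NA_real_` (with a warning) if either input is
#'   constant after dropping.
#' @export
metric_correlation <- function(data, a, b) {
  x <- dplyr::pull(data, {{ a }})
  y <- dplyr::pull(data, {{ b }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) abort("Need >= 3 paired finite values.")
  if (var(x) == 0 || var(y) == 0) {
    warn("Constant input; Spearman correlation undefined.")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}
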