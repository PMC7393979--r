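#' Overyielding log response ratios
#'
#' `log_ratio_mean()` (non-transgressive overyielding, LRmean) compares a
#' polyculture's function with the mean monoculture function of its member
#' species: `ln(poly / mean(monos))`; positive values mean the mixture beats
#' the average member. `log_ratio_max()` (transgressive overyielding, LRmax)
#' compares with the best member monoculture: `ln(poly / max(monos))`;
#' positive values mean the mixture beats its best member. LRmax <= LRmean
#' always.
#'
#' @param poly_value Polyculture response (> 0).
#' @param mono_values Monoculture responses of the polyculture's member
#'   species (> 0).
#' @return The log response ratio.
#' @examples
#' log_ratio_mean(0.6, c(0.2, 0.3, 0.4)) # log(2)
#' @export
log_ratio_mean <- function(poly_value, mono_values) {
  .check_lrr(poly_value, mono_values)
  log(poly_value / mean(mono_values))
}

#' @rdname log_ratio_mean
#' @export
log_ratio_max <- function(poly_value, mono_values) {
  .check_lrr(poly_value, mono_values)
  log(poly_value / max(mono_values))
}

.check_lrr <- function(poly_value, mono_values) {
  if (length(poly_value) != 1 || length(mono_values) < 1) {
    abort("Need one polyculture value and >= 1 monoculture values.")
  }
  if (!is.finite(poly_value) || poly_value <= 0 ||
      any(!is.finite(mono_values)) || any(mono_values <= 0)) {
    abort("Log response ratios are undefined for nonpositive responses.",
          class = "befmix_undefined_lrr")
  }
  invisible(TRUE)
}

#' Overyielding ratios for every polyculture replicate in a design
#'
#' Computes LRmean and LRmax per polyculture replicate and response variable,
#' against the mean across replicates of each member species' monoculture
#' (keeping polyculture-level variance for the one-sample tests). Replicates
#' with nonpositive polyculture or member-monoculture responses yield `NA`
#' and are counted in the `dropped` attribute, never silently lost.
#'
#' @param design Design tibble (see [half_fraction_design()]); monocultures
#'   are the `richness == 1` design rows.
#' @param responses Response tibble from [response_table()] whose
#'   `ecosystem_id`, `replicate` match the design rows.
#' @param response_cols Response columns to ratio (default `od600`,
#'   `scod_re`).
#' @param mono_stat How member monocultures are summarised before the ratio:
#'   `"replicate_mean"` (default) or `"median"`.
#' @return Long tibble: `ecosystem_id`, `replicate`, `richness`, `response`,
#'   `lr_mean`, `lr_max`; attribute `dropped` counts undefined ratios per
#'   response.
#' @export
overyielding_ratios <- function(design, responses,
                                response_cols = c("od600", "scod_re"),
                                mono_stat = c("replicate_mean", "median")) {
  mono_stat <- match.arg(mono_stat)
  sp <- design_species(design)
  members <- design_members(design)
  names(members) <- design$run_id

  long <- responses |>
    tidyr::pivot_longer(dplyr::all_of(response_cols),
                        names_to = "response", values_to = "value") |>
    dplyr::inner_join(
      dplyr::select(design, ecosystem_id = "run_id", "replicate", "richness"),
      by = c("ecosystem_id", "replicate")
    )

  # per-species monoculture reference value, per response
  mono_runs <- design$run_id[design$richness == 1L & design$role == "design_run"]
  mono_map <- vapply(members[mono_runs], `[`, character(1), 1)
  stat_fun <- if (mono_stat == "replicate_mean") mean else median
  mono_ref <- long |>
    dplyr::filter(.data$ecosystem_id %in% mono_runs) |>
    dplyr::mutate(species = mono_map[.data$ecosystem_id]) |>
    dplyr::group_by(.data$species, .data$response) |>
    dplyr::summarise(mono_value = stat_fun(.data$value), .groups = "drop")
  if (nrow(mono_ref) == 0) {
    warn("Design has no monocultures; overyielding ratios cannot be computed.")
    return(structure(
      tibble::tibble(ecosystem_id = character(), replicate = integer(),
                     richness = integer(), response = character(),
                     lr_mean = double(), lr_max = double()),
      dropped = integer(0)
    ))
  }

  poly <- long |>
    dplyr::filter(.data$richness >= 2)
  ref_by_resp <- split(mono_ref, mono_ref$response)

  rows <- purrr::pmap(
    list(poly$ecosystem_id, poly$response, poly$value),
    function(id, resp, value) {
      mem <- members[[id]]
      ref <- ref_by_resp[[resp]]
      monos <- ref$mono_value[match(mem, ref$species)]
      ok <- !anyNA(monos) && all(monos > 0) &&
        is.finite(value) && value > 0
      if (!ok) {
        c(lr_mean = NA_real_, lr_max = NA_real_)
      } else {
        c(lr_mean = log(value / mean(monos)),
          lr_max = log(value / max(monos)))
      }
    }
  )
  out <- poly |>
    dplyr::mutate(
      lr_mean = vapply(rows, `[[`, double(1), "lr_mean"),
      lr_max = vapply(rows, `[[`, double(1), "lr_max")
    ) |>
    dplyr::select("ecosystem_id", "replicate", "richness", "response",
                  "lr_mean", "lr_max")

  dropped <- tapply(is.na(out$lr_mean), out$response, sum)
  if (any(dropped > 0)) {
    warn(paste0("Undefined log response ratios excluded: ",
                paste(names(dropped)[dropped > 0], dropped[dropped > 0],
                      sep = "=", collapse = ", ")))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Richness-level tests of overyielding ratios
#'
#' For one log-response-ratio column: a one-sample t test of each richness
#' level's mean against 0, then an across-level comparison. The family is
#' chosen by a residual-normality gate unless forced: Shapiro-Wilk on the
#' group-centred residuals routes to ordinary one-way ANOVA (with Tukey HSD
#' post hoc); non-normal residuals route to Kruskal-Wallis (pairwise Wilcoxon
#' post hoc, Holm-adjusted); `family = "welch"` forces Welch's ANOVA with
#' pairwise Welch t tests.
#'
#' @param lrr Tibble from [overyielding_ratios()], already filtered to one
#'   `response`.
#' @param value_col Ratio column to test: `"lr_max"` (default, transgressive)
#'   or `"lr_mean"`.
#' @param family `"auto"` (normality-gated), `"anova"`, `"welch"` or
#'   `"kruskal"`.
#' @param alpha Significance level for reporting (default 0.05).
#' @return A list of class `bef_group_tests`: `per_group` (per-richness mean,
#'   t, p, n), `omnibus` (one-row tibble: family, statistic, df, p),
#'   `posthoc` (pairwise comparisons), `alpha`.
#' @export
overyielding_tests <- function(lrr, value_col = c("lr_max", "lr_mean"),
                               family = c("auto", "anova", "welch", "kruskal"),
                               alpha = 0.05) {
  value_col <- match.arg(value_col)
  family <- match.arg(family)
  d <- tibble::tibble(
    richness = lrr$richness,
    value = lrr[[value_col]]
  ) |>
    dplyr::filter(is.finite(.data$value))

  sizes <- table(d$richness)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn(paste0("Richness level(s) skipped (fewer than 2 values): ",
                paste(small, collapse = ", ")))
    d <- d[!d$richness %in% as.integer(small), ]
  }
  if (nrow(d) == 0) abort("No testable groups.")

  per_group <- d |>
    dplyr::group_by(.data$richness) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      # a zero-spread group is degenerate for the t test: its mean either is
      # or is not 0 with no sampling uncertainty
      statistic = ifelse(.data$sd > 0,
                         .data$mean / (.data$sd / sqrt(.data$n)), NA_real_),
      p_value = dplyr::case_when(
        .data$sd > 0 ~ 2 * pt(abs(.data$statistic), .data$n - 1,
                              lower.tail = FALSE),
        .data$mean == 0 ~ 1,
        TRUE ~ 0
      )
    )

  n_groups <- length(unique(d$richness))
  if (n_groups < 2 || var(d$value) == 0) {
    omnibus <- tibble::tibble(family = "none", statistic = NA_real_,
                              df = NA_real_, p_value = NA_real_)
    posthoc <- tibble::tibble()
  } else {
    g <- factor(d$richness)
    if (family == "auto") {
      resid <- d$value - stats::ave(d$value, g)
      family <- if (var(resid) == 0 ||
                    (length(resid) >= 3 && length(resid) <= 5000 &&
                     shapiro.test(resid)$p.value >= alpha)) "anova" else "kruskal"
    }
    if (family == "anova") {
      fit <- aov(value ~ g, data = d)
      s <- summary(fit)[[1]]
      omnibus <- tibble::tibble(family = "anova", statistic = s$`F value`[1],
                                df = s$Df[1], p_value = s$`Pr(>F)`[1])
      tk <- TukeyHSD(fit)$g
      posthoc <- tibble::tibble(comparison = rownames(tk),
                                diff = tk[, "diff"], p_value = tk[, "p adj"])
    } else if (family == "welch") {
      w <- oneway.test(value ~ g, data = d, var.equal = FALSE)
      omnibus <- tibble::tibble(family = "welch", statistic = w$statistic,
                                df = w$parameter[1], p_value = w$p.value)
      pw <- pairwise.t.test(d$value, g, pool.sd = FALSE,
                            p.adjust.method = "holm")$p.value
      posthoc <- .pairwise_to_tbl(pw)
    } else {
      kw <- kruskal.test(d$value, g)
      omnibus <- tibble::tibble(family = "kruskal", statistic = kw$statistic,
                                df = kw$parameter, p_value = kw$p.value)
      pw <- suppressWarnings(
        pairwise.wilcox.test(d$value, g, p.adjust.method = "holm")$p.value
      )
      posthoc <- .pairwise_to_tbl(pw)
    }
  }

  structure(list(per_group = per_group, omnibus = omnibus, posthoc = posthoc,
                 value_col = value_col, alpha = alpha),
            class = "bef_group_tests")
}

.pairwise_to_tbl <- function(pw) {
  out <- as.data.frame(as.table(pw))
  names(out) <- c("group_a", "group_b", "p_value")
  tibble::as_tibble(out[!is.na(out$p_value), ]) |>
    dplyr::mutate(comparison = paste(.data$group_a, .data$group_b, sep = "-"),
                  .before = 1) |>
    dplyr::select("comparison", "p_value")
}

#' @export
print.bef_group_tests <- function(x, ...) {
  cat("Overyielding tests on", x$value_col, "\n")
  cat("Per-richness one-sample t tests vs 0:\n")
  print(x$per_group)
  cat("Across-richness omnibus (", x$omnibus$family[1], "):\n", sep = "")
  print(x$omnibus)
  invisible(x)
}
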