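#' Per-community diversity metrics over a design
#'
#' Computes species richness (SR), Faith's phylogenetic diversity (FPD),
#' mean pairwise phylogenetic distance (MPD), dendrogram functional
#' diversity (dFD) and functional dissimilarity (FDis) for every distinct
#' biotic community in a design. MPD and FDis are pairwise metrics and are
#' `NA` for monocultures.
#'
#' @param design Design tibble.
#' @param tree Rooted phylogeny over the species pool ([ape::phylo]).
#' @param trait_dist Trait distance matrix over the pool (or `NULL` to skip
#'   the functional metrics).
#' @param include_root Root convention for FPD (see [faith_pd()]).
#' @param linkage Linkage for the functional dendrogram (see
#'   [functional_dendrogram()]).
#' @param fdis_agg `"mean"` or `"sum"` (see [fdis()]).
#' @return Tibble: `ecosystem_id`, `sr`, `fpd`, `mpd`, `dfd`, `fdis` — one
#'   row per distinct biotic condition.
#' @export
community_metrics <- function(design, tree, trait_dist = NULL,
                              include_root = TRUE,
                              linkage = c("average", "complete"),
                              fdis_agg = c("mean", "sum")) {
  linkage <- match.arg(linkage)
  fdis_agg <- match.arg(fdis_agg)
  conditions <- design |>
    dplyr::filter(.data$richness > 0) |>
    dplyr::distinct(.data$run_id, .keep_all = TRUE)
  members <- design_members(conditions)
  coph <- cophenetic_matrix(tree)
  dend <- if (!is.null(trait_dist)) functional_dendrogram(trait_dist, linkage)

  tibble::tibble(
    ecosystem_id = conditions$run_id,
    sr = conditions$richness,
    fpd = vapply(members, faith_pd, double(1), tree = tree,
                 include_root = include_root),
    mpd = vapply(members, mpd, double(1), m = coph),
    dfd = if (is.null(trait_dist)) NA_real_ else
      vapply(members, function(m) dfd(dend, m), double(1)),
    fdis = if (is.null(trait_dist)) NA_real_ else
      vapply(members, fdis, double(1), m = trait_dist, agg = fdis_agg)
  )
}

#' Run the full biodiversity-ecosystem-functioning analysis
#'
#' Orchestrates the whole analysis over a community design: per-community
#' diversity metrics, response extraction, diversity-function regressions
#' (over all communities and within intermediate richness subsets),
#' Spearman correlations between the diversity axes, overyielding log
#' response ratios with richness-level tests, and the species main-effects
#' t-ratio screen.
#'
#' @param design Design tibble ([half_fraction_design()] +
#'   [augment_design()]).
#' @param function_tbl Long function table (measured, or from a
#'   [simulate_function_calibrated()]-style generator).
#' @param tree Rooted phylogeny over the pool.
#' @param trait_dist Trait distance matrix over the pool (`NULL` skips dFD /
#'   FDis and their regressions).
#' @param od_time OD600 reading used as the biomass response (h; default
#'   144; sCOD uses the endpoint values in the table).
#' @param alpha Significance level (default 0.05).
#' @param sr_subsets List of richness subsets to re-run the regressions on
#'   (default `list(c(3, 5))`, the intermediate levels where the metrics
#'   vary independently of SR).
#' @param include_root,linkage,fdis_agg Metric options; see
#'   [community_metrics()].
#' @param lrr_family Test family for [overyielding_tests()].
#' @return A `bef_summary` list: `metrics`, `responses`, `community_table`
#'   (metrics joined to per-replicate responses), `regressions` (one row per
#'   metric x response x subset), `correlations`, `lrr`, `lrr_tests`,
#'   `screen`, `log` (dropped-row accounting), `options`.
#' @export
run_bef_pipeline <- function(design, function_tbl, tree, trait_dist = NULL,
                             od_time = 144, alpha = 0.05,
                             sr_subsets = list(c(3, 5)),
                             include_root = TRUE,
                             linkage = c("average", "complete"),
                             fdis_agg = c("mean", "sum"),
                             lrr_family = "auto") {
  linkage <- match.arg(linkage)
  fdis_agg <- match.arg(fdis_agg)
  .validate_pipeline_inputs(design, function_tbl, tree, trait_dist)

  responses <- response_table(function_tbl, od_time = od_time)
  metrics <- community_metrics(design, tree, trait_dist,
                               include_root = include_root,
                               linkage = linkage, fdis_agg = fdis_agg)
  community_table <- responses |>
    dplyr::inner_join(metrics, by = c(ecosystem_id = "ecosystem_id")) |>
    dplyr::arrange(.data$ecosystem_id, .data$replicate)

  metric_cols <- c("sr", "fpd", "mpd", "dfd", "fdis")
  metric_cols <- metric_cols[vapply(metric_cols, function(m)
    any(is.finite(community_table[[m]])), logical(1))]

  subsets <- c(list(NULL), sr_subsets)
  regressions <- purrr::map_dfr(subsets, function(sub) {
    d <- community_table
    label <- "all"
    if (!is.null(sub)) {
      d <- dplyr::filter(d, .data$sr %in% sub)
      label <- paste0("sr_", paste(sub, collapse = "_"))
    }
    purrr::map_dfr(metric_cols, function(m) {
      purrr::map_dfr(.bef_responses, function(r) {
        fit <- tryCatch(
          bef_regression(d, !!rlang::sym(m), !!rlang::sym(r)),
          error = function(e) NULL
        )
        if (is.null(fit)) return(tibble::tibble())
        dplyr::mutate(glance(fit), subset = label, .before = 1)
      })
    })
  })

  correlations <- purrr::map_dfr(
    utils::combn(metric_cols, 2, simplify = FALSE),
    function(pr) {
      rho <- tryCatch(
        suppressWarnings(
          metric_correlation(metrics, !!rlang::sym(pr[1]), !!rlang::sym(pr[2]))
        ),
        error = function(e) NA_real_
      )
      tibble::tibble(metric_a = pr[1], metric_b = pr[2], spearman_rho = rho)
    }
  )

  has_mono <- any(design$richness == 1L & design$role == "design_run")
  if (has_mono) {
    lrr <- overyielding_ratios(design, responses)
    lrr_tests <- purrr::map(
      setNames(.bef_responses, .bef_responses),
      function(r) {
        d <- dplyr::filter(lrr, .data$response == r)
        list(
          lr_mean = overyielding_tests(d, "lr_mean", family = lrr_family,
                                       alpha = alpha),
          lr_max = overyielding_tests(d, "lr_max", family = lrr_family,
                                      alpha = alpha)
        )
      }
    )
  } else {
    warn("Design has no monocultures; overyielding stages skipped.")
    lrr <- NULL
    lrr_tests <- NULL
  }

  screen_data <- design |>
    dplyr::inner_join(responses,
                      by = c(run_id = "ecosystem_id", "replicate"))
  screen <- purrr::map(
    setNames(.bef_responses, .bef_responses),
    function(r) main_effects_screen(screen_data, !!rlang::sym(r),
                                    species = design_species(design),
                                    alpha = alpha)
  )

  log_tbl <- tibble::tibble(
    stage = c("mpd_undefined_rows", "fdis_undefined_rows",
              "lrr_undefined_values"),
    n = c(sum(!is.finite(metrics$mpd)),
          sum(!is.finite(metrics$fdis)),
          if (is.null(lrr)) NA_integer_ else sum(!is.finite(lrr$lr_mean)))
  )

  structure(
    list(metrics = metrics, responses = responses,
         community_table = community_table, regressions = regressions,
         correlations = correlations, lrr = lrr, lrr_tests = lrr_tests,
         screen = screen, log = log_tbl,
         options = list(od_time = od_time, alpha = alpha,
                        include_root = include_root, linkage = linkage,
                        fdis_agg = fdis_agg, sr_subsets = sr_subsets)),
    class = "bef_summary"
  )
}

.validate_pipeline_inputs <- function(design, function_tbl, tree, trait_dist) {
  sp <- design_species(design)
  if (length(sp) < 2) abort("Design has fewer than 2 species columns.")
  bad <- !vapply(design[sp], function(x) all(x %in% c(-1L, 1L)), logical(1))
  if (any(bad)) {
    abort(paste0("Design levels must be -1/+1; offending column(s): ",
                 paste(sp[bad], collapse = ", ")))
  }
  missing_tips <- setdiff(sp, tree$tip.label)
  if (length(missing_tips) > 0) {
    abort(paste0("Tree lacks design species: ",
                 paste(missing_tips, collapse = ", ")))
  }
  if (!is.null(trait_dist)) {
    trait_missing <- setdiff(sp, rownames(as_distance_matrix(trait_dist)))
    if (length(trait_missing) > 0) {
      abort(paste0("Trait matrix lacks design species: ",
                   paste(trait_missing, collapse = ", ")))
    }
  }
  ids <- unique(paste(function_tbl$ecosystem_id, function_tbl$replicate))
  want <- paste(design$run_id, design$replicate)
  orphan <- setdiff(want, ids)
  if (length(orphan) > 0) {
    abort(paste0(length(orphan),
                 " design rows lack responses; first: ", orphan[1]))
  }
  invisible(TRUE)
}

#' @export
print.bef_summary <- function(x, ...) {
  cat("BEF pipeline summary\n")
  cat("  communities:", nrow(x$metrics), " replicated responses:",
      nrow(x$responses), "\n")
  cat("  regressions (subset = all):\n")
  print(dplyr::filter(x$regressions, .data$subset == "all") |>
          dplyr::select("metric", "response", "slope", "r_squared",
                        "statistic", "p_value"))
  cat("  dropped/undefined rows:\n")
  print(x$log)
  invisible(x)
}

#' Write a pipeline summary to disk
#'
#' Emits `report.json` (regressions, correlations, per-group LRR tests,
#' screen tables, drop log, options echo), per-table TSVs under `tables/`,
#' and a `run.log` echoing options and row accounting. Output is
#' deterministic for a deterministic summary.
#'
#' @param summary A `bef_summary` from [run_bef_pipeline()].
#' @param dir Output directory (created if needed).
#' @param seed Optional seed to echo into the report, for provenance.
#' @return `dir`, invisibly.
#' @export
write_bef_report <- function(summary, dir, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tdir <- file.path(dir, "tables")
  if (!dir.exists(tdir)) dir.create(tdir)

  tables <- list(
    metrics = summary$metrics,
    responses = summary$responses,
    community_table = summary$community_table,
    regressions = summary$regressions,
    correlations = summary$correlations
  )
  if (!is.null(summary$lrr)) tables$lrr <- summary$lrr
  for (r in names(summary$screen)) {
    tables[[paste0("screen_", r)]] <- tidy(summary$screen[[r]])
  }
  for (nm in names(tables)) {
    readr::write_tsv(tables[[nm]], file.path(tdir, paste0(nm, ".tsv")))
  }

  report <- list(
    seed = seed,
    options = summary$options,
    regressions = summary$regressions,
    correlations = summary$correlations,
    screen = lapply(summary$screen, function(s)
      list(table = tidy(s), glance = glance(s))),
    lrr_tests = if (!is.null(summary$lrr_tests))
      lapply(summary$lrr_tests, function(resp)
        lapply(resp, function(t)
          list(per_group = t$per_group, omnibus = t$omnibus,
               posthoc = t$posthoc))),
    log = summary$log
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  writeLines(
    c("befmix pipeline run",
      paste0("seed: ", seed %||% "NA"),
      paste0("options: ", jsonlite::toJSON(summary$options, auto_unbox = TRUE)),
      paste0("dropped: ",
             paste(summary$log$stage, summary$log$n, sep = "=",
                   collapse = ", "))),
    file.path(dir, "run.log")
  )
  invisible(dir)
}

#' One-call synthetic combinatorial biodiversity experiment
#'
#' Convenience wrapper binding the generators to the design machinery: a
#' pool ([simulate_pool()]), the augmented half-fraction design over it, and
#' a function table in calibrated or mechanistic mode — everything
#' [run_bef_pipeline()] consumes, from a single seed.
#'
#' @param n_species Pool/design size (default 6).
#' @param seed Master seed (forked per stage).
#' @param mode `"calibrated"` (default) or `"mechanistic"`.
#' @param n_controls,n_replicates Design augmentation (defaults 5 and 3: the
#'   114-ecosystem layout for 6 species).
#' @param ... Passed to the chosen generator.
#' @return List: `design`, `pool`, `function_tbl`, `trait_dist`, `tree`.
#' @export
simulate_bef_experiment <- function(n_species = 6, seed = 1L,
                                    mode = c("calibrated", "mechanistic"),
                                    n_controls = 5, n_replicates = 3, ...) {
  mode <- match.arg(mode)
  pool <- simulate_pool(n_species, seed = .fork_seed(seed, "pool-stage"))
  design <- half_fraction_design(pool$species) |>
    augment_design(add_full_community = TRUE, n_controls = n_controls,
                   n_replicates = n_replicates)
  fn_seed <- .fork_seed(seed, "function-stage")
  function_tbl <- if (mode == "calibrated") {
    simulate_function_calibrated(design, seed = fn_seed, ...)
  } else {
    simulate_function_mechanistic(design, seed = fn_seed, ...)
  }
  profile <- normalize_plate(pool$plate, pool$eeq)
  list(design = design, pool = pool, function_tbl = function_tbl,
       trait_dist = trait_distance_matrix(profile), tree = pool$tree)
}
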