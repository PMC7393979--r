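#' Default richness-level calibration for the synthetic generator
#'
#' Per-richness-level means and standard deviations of the two responses for
#' mono-, tri-, penta- and hexacultures — the distributional structure the
#' calibrated generator reproduces — together with the initial soluble COD of
#' the synthetic wastewater (540 +/- 21 mg O2/L).
#'
#' @return Tibble with columns `richness`, `scod_re_mean`, `scod_re_sd`,
#'   `od600_mean`, `od600_sd`; attributes `scod_initial_mean`,
#'   `scod_initial_sd`.
#' @export
default_calibration <- function() {
  out <- tibble::tibble(
    richness = c(1L, 3L, 5L, 6L),
    scod_re_mean = c(0.266, 0.542, 0.742, 0.822),
    scod_re_sd = c(0.146, 0.155, 0.136, 0.019),
    od600_mean = c(0.065, 0.132, 0.173, 0.216),
    od600_sd = c(0.052, 0.046, 0.049, 0.019)
  )
  attr(out, "scod_initial_mean") <- 540
  attr(out, "scod_initial_sd") <- 21
  out
}

# truncated-normal draw by clipping (bias negligible at the calibrated SDs
# except monoculture OD; documented in the vignette)
.rnorm_clip <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

# shared shape of the simulated OD600 growth curve: saturating rise scaled so
# the reading at `ref_time` equals the drawn endpoint value
.od_curve <- function(od_at_ref, times, ref_time = 144, tau = 48) {
  g <- 1 - exp(-times / tau)
  od_at_ref * g / (1 - exp(-ref_time / tau))
}

.row_function_tbl <- function(design, re, od, scod_init, od_times, ref_time) {
  purrr::pmap_dfr(
    list(design$run_id, design$replicate, re, od, scod_init),
    function(id, rep, re_i, od_i, init_i) {
      tibble::tibble(
        ecosystem_id = id, replicate = rep, time_h = od_times,
        od600 = .od_curve(od_i, od_times, ref_time),
        scod_initial = init_i,
        scod_final = pmax(init_i * (1 - re_i), 0)
      )
    }
  )
}

#' Calibrated synthetic function table
#'
#' Draws per-ecosystem responses from the per-richness-level normal
#' distributions of the calibration table: sCOD removal efficiency clipped to
#' `[0, 1]`, OD600 clipped to `>= 0`, initial sCOD from its own normal, and
#' `scod_final = scod_initial * (1 - RE)`. Abiotic controls get near-zero
#' removal and optical density. Random streams are keyed per (ecosystem,
#' replicate), so adding rows to a design never changes existing draws.
#'
#' @param design Design tibble (see [augment_design()]).
#' @param calibration Calibration tibble as from [default_calibration()];
#'   every biotic richness level in the design must have a row.
#' @param seed Integer master seed.
#' @param od_times OD600 sampling times in hours.
#' @param od_ref_time Time whose OD600 reading equals the calibrated draw
#'   (default 144 h).
#' @return Long function table: `ecosystem_id`, `replicate`, `time_h`,
#'   `od600`, `scod_initial`, `scod_final`.
#' @export
simulate_function_calibrated <- function(design,
                                         calibration = default_calibration(),
                                         seed = 1L,
                                         od_times = c(0, 48, 96, 144, 192),
                                         od_ref_time = 144) {
  biotic <- design$richness > 0
  need <- sort(unique(design$richness[biotic]))
  missing <- setdiff(need, calibration$richness)
  if (length(missing) > 0) {
    abort(paste0("Calibration lacks richness level(s): ",
                 paste(missing, collapse = ", ")))
  }
  init_mean <- attr(calibration, "scod_initial_mean") %||% 540
  init_sd <- attr(calibration, "scod_initial_sd") %||% 21

  cal <- calibration[match(design$richness, calibration$richness), ]
  n <- nrow(design)
  re <- od <- init <- numeric(n)
  for (i in seq_len(n)) {
    rs <- .fork_seed(seed, paste(design$run_id[i], design$replicate[i]))
    withr::local_seed(rs)
    init[i] <- rnorm(1, init_mean, init_sd)
    if (biotic[i]) {
      re[i] <- .rnorm_clip(1, cal$scod_re_mean[i], cal$scod_re_sd[i], 0, 1)
      od[i] <- .rnorm_clip(1, cal$od600_mean[i], cal$od600_sd[i], 0)
    } else {
      re[i] <- rnorm(1, 0, 0.005)
      od[i] <- .rnorm_clip(1, 0, 0.002, 0)
    }
  }
  .row_function_tbl(design, re, od, init, od_times, od_ref_time)
}

#' Mechanistic synthetic function table
#'
#' Generative model with explicit species-identity (selection) and
#' diversity (complementarity) knobs. Per biotic community c,
#' \deqn{\mathrm{logit}(RE_c) = \beta_0 + \overline{a}_{i \in c} +
#'   \gamma \ln(SR_c) + \varepsilon,\quad \varepsilon \sim N(0, \sigma^2)}
#' so with \eqn{\gamma = 0, \sigma = 0} a polyculture's logit-scale removal is
#' exactly the mean of its members' — every mixture sits below its best
#' member (LRmax < 0) — while \eqn{\gamma > 0} lifts richer communities above
#' their members (transgressive overyielding). OD600 is a fixed fraction of
#' RE (`od_scale`), mimicking a biomass proxy proportional to substrate
#' conversion.
#'
#' @param design Design tibble.
#' @param effects Named numeric vector: logit-scale identity effect per
#'   species (one per design species).
#' @param beta0 Baseline on the logit scale.
#' @param gamma Complementarity coefficient on `ln(SR)`.
#' @param sigma Noise SD on the logit scale (>= 0).
#' @param seed Integer master seed.
#' @param link `"logit"` (default, keeps RE in (0,1)) or `"identity"` (for
#'   linear-theory checks; RE clipped to `[0, 1]`).
#' @param od_scale OD600 per unit RE (default 0.26).
#' @param od_times,od_ref_time As in [simulate_function_calibrated()].
#' @return Long function table (same schema as
#'   [simulate_function_calibrated()]).
#' @export
simulate_function_mechanistic <- function(design, effects, beta0 = 0,
                                          gamma = 0, sigma = 0.1, seed = 1L,
                                          link = c("logit", "identity"),
                                          od_scale = 0.26,
                                          od_times = c(0, 48, 96, 144, 192),
                                          od_ref_time = 144) {
  link <- match.arg(link)
  if (sigma < 0) abort("`sigma` must be >= 0.")
  sp <- design_species(design)
  missing <- setdiff(sp, names(effects))
  if (length(missing) > 0) {
    abort(paste0("`effects` lacks species: ", paste(missing, collapse = ", ")))
  }
  members <- design_members(design)
  n <- nrow(design)
  re <- init <- numeric(n)
  for (i in seq_len(n)) {
    rs <- .fork_seed(seed, paste(design$run_id[i], design$replicate[i]))
    withr::local_seed(rs)
    init[i] <- rnorm(1, 540, 21)
    mem <- members[[i]]
    if (length(mem) == 0) {
      re[i] <- rnorm(1, 0, 0.005)
    } else {
      eta <- beta0 + mean(effects[mem]) + gamma * log(length(mem)) +
        rnorm(1, 0, sigma)
      re[i] <- if (link == "logit") plogis(eta) else min(max(eta, 0), 1)
    }
  }
  od <- pmax(re, 0) * od_scale
  .row_function_tbl(design, re, od, init, od_times, od_ref_time)
}

#' Synthetic species pool: random coalescent tree plus plate readings
#'
#' Emulates the upstream inputs of a consortium study: an ultrametric
#' phylogeny over the pool (random sequential coalescence via
#' [ape::rcoal()]) and per-species carbon-source plate readings with
#' positive electron equivalents, nonnegative absorbances and at least one
#' active substrate per species (so plate normalisation never degenerates).
#'
#' @param n_species Pool size (>= 1).
#' @param n_substrates Number of carbon sources (default 31).
#' @param n_replicates Replicate wells per substrate (default 3).
#' @param seed Integer seed.
#' @param p_active Probability a species metabolises a given substrate.
#' @return List: `tree` ([ape::phylo]), `plate` (long tibble incl. blank
#'   rows), `eeq` (substrate electron-equivalent table), `species`.
#' @export
simulate_pool <- function(n_species, n_substrates = 31, n_replicates = 3,
                          seed = 1L, p_active = 0.7) {
  if (n_species < 1) abort("`n_species` must be >= 1.")
  species <- sprintf("sp%02d", seq_len(n_species))
  substrates <- sprintf("substrate%02d", seq_len(n_substrates))
  withr::local_seed(.fork_seed(seed, "pool"))

  tree <- if (n_species == 1) {
    .single_tip_tree(species)
  } else {
    ape::rcoal(n_species, tip.label = species)
  }

  eeq <- tibble::tibble(
    substrate = substrates,
    eeq = round(runif(n_substrates, 4, 40), 1)
  )
  plate <- purrr::map_dfr(species, function(s) {
    active <- runif(n_substrates) < p_active
    if (!any(active)) active[sample.int(n_substrates, 1)] <- TRUE
    level <- ifelse(active, stats::rlnorm(n_substrates, log(0.6), 0.5), 0)
    grid <- tidyr::expand_grid(substrate = c(substrates, "blank"),
                               replicate = seq_len(n_replicates))
    base <- c(level, 0)[match(grid$substrate, c(substrates, "blank"))]
    grid |>
      dplyr::mutate(
        species = s,
        absorbance = pmax(base + 0.05 + rnorm(dplyr::n(), 0, 0.01), 0),
        .before = 1
      )
  })
  list(tree = tree, plate = plate, eeq = eeq, species = species)
}
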