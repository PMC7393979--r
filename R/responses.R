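#' Soluble COD removal efficiency
#'
#' Fraction of the introduced soluble chemical oxygen demand removed over the
#' incubation: `(initial - final) / initial` (mg sCOD removed per mg sCOD
#' introduced). Slightly negative values can arise from measurement noise and
#' are kept with a warning; values below -0.1 are additionally flagged for
#' review.
#'
#' @param initial Initial sCOD, mg O2/L (> 0). Vectorised.
#' @param final Final sCOD, mg O2/L (>= 0). Vectorised.
#' @return Removal efficiency, <= 1.
#' @examples
#' scod_removal_efficiency(540, 270) # 0.5
#' @export
scod_removal_efficiency <- function(initial, final) {
  if (any(initial <= 0)) abort("`initial` sCOD must be > 0.")
  if (any(final < 0)) abort("`final` sCOD must be >= 0.")
  re <- (initial - final) / initial
  if (any(re < 0)) {
    n_flag <- sum(re < -0.1)
    warn(paste0(sum(re < 0), " negative removal efficiencies retained",
                if (n_flag > 0) paste0("; ", n_flag, " below -0.1 (review)")))
  }
  re
}

#' Mean cell volume from volumetric and numeric particle counts
#'
#' @param volume_per_ml Total cell volume per mL (um^3/mL).
#' @param cells_per_ml Cell count per mL (> 0).
#' @return Mean cell volume, um^3 per cell. Vectorised.
#' @export
mean_cell_volume <- function(volume_per_ml, cells_per_ml) {
  if (any(cells_per_ml <= 0)) abort("`cells_per_ml` must be > 0.")
  volume_per_ml / cells_per_ml
}

#' Cell concentration after inoculating into diluent
#'
#' Concentration obtained when `inoc_vol` of a stock at `stock` cells/mL is
#' added to `diluent_vol` of medium: `stock * inoc_vol / (inoc_vol +
#' diluent_vol)`. 45 uL of an 8e8 cells/mL assemblage into 1755 uL gives the
#' standard 2.0e7 cells/mL starting density.
#'
#' @param stock Stock concentration, cells/mL.
#' @param inoc_vol Inoculum volume (> 0), any volume unit.
#' @param diluent_vol Diluent volume (>= 0), same unit.
#' @return Concentration, cells/mL.
#' @export
inoculum_concentration <- function(stock, inoc_vol, diluent_vol) {
  if (any(inoc_vol <= 0)) abort("`inoc_vol` must be > 0.")
  if (any(diluent_vol < 0)) abort("`diluent_vol` must be >= 0.")
  stock * inoc_vol / (inoc_vol + diluent_vol)
}

#' Per-capita constituent load of domestic wastewater
#'
#' Daily mass discharge per person from a per-capita flow and a constituent
#' concentration: `flow * conc / 1000` (L/cap/day x mg/L -> g/cap/day). A
#' 180 L/cap/day person load at 750 mg COD/L is 135 g COD/cap/day.
#'
#' @param flow Flow, L per capita per day (>= 0).
#' @param conc Concentration, mg/L (>= 0).
#' @return Load, g per capita per day.
#' @export
per_capita_load <- function(flow, conc) {
  if (any(flow < 0) || any(conc < 0)) abort("Flow and concentration must be >= 0.")
  flow * conc / 1000
}

#' Per-ecosystem response variables from a function table
#'
#' Collapses a long function table (OD600 time series plus endpoint sCOD) to
#' one row per ecosystem x replicate with the two analysis responses: the
#' OD600 reading at `od_time` (nearest measured time; biomass gross-yield
#' proxy, flagged as morphology-biased) and the end-of-run sCOD removal
#' efficiency.
#'
#' @param function_tbl Long tibble: `ecosystem_id`, `replicate`, `time_h`,
#'   `od600`, `scod_initial`, `scod_final`.
#' @param od_time Time (h) of the OD600 reading used as the biomass response
#'   (default 144).
#' @return Tibble `ecosystem_id`, `replicate`, `od600`, `scod_re`, with
#'   attribute `od600_bias = "morphology-biased (optical proxy)"`.
#' @export
response_table <- function(function_tbl, od_time = 144) {
  need <- c("ecosystem_id", "replicate", "time_h", "od600",
            "scod_initial", "scod_final")
  missing <- setdiff(need, names(function_tbl))
  if (length(missing) > 0) {
    abort(paste0("Function table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- function_tbl |>
    dplyr::group_by(.data$ecosystem_id, .data$replicate) |>
    dplyr::summarise(
      od600 = .data$od600[which.min(abs(.data$time_h - od_time))],
      scod_initial = .data$scod_initial[1],
      scod_final = .data$scod_final[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      scod_re = scod_removal_efficiency(.data$scod_initial, .data$scod_final)
    ) |>
    dplyr::select("ecosystem_id", "replicate", "od600", "scod_re")
  attr(out, "od600_bias") <- "morphology-biased (optical proxy)"
  out
}
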