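#' Two-level half-fraction factorial consortium design
#'
#' Builds the \eqn{2^{k-1}} half fraction of a two-level presence/absence
#' factorial over `k` species. Presence is coded `+1`, absence `-1`. With the
#' negative generator sign the defining relation is \eqn{I = -X_1 X_2 \cdots
#' X_k}: every retained run has level product \eqn{-1}, so for `k = 6` only
#' mono-, tri- and pentacultures appear (6, 20 and 6 runs).
#'
#' @param species Character vector of species names, or a single integer `k`
#'   (names `sp1 ... spk` are generated). At least 2 species.
#' @param sign Generator sign, `"neg"` (default, level product \eqn{-1}) or
#'   `"pos"`.
#' @return A tibble with one row per run: `run_id`, `role`
#'   (`"design_run"`), `replicate`, `richness`, and one `+1`/`-1` column per
#'   species. Rows are ordered lexicographically over the level pattern with
#'   `-1` before `+1`.
#' @examples
#' d <- half_fraction_design(6)
#' table(d$richness)
#' @seealso [augment_design()], [alias_structure()]
#' @export
half_fraction_design <- function(species, sign = c("neg", "pos")) {
  sign <- match.arg(sign)
  if (is.numeric(species) && length(species) == 1) {
    species <- paste0("sp", seq_len(species))
  }
  species <- as.character(species)
  k <- length(species)
  if (k < 2) {
    abort("`species` must name at least 2 factors for a half fraction.")
  }
  if (anyDuplicated(species)) abort("Species names must be unique.")

  sgn <- if (sign == "neg") -1L else 1L
  # enumerate the k-1 free factors; the last column is set by the generator
  base <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k - 1)))
  gen <- sgn * as.integer(apply(base, 1, prod))
  lev <- cbind(base, gen)
  colnames(lev) <- species
  # lexicographic run order over the full pattern, -1 < +1
  ord <- do.call(order, as.data.frame(lev))
  lev <- lev[ord, , drop = FALSE]

  out <- tibble::as_tibble(lev)
  dplyr::bind_cols(
    tibble::tibble(
      run_id = sprintf("run%02d", seq_len(nrow(lev))),
      role = "design_run",
      replicate = 1L,
      richness = as.integer(rowSums(lev == 1L))
    ),
    out
  )
}

#' Species columns of a design table
#'
#' @param design A design tibble as produced by [half_fraction_design()].
#' @return Character vector of species column names.
#' @export
design_species <- function(design) {
  setdiff(names(design), c("run_id", "role", "replicate", "richness"))
}

#' Augment a factorial design with the full community and abiotic controls
#'
#' Adds the all-species community and all-absent abiotic control conditions,
#' then replicates every condition. With the 32-run `k = 6` half fraction,
#' one full community, five controls and triplicates this gives the 114
#' ecosystems of a complete combinatorial biodiversity experiment.
#'
#' @param design Design tibble from [half_fraction_design()].
#' @param add_full_community Add one all-`+1` hexaculture-style condition?
#' @param n_controls Number of distinct abiotic (all-`-1`) control conditions.
#' @param n_replicates Replicates per condition (>= 1).
#' @return A design tibble with `role` in `design_run`, `full_community`,
#'   `abiotic_control` and a `replicate` index; `n_replicates * (runs +
#'   add_full_community + n_controls)` rows.
#' @examples
#' d <- augment_design(half_fraction_design(6), n_controls = 5, n_replicates = 3)
#' nrow(d) # 114
#' @export
augment_design <- function(design, add_full_community = TRUE,
                           n_controls = 0L, n_replicates = 1L) {
  if (n_controls < 0) abort("`n_controls` must be >= 0.")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  sp <- design_species(design)
  k <- length(sp)

  extras <- list()
  if (isTRUE(add_full_community)) {
    full <- tibble::as_tibble(setNames(as.list(rep(1L, k)), sp))
    extras$full <- dplyr::bind_cols(
      tibble::tibble(run_id = "full", role = "full_community",
                     replicate = 1L, richness = k),
      full
    )
  }
  if (n_controls > 0) {
    ctrl <- tibble::as_tibble(setNames(as.list(rep(-1L, k)), sp))
    extras$ctrl <- dplyr::bind_cols(
      tibble::tibble(run_id = sprintf("ctrl%02d", seq_len(n_controls)),
                     role = "abiotic_control", replicate = 1L, richness = 0L),
      ctrl[rep(1, n_controls), ]
    )
  }
  conditions <- dplyr::bind_rows(c(list(design = design), extras))

  dplyr::bind_rows(lapply(seq_len(n_replicates), function(r) {
    dplyr::mutate(conditions, replicate = as.integer(r))
  })) |>
    dplyr::arrange(.data$run_id, .data$replicate)
}

#' Alias structure of a two-level design, up to two-factor interactions
#'
#' Reports every pair of effect columns (main effects and two-factor
#' interactions, plus the intercept) that are fully collinear over the design
#' runs, i.e. confounded. A resolution-VI half fraction such as the `k = 6`
#' negative-generator design returns an empty report: all main effects and
#' two-factor interactions are estimable free of each other.
#'
#' @param design Design tibble; only `role == "design_run"` rows are used,
#'   de-duplicated to one row per level pattern.
#' @return A tibble with columns `effect_a`, `effect_b`, `sign` (`+1` if the
#'   columns are equal, `-1` if opposite), one row per aliased pair. Zero rows
#'   means no aliasing among effects of order <= 2.
#' @examples
#' nrow(alias_structure(half_fraction_design(6))) # 0
#' nrow(alias_structure(half_fraction_design(3))) # k = 3 fraction is aliased
#' @export
alias_structure <- function(design) {
  sp <- design_species(design)
  runs <- design
  if ("role" %in% names(runs)) {
    runs <- dplyr::filter(runs, .data$role == "design_run")
  }
  runs <- dplyr::distinct(runs, dplyr::across(dplyr::all_of(sp)))
  if (nrow(runs) == 0) abort("Design contains no design_run rows.")
  m <- as.matrix(runs)

  cols <- list(`(Intercept)` = rep(1L, nrow(m)))
  for (s in sp) cols[[s]] <- m[, s]
  if (length(sp) >= 2) {
    for (pr in utils::combn(sp, 2, simplify = FALSE)) {
      cols[[paste(pr, collapse = ":")]] <- m[, pr[1]] * m[, pr[2]]
    }
  }
  nm <- names(cols)
  n <- nrow(m)
  out <- list()
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (j <= i) next
      dp <- sum(cols[[i]] * cols[[j]])
      if (abs(dp) == n) {
        out[[length(out) + 1]] <- tibble::tibble(
          effect_a = nm[i], effect_b = nm[j], sign = as.integer(sign(dp))
        )
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(effect_a = character(), effect_b = character(),
                   sign = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Read / write a design table as CSV
#'
#' On disk the presence levels are encoded 0/1 for readability; in memory the
#' analysis coding is `-1`/`+1` (the factor levels of the two-level design).
#'
#' @param design Design tibble.
#' @param path File path.
#' @return `read_design_csv()` returns the design tibble in `-1`/`+1` coding;
#'   `write_design_csv()` returns `path` invisibly.
#' @export
write_design_csv <- function(design, path) {
  sp <- design_species(design)
  out <- dplyr::mutate(
    design,
    dplyr::across(dplyr::all_of(sp), ~ as.integer((.x + 1L) / 2L))
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  sp <- design_species(d)
  bad <- !vapply(d[sp], function(x) all(x %in% c(0, 1)), logical(1))
  if (any(bad)) {
    abort(paste0("Non-0/1 presence entries in column(s): ",
                 paste(sp[bad], collapse = ", ")))
  }
  dplyr::mutate(
    d,
    replicate = as.integer(.data$replicate),
    richness = as.integer(.data$richness),
    dplyr::across(dplyr::all_of(sp), ~ as.integer(2L * .x - 1L))
  )
}

#' Member species of one design row
#'
#' @param design Design tibble.
#' @return A list (one element per row) of character vectors of present
#'   species.
#' @export
design_members <- function(design) {
  sp <- design_species(design)
  m <- as.matrix(design[sp])
  lapply(seq_len(nrow(m)), function(i) sp[m[i, ] == 1L])
}
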