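#' Electron-equivalent normalised trait profile from plate readings
#'
#' Converts community-level physiological profiling reads (e.g. a 31-substrate
#' carbon-source plate read at 590 nm) into a per-species trait profile:
#' replicate absorbances are averaged, blank-corrected (negative activity
#' clips to 0), divided by the substrate's electron equivalents (eeq, mol e-
#' per well) so substrates of different reductance are comparable, and finally
#' divided by the plate average, so each species' profile has mean 1 across
#' substrates by construction.
#'
#' @param plate Long tibble with columns `species`, `substrate`, `absorbance`
#'   and optionally `replicate`. Blank wells appear as rows whose `substrate`
#'   equals `blank`.
#' @param eeq Tibble with columns `substrate`, `eeq` (> 0), one row per
#'   non-blank substrate; alternatively `plate` may carry an `eeq` column.
#' @param blank Name of the blank substrate (default `"blank"`).
#' @return A wide tibble: `species` plus one normalised-activity column per
#'   substrate; every row means to 1 within 1e-9.
#' @export
normalize_plate <- function(plate, eeq = NULL, blank = "blank") {
  need <- c("species", "substrate", "absorbance")
  if (!all(need %in% names(plate))) {
    abort("`plate` needs columns species, substrate, absorbance.")
  }
  if (any(plate$absorbance < 0)) abort("Absorbances must be >= 0.")
  if (is.null(eeq)) {
    if (!"eeq" %in% names(plate)) abort("Provide `eeq` or an eeq column.")
    eeq <- dplyr::distinct(plate[plate$substrate != blank, c("substrate", "eeq")])
  }
  if (any(eeq$eeq <= 0)) abort("All eeq values must be > 0.")

  blanks <- plate |>
    dplyr::filter(.data$substrate == blank) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(blank_od = mean(.data$absorbance), .groups = "drop")
  if (nrow(blanks) == 0) {
    blanks <- tibble::tibble(species = unique(plate$species), blank_od = 0)
  }

  prof <- plate |>
    dplyr::filter(.data$substrate != blank) |>
    dplyr::group_by(.data$species, .data$substrate) |>
    dplyr::summarise(au_raw = mean(.data$absorbance), .groups = "drop") |>
    dplyr::left_join(blanks, by = "species") |>
    dplyr::left_join(eeq[, c("substrate", "eeq")], by = "substrate")
  if (anyNA(prof$eeq)) {
    abort(paste0("Missing eeq for substrate(s): ",
                 paste(unique(prof$substrate[is.na(prof$eeq)]), collapse = ", ")))
  }
  prof <- prof |>
    dplyr::mutate(
      au = pmax(.data$au_raw - .data$blank_od, 0),
      aueeq = .data$au / .data$eeq
    ) |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(plate_mean = mean(.data$aueeq)) |>
    dplyr::ungroup()
  dead <- unique(prof$species[prof$plate_mean == 0])
  if (length(dead) > 0) {
    abort(paste0("Degenerate profile (no activity on any substrate): ",
                 paste(dead, collapse = ", ")))
  }
  prof |>
    dplyr::mutate(activity = .data$aueeq / .data$plate_mean) |>
    dplyr::select("species", "substrate", "activity") |>
    tidyr::pivot_wider(names_from = "substrate", values_from = "activity") |>
    dplyr::arrange(.data$species)
}

#' Euclidean trait distance matrix between species profiles
#'
#' @param profile Wide trait-profile tibble (`species` + substrate columns),
#'   as returned by [normalize_plate()].
#' @return A labelled symmetric distance matrix.
#' @export
trait_distance_matrix <- function(profile) {
  if (!"species" %in% names(profile)) abort("`profile` needs a species column.")
  m <- as.matrix(profile[, setdiff(names(profile), "species")])
  if (anyNA(m)) abort("Profiles must share the same substrate set (no NA).")
  rownames(m) <- profile$species
  as.matrix(dist(m, method = "euclidean"))
}

#' Functional dissimilarity (FDis) of a species subset
#'
#' Mean pairwise Euclidean distance between the member species in trait
#' space. The mean (rather than the sum) is richness-independent, which is
#' what makes FDis usable as a diversity axis decorrelated from species
#' richness; the raw sum is available with `agg = "sum"`.
#'
#' @param m Trait distance matrix from [trait_distance_matrix()].
#' @param members Character vector of species; singletons return `NA`.
#' @param agg `"mean"` (default) or `"sum"` over pairs.
#' @return Nonnegative scalar, or `NA_real_` for a singleton.
#' @export
fdis <- function(m, members, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  m <- as_distance_matrix(m)
  members <- unique(as.character(members))
  missing <- setdiff(members, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("Unknown species: ", paste(missing, collapse = ", ")))
  }
  if (length(members) < 2) return(NA_real_)
  sub <- m[members, members]
  v <- sub[upper.tri(sub)]
  if (agg == "mean") mean(v) else sum(v)
}

#' Functional dendrogram over the full species pool
#'
#' Agglomerative clustering of the trait distance matrix; the dendrogram is
#' built once over the whole pool so that [dfd()] is monotone in its member
#' set.
#'
#' @param m Trait distance matrix.
#' @param linkage Agglomeration method: `"average"` (default, UPGMA, matches
#'   the phylogenetic side) or `"complete"`.
#' @return An [ape::phylo] dendrogram whose cophenetic distances live on the
#'   trait-distance scale.
#' @export
functional_dendrogram <- function(m, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  m <- as_distance_matrix(m)
  labs <- sort(rownames(m))
  if (length(labs) == 1) return(.single_tip_tree(labs))
  h <- hclust(as.dist(m[labs, labs]), method = linkage)
  ape::as.phylo(h)
}

#' Dendrogram-based functional diversity (dFD) of a species subset
#'
#' Branch-length sum of the minimal functional-dendrogram subtree connecting
#' the member species — the same spanning-subtree machinery as [faith_pd()]
#' applied to the trait dendrogram. By default the path above the members'
#' MRCA is excluded, so a monoculture scores 0 and dFD vanishes exactly when
#' all member profiles are identical.
#'
#' @param x Trait distance matrix over the full pool, or a prebuilt
#'   dendrogram ([ape::phylo]) from [functional_dendrogram()].
#' @param members Nonempty character vector of species.
#' @param linkage Linkage used when `x` is a matrix; see
#'   [functional_dendrogram()].
#' @param include_root Count the MRCA-to-root path (as in rooted Faith's PD)?
#'   Default `FALSE`.
#' @return Nonnegative branch-length sum.
#' @export
dfd <- function(x, members, linkage = c("average", "complete"),
                include_root = FALSE) {
  dend <- if (inherits(x, "phylo")) x else functional_dendrogram(x, linkage)
  faith_pd(dend, members, include_root = include_root)
}
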