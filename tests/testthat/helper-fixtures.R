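# shared fixtures, all built in code

# the hand-worked 3-leaf ultrametric example: A,B at distance 2, C at 6
three_leaf_matrix <- function() {
  matrix(c(0, 2, 6,
           2, 0, 6,
           6, 6, 0), 3, byrow = TRUE,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# independent Faith's-PD oracle: explicit union of root-to-tip edge sets
# walked through the edge table, kept separate from the package internals
brute_faith_pd <- function(tree, members, include_root = TRUE) {
  stopifnot(all(members %in% tree$tip.label))
  edge <- tree$edge
  paths <- lapply(match(members, tree$tip.label), function(tip) {
    idx <- integer(0)
    node <- tip
    repeat {
      row <- which(edge[, 2] == node)
      if (length(row) == 0) break
      idx <- c(idx, row)
      node <- edge[row, 1]
    }
    idx
  })
  edges <- unique(unlist(paths))
  if (!include_root) edges <- setdiff(edges, Reduce(intersect, paths))
  sum(tree$edge.length[edges])
}

# brute-force enumeration of all 2^k presence patterns with level product s
enumerate_fraction <- function(k, s = -1L) {
  g <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), k)))
  g[apply(g, 1, prod) == s, , drop = FALSE]
}

# minimal long plate table for one or more species
make_plate <- function(au, eeq, species = "sp1", blank_od = 0) {
  stopifnot(length(au) == length(eeq))
  subs <- paste0("s", seq_along(au))
  vals <- rep(c(pmax(au + blank_od, 0), blank_od), times = length(species))
  plate <- tidyr::expand_grid(species = species,
                              substrate = c(subs, "blank")) |>
    dplyr::mutate(absorbance = vals)
  list(plate = plate, eeq = tibble::tibble(substrate = subs, eeq = eeq))
}

# design + matching endpoint-only function table from explicit responses:
# `responses` has ecosystem_id, replicate, od600, scod_re
make_function_tbl <- function(responses, scod_initial = 540) {
  responses |>
    dplyr::rowwise() |>
    dplyr::mutate(tbl = list(tibble::tibble(
      time_h = c(0, 144, 192),
      od600 = c(0, od600, od600),
      scod_initial = scod_initial,
      scod_final = scod_initial * (1 - scod_re)
    ))) |>
    dplyr::ungroup() |>
    dplyr::select("ecosystem_id", "replicate", "tbl") |>
    tidyr::unnest("tbl")
}
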