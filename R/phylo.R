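#' Validate a species distance matrix
#'
#' @param m Square numeric matrix (or data frame) with matching row/column
#'   labels, zero diagonal, symmetric, nonnegative.
#' @return The validated matrix with dimnames.
#' @export
as_distance_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("Distance matrix must be square.")
  if (is.null(rownames(m)) && is.null(colnames(m))) {
    abort("Distance matrix must carry species labels.")
  }
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m))) {
    abort("Row and column labels must match.")
  }
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("Distances must be nonnegative.")
  if (any(abs(diag(m)) > 1e-12)) abort("Diagonal must be zero.")
  if (any(abs(m - t(m)) > 1e-9)) abort("Distance matrix must be symmetric.")
  m
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering yielding an ultrametric rooted
#' tree: the cophenetic (tip-to-tip path) distance between two tips equals the
#' average-linkage merge height of their clusters on the scale of the input
#' distances. Labels are sorted before clustering so equal-height merges
#' resolve to the lexicographically smallest label set.
#'
#' @param m Distance matrix acceptable to [as_distance_matrix()].
#' @return An [ape::phylo] rooted ultrametric tree.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- upgma_tree(d)
#' cophenetic_matrix(tr)["A", "C"] # 6
#' @export
upgma_tree <- function(m) {
  m <- as_distance_matrix(m)
  labs <- sort(rownames(m))
  if (length(labs) == 1) return(.single_tip_tree(labs))
  m <- m[labs, labs]
  h <- hclust(as.dist(m), method = "average")
  tr <- ape::as.phylo(h)
  tr
}

.single_tip_tree <- function(label) {
  structure(
    list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
         edge.length = 0, Nnode = 1L),
    class = "phylo", order = "cladewise"
  )
}

#' Cophenetic distance matrix of a rooted tree
#'
#' Tip-to-tip path lengths; bridges a tree back to the matrix form consumed
#' by [mpd()].
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @return Symmetric matrix with zero diagonal, labelled by tip.
#' @export
cophenetic_matrix <- function(tree) {
  if (length(tree$tip.label) == 1) {
    return(matrix(0, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  m <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(m))
  m[labs, labs]
}

# edge indices on the path from each tip up to the root
.edges_to_root <- function(tree, node) {
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  idx <- integer(0)
  cur <- node
  repeat {
    e <- match(cur, child)
    if (is.na(e)) break
    idx <- c(idx, e)
    cur <- parent[e]
  }
  idx
}

#' Faith's phylogenetic diversity of a species subset
#'
#' Sum of the branch lengths of the tree subtree connecting the member
#' species. Under the default include-root convention the path to the root is
#' counted, so a monoculture scores its root-to-tip distance; with
#' `include_root = FALSE` only edges below the members' most recent common
#' ancestor count and a monoculture scores 0.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param members Nonempty character vector of tip labels.
#' @param include_root Count the path from the members' MRCA up to the root?
#' @return Branch-length sum (units of the tree's branch lengths).
#' @export
faith_pd <- function(tree, members, include_root = TRUE) {
  members <- unique(as.character(members))
  if (length(members) == 0) abort("`members` must be nonempty.")
  missing <- setdiff(members, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("Unknown species: ", paste(missing, collapse = ", ")))
  }
  tips <- match(members, tree$tip.label)
  paths <- lapply(tips, .edges_to_root, tree = tree)
  union_edges <- unique(unlist(paths))
  if (!include_root) {
    # edges shared by every member's root path lie above the MRCA
    shared <- Reduce(intersect, paths)
    union_edges <- setdiff(union_edges, shared)
  }
  sum(tree$edge.length[union_edges])
}

#' Mean pairwise distance of a species subset
#'
#' Average distance over all unordered pairs of the member species. A
#' monoculture has no pairs; `NA` is returned (an undefined marker, not 0) and
#' such rows are dropped from downstream regressions.
#'
#' @param m Distance matrix acceptable to [as_distance_matrix()] (e.g. a
#'   cophenetic matrix).
#' @param members Character vector of species labels, subset of the matrix
#'   labels.
#' @return Mean pairwise distance, or `NA_real_` for fewer than 2 members.
#' @export
mpd <- function(m, members) {
  m <- as_distance_matrix(m)
  members <- unique(as.character(members))
  missing <- setdiff(members, rownames(m))
  if (length(missing) > 0) {
    abort(paste0("Unknown species: ", paste(missing, collapse = ", ")))
  }
  if (length(members) < 2) return(NA_real_)
  sub <- m[members, members]
  mean(sub[upper.tri(sub)])
}

#' Read / write trees in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()]; reading
#' requires branch lengths since every metric here consumes them.
#'
#' @param path File path.
#' @param tree An [ape::phylo] object.
#' @return `read_tree_newick()` returns a `phylo`; `write_tree_newick()`
#'   returns `path` invisibly.
#' @export
read_tree_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) {
    abort("Tree has no branch lengths; metrics require them.")
  }
  tr
}

#' @rdname read_tree_newick
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a labelled square distance matrix from CSV
#'
#' Expects a header row and a first column both carrying the species labels.
#'
#' @param path File path.
#' @return A validated distance matrix.
#' @export
read_distance_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- as.character(d[[1]])
  as_distance_matrix(m)
}
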