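test_that("UPGMA reproduces hand-worked merge heights", {
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(0.4, 0.4))
  expect_equal(cophenetic_matrix(t2)["A", "B"], 0.8)

  t3 <- upgma_tree(three_leaf_matrix())
  cm <- cophenetic_matrix(t3)
  expect_equal(cm["A", "B"], 2)
  expect_equal(cm["A", "C"], 6)
  expect_equal(cm["B", "C"], 6)
  # (AB) merges at height 1, then C joins at height 3: C's pendant branch
  c_edge <- t3$edge.length[t3$edge[, 2] == which(t3$tip.label == "C")]
  expect_equal(c_edge, 3)
})

test_that("UPGMA trees are ultrametric for random distance matrices", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(3:9, 1)
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.1, 5)
    m <- m + t(m)
    tr <- upgma_tree(m)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  }
})

test_that("upgma_tree then cophenetic_matrix round-trips ultrametric input", {
  set.seed(7)
  for (i in 1:5) {
    src <- ape::rcoal(6, tip.label = paste0("t", 1:6))
    cm <- cophenetic_matrix(src)
    back <- cophenetic_matrix(upgma_tree(cm))
    expect_equal(back, cm[rownames(back), colnames(back)], tolerance = 1e-9)
  }
})

test_that("distance-matrix validation rejects malformed input", {
  m <- three_leaf_matrix()
  bad <- m; bad[1, 2] <- 9
  expect_error(as_distance_matrix(bad), "symmetric")
  neg <- m; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(as_distance_matrix(neg), "nonnegative")
  diag_bad <- m; diag(diag_bad) <- 1
  expect_error(as_distance_matrix(diag_bad), "Diagonal")
  expect_error(upgma_tree(matrix(0, 2, 3)), "square")
})

test_that("Faith's PD matches the hand-worked subsets of the 3-leaf tree", {
  tr <- upgma_tree(three_leaf_matrix())
  expect_equal(faith_pd(tr, c("A", "B", "C")), sum(tr$edge.length))
  expect_equal(faith_pd(tr, "C"), 3)          # root-to-tip path
  expect_equal(faith_pd(tr, c("A", "B")), 4)  # 1 + 1 + 2
  expect_equal(faith_pd(tr, "C", include_root = FALSE), 0)
  expect_error(faith_pd(tr, "Z"), "Unknown species")
  expect_error(faith_pd(tr, character(0)), "nonempty")
})

test_that("Faith's PD equals the edge-union brute force on random trees", {
  set.seed(42)
  for (i in 1:5) {
    tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
    tips <- tr$tip.label
    for (bits in 1:255) {
      members <- tips[as.logical(bitwAnd(bits, 2^(0:7)))]
      expect_equal(faith_pd(tr, members), brute_faith_pd(tr, members))
      expect_equal(faith_pd(tr, members, include_root = FALSE),
                   brute_faith_pd(tr, members, include_root = FALSE))
    }
  }
})

test_that("Faith's PD agrees with picante and is monotone in the member set", {
  skip_if_not_installed("picante")
  set.seed(5)
  tr <- ape::rcoal(8, tip.label = paste0("t", 1:8))
  for (i in 1:20) {
    members <- sample(tr$tip.label, sample(2:8, 1))
    comm <- matrix(as.integer(tr$tip.label %in% members), 1,
                   dimnames = list("c1", tr$tip.label))
    expect_equal(faith_pd(tr, members),
                 picante::pd(comm, tr, include.root = TRUE)$PD)
    sub <- sample(members, max(1, length(members) - 2))
    expect_lte(faith_pd(tr, sub), faith_pd(tr, members))
  }
})

test_that("MPD is the mean over unordered pairs, NA for monocultures", {
  m <- three_leaf_matrix()
  expect_equal(mpd(m, c("A", "B")), 2)
  expect_equal(mpd(m, c("A", "B", "C")), 14 / 3)
  expect_equal(mpd(m, c("C", "B", "A")), 14 / 3)  # order-invariant
  expect_true(is.na(mpd(m, "A")))
  expect_error(mpd(m, "Z"), "Unknown species")

  set.seed(9)
  big <- matrix(0, 7, 7, dimnames = list(letters[1:7], letters[1:7]))
  big[upper.tri(big)] <- runif(21, 0.5, 4)
  big <- big + t(big)
  members <- c("a", "c", "e", "g")
  v <- big[members, members][upper.tri(diag(4))]
  expect_gte(mpd(big, members), min(v))
  expect_lte(mpd(big, members), max(v))
})

test_that("single-species pool yields a zero-height single-leaf tree", {
  m1 <- matrix(0, 1, 1, dimnames = list("only", "only"))
  t1 <- upgma_tree(m1)
  expect_equal(t1$tip.label, "only")
  expect_equal(sum(t1$edge.length), 0)
  expect_equal(cophenetic_matrix(t1), matrix(0, 1, 1,
               dimnames = list("only", "only")))
})

test_that("newick and distance CSV readers round-trip", {
  tr <- upgma_tree(three_leaf_matrix())
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tr, path)
  back <- read_tree_newick(path)
  expect_equal(cophenetic_matrix(back), cophenetic_matrix(tr))

  csv <- withr::local_tempfile(fileext = ".csv")
  m <- three_leaf_matrix()
  readr::write_csv(tibble::as_tibble(cbind(species = rownames(m),
                                           as.data.frame(m))), csv)
  expect_equal(read_distance_csv(csv), m)
})
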