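test_that("worked reconstructions: 3-tip star and balanced 4-tip tree", {
  star <- ape::read.tree(text = "(A,B,C);")
  star$edge.length <- rep(1, 3)
  M3 <- matrix(c(0, 0, 3), 3, 1, dimnames = list(c("A", "B", "C"), NULL))
  a3 <- reconstruct_ancestral_shapes(star, M3)
  expect_equal(unname(a3$node_shapes[1, 1]), 1)
  expect_equal(a3$tree_length, 6)

  tr <- ape::read.tree(text = "((A,B),(C,D));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  M4 <- matrix(c(0, 0, 6, 6), 4, 1,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  a4 <- reconstruct_ancestral_shapes(tr, M4)
  # ape numbering: node_5 = root, node_6 = (A,B) ancestor, node_7 = (C,D)
  expect_equal(unname(a4$node_shapes[, 1]), c(3, 1, 5))
  expect_equal(a4$tree_length, 12)

  # identical tips: all nodes equal, zero length
  M0 <- matrix(2.5, 4, 2, dimnames = list(c("A", "B", "C", "D"), NULL))
  a0 <- reconstruct_ancestral_shapes(tr, M0)
  expect_true(all(abs(a0$node_shapes - 2.5) < 1e-12))
  expect_equal(a0$tree_length, 0)
})

test_that("linear-system solution matches brute-force minimization", {
  set.seed(20)
  for (r in 1:8) {
    tr <- ape::rtree(8)
    tr$edge.length <- rep(1, nrow(tr$edge))
    M <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(tr$tip.label, NULL))
    a <- reconstruct_ancestral_shapes(tr, M)
    expect_equal(a$tree_length, brute_tree_length(tr, M), tolerance = 1e-8)
  }
})

test_that("reconstruction solves the neighbour-mean conditions", {
  set.seed(21)
  tr <- ape::rtree(7)
  tr$edge.length <- rep(1, nrow(tr$edge))
  M <- matrix(rnorm(14), 7, 2, dimnames = list(tr$tip.label, NULL))
  a <- reconstruct_ancestral_shapes(tr, M)
  all_vals <- rbind(M[tr$tip.label, ], unname(a$node_shapes))
  for (nd in 8:(7 + tr$Nnode)) {
    nb <- c(tr$edge[tr$edge[, 1] == nd, 2], tr$edge[tr$edge[, 2] == nd, 1])
    expect_equal(all_vals[nd, ], colMeans(all_vals[nb, , drop = FALSE]),
                 tolerance = 1e-10)
  }
})

test_that("agreement with the Brownian-motion ML oracle at unit lengths", {
  # with unit branch lengths, squared-change parsimony equals the ML/BM
  # ancestral estimate; phytools::fastAnc is the independent route
  skip_if_not_installed("phytools")
  set.seed(22)
  tr <- ape::rtree(9)
  tr$edge.length <- rep(1, nrow(tr$edge))
  x <- rnorm(9); names(x) <- tr$tip.label
  a <- reconstruct_ancestral_shapes(tr, matrix(x, ncol = 1,
                                               dimnames = list(names(x))))
  fa <- phytools::fastAnc(tr, x)
  expect_equal(unname(a$node_shapes[, 1]), unname(as.numeric(fa)),
               tolerance = 1e-6)
})

test_that("tree length is invariant to re-rooting at internal nodes", {
  set.seed(23)
  tr <- ape::rtree(7)
  tr$edge.length <- rep(1, nrow(tr$edge))
  tru <- ape::unroot(tr)
  tru$edge.length <- rep(1, nrow(tru$edge))
  M <- matrix(rnorm(7 * 2), 7, 2, dimnames = list(tr$tip.label, NULL))
  base_len <- reconstruct_ancestral_shapes(tru, M)$tree_length
  for (nd in (7 + 1):(7 + tru$Nnode)) {
    rr <- ape::root(tru, node = nd, resolve.root = FALSE)
    rr$edge.length <- rep(1, nrow(rr$edge))
    expect_equal(reconstruct_ancestral_shapes(rr, M)$tree_length, base_len,
                 tolerance = 1e-10)
  }
})

test_that("signal test: identical tips give p = 1; strong clades give min p", {
  tr <- ape::read.tree(text = "(((A,B),C),((D,E),F));")
  tr$edge.length <- rep(1, nrow(tr$edge))
  M <- matrix(1.7, 6, 2, dimnames = list(tr$tip.label, NULL))
  st <- permutation_signal_test(tr, M, n_perm = 99, seed = 1)
  expect_equal(st$p_value, 1)

  # two clades far apart: observed length at the enumeration optimum
  set.seed(24)
  M2 <- rbind(matrix(rnorm(6, sd = 0.01), 3, 2),
              matrix(rnorm(6, sd = 0.01) + 10, 3, 2))
  rownames(M2) <- c("A", "B", "C", "D", "E", "F")
  st2 <- permutation_signal_test(tr, M2, n_perm = 199, seed = 2)
  expect_lte(st2$p_value, 0.06)  # within-clade relabelings tie approximately
  # any permutation moving a tip across clades is far longer than observed
  expect_true(all(st2$permuted_lengths >= st2$observed_length - 0.1))
})

test_that("permutation p is invariant to a common rotation of tip shapes", {
  set.seed(25)
  tr <- ape::rtree(8)
  tr$edge.length <- rep(1, nrow(tr$edge))
  M <- matrix(rnorm(8 * 4, sd = 1), 8, 4, dimnames = list(tr$tip.label, NULL))
  p1 <- permutation_signal_test(tr, M, n_perm = 99, seed = 9)$p_value
  th <- 0.77
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  M2 <- cbind(M[, 1:2] %*% R, M[, 3:4] %*% R)
  p2 <- permutation_signal_test(tr, M2, n_perm = 99, seed = 9)$p_value
  expect_equal(p1, p2)
})

test_that("homoplasy indices: bounds, optimal-tree case, star worst case", {
  set.seed(26)
  # random 6-tip data: enumerate and check min <= every topology <= star
  tr <- ape::rtree(6)
  tr$edge.length <- rep(1, nrow(tr$edge))
  M <- matrix(rnorm(12), 6, 2, dimnames = list(tr$tip.label, NULL))
  h <- homoplasy_indices(tr, M)
  expect_equal(h$n_topologies, 105)
  expect_lte(h$min_length, h$observed_length + 1e-12)
  expect_lte(h$observed_length, h$max_length + 1e-12)
  expect_gte(h$SCI, 0); expect_lte(h$SCI, 1)
  expect_gte(h$SRI, 0); expect_lte(h$SRI, 1)

  # the argmin quartet topology (found by scanning all three) has
  # SCI = SRI = 1; the worst of the three has the smallest SRI
  set.seed(28)
  M2 <- matrix(rnorm(8), 4, 2, dimnames = list(LETTERS[1:4], NULL))
  quartets <- c("((A,B),(C,D));", "((A,C),(B,D));", "((A,D),(B,C));")
  hs <- lapply(quartets, function(txt) {
    q <- ape::read.tree(text = txt)
    q$edge.length <- rep(1, nrow(q$edge))
    homoplasy_indices(q, M2)
  })
  best <- which.min(vapply(hs, function(h) h$observed_length, numeric(1)))
  expect_equal(hs[[best]]$SCI, 1, tolerance = 1e-9)
  expect_equal(hs[[best]]$SRI, 1, tolerance = 1e-9)
  expect_true(all(vapply(hs, function(h) h$min_length, numeric(1)) -
                    hs[[best]]$observed_length < 1e-9))

  # n above the cap refuses exhaustive search but allows the heuristic
  tr3 <- ape::rtree(13)
  tr3$edge.length <- rep(1, nrow(tr3$edge))
  M3 <- matrix(rnorm(26), 13, 2, dimnames = list(tr3$tip.label, NULL))
  expect_error(homoplasy_indices(tr3, M3), "limited to 11")
  h3 <- homoplasy_indices(tr3, M3, heuristic = TRUE)
  expect_false(h3$exact)
  expect_lte(h3$min_length, h3$observed_length + 1e-12)
})

test_that("every enumerated topology lies between Steiner min and star max", {
  set.seed(27)
  M <- matrix(rnorm(12), 6, 2)
  rownames(M) <- LETTERS[1:6]
  star_len <- sum(sweep(M, 2, colMeans(M))^2)
  lens <- c()
  env <- environment()
  sciurmorph:::enumerate_topologies(6, function(edges) {
    env$lens <- c(env$lens, sciurmorph:::sqcp_length(edges, 6, M))
  })
  expect_equal(length(lens), 105)
  expect_true(all(lens <= star_len + 1e-9))
  expect_true(all(lens >= min(lens) - 1e-12))
})
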