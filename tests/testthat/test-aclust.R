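test_that("collinear distances embed into one effective dimension", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  e <- embed_distances(d)
  expect_equal(as.matrix(dist(e$coords)), d, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_length(e$eigenvalues, 1)
  expect_equal(e$negative_mass, 0, tolerance = 1e-9)
})

test_that("a single point embeds to an empty coordinate vector", {
  d <- matrix(0, 1, 1, dimnames = list("a", "a"))
  e <- embed_distances(d)
  expect_equal(dim(e$coords), c(1, 0))
})

test_that("coincident points give a zero-dimensional embedding, not an error", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  e <- embed_distances(d)
  expect_equal(ncol(e$coords), 0)
})

test_that("Euclidean-realizable matrices round-trip within 1e-8", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    X <- matrix(rnorm(n * 6), n, 6)
    rownames(X) <- sprintf("p%02d", seq_len(n))
    d <- as.matrix(dist(X))
    e <- embed_distances(d)
    expect_lt(max(abs(as.matrix(dist(e$coords)) - d)), 1e-8)
  }
})

test_that("non-metric input drops negative mass and logs it", {
  d <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))  # violates triangle
  e <- embed_distances(d)
  expect_gt(e$negative_mass, 0)
})

test_that("input validation rejects asymmetric or nonzero-diagonal matrices", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(embed_distances(d), class = "gtclan_input_error")
  d2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(embed_distances(d2), class = "gtclan_input_error")
})

test_that("two leaves join at their midpoint", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t <- nnj_tree(embed_distances(d))
  expect_equal(to_newick(t), "(A:0.5,B:0.5);")
})

test_that("nearest pairs join first on collinear points", {
  x <- c(a = 0, b = 1, c = 10, d = 11)
  d <- as.matrix(dist(x))
  t <- nnj_tree(embed_distances(d))
  nwk <- to_newick(t)
  expect_match(nwk, "\\(\\(a:[^,]+,b:[^)]+\\):[^,]+,\\(c:[^,]+,d:[^)]+\\):")
})

test_that("distance ties break toward the lowest id-sorted pair", {
  # equilateral triangle: all pairs tie; (a, b) must join first
  d <- matrix(1, 3, 3, dimnames = list(c("b", "c", "a"), c("b", "c", "a")))
  diag(d) <- 0
  t <- nnj_tree(embed_distances(d))
  expect_match(to_newick(t), "^\\(\\(a:")
})

test_that("trees preserve leaves and have nonnegative branch lengths", {
  set.seed(41)
  X <- matrix(rnorm(20 * 4), 20, 4)
  rownames(X) <- sprintf("s%02d", 1:20)
  d <- as.matrix(dist(X))
  t <- aclust(d)
  collect_lengths <- function(node) {
    if (!is.null(node$leaf)) return(numeric(0))
    c(node$lengths, collect_lengths(node$children[[1]]),
      collect_lengths(node$children[[2]]))
  }
  expect_setequal(gtclan:::.tree_leaves(t$root), rownames(X))
  expect_true(all(collect_lengths(t$root) >= 0))
})

test_that("refinement leaves well-separated clades intact and is idempotent", {
  g <- generate_hierarchical_points(n_clades = 2, points_per_clade = 4,
                                    separation = 10, seed = 3)
  t0 <- nnj_tree(embed_distances(g$dist))
  t1 <- recursive_refine(t0, g$dist)
  expect_equal(to_newick(t1), to_newick(recursive_refine(t1, g$dist)))
  # small subtrees (below min_leaves) are kept as built
  topo <- function(t) gsub(":[0-9.eE+-]+", "", to_newick(t))
  t2 <- recursive_refine(t0, g$dist, min_leaves = 100)
  expect_equal(topo(t2), topo(t0))
  expect_error(recursive_refine(t0, g$dist[1:5, 1:5]),
               class = "gtclan_input_error")
})

test_that("planted topologies are recovered exactly (RF = 0)", {
  for (seed in 1:2) {
    g <- generate_hierarchical_points(n_clades = 3, points_per_clade = 6,
                                      separation = 10, seed = seed)
    t <- aclust(g$dist)
    rf <- phangorn::RF.dist(ape::read.tree(text = to_newick(t)),
                            ape::read.tree(text = g$newick))
    expect_equal(rf, 0)
  }
})

test_that("newick output round-trips through a standard parser", {
  set.seed(51)
  X <- matrix(rnorm(8 * 3), 8, 3)
  rownames(X) <- sprintf("s%d", 1:8)
  d <- as.matrix(dist(X))
  t <- aclust(d)
  ph <- ape::read.tree(text = to_newick(t))
  expect_setequal(ph$tip.label, rownames(X))
  expect_equal(ape::Ntip(ph), 8)
  expect_true(ape::is.binary(ph))
  # reserved characters are quoted
  d2 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("x y", "b"), c("x y", "b")))
  nwk <- to_newick(nnj_tree(embed_distances(d2)))
  expect_match(nwk, "'x y'", fixed = TRUE)
  tips <- gsub("^'|'$", "", ape::read.tree(text = nwk)$tip.label)
  expect_equal(sort(tips), sort(c("x y", "b")))
})
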