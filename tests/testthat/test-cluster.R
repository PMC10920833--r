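test_that("redundancy reduction collapses near-duplicates only", {
  base <- paste(rep("MKTAYIAKQR", 10), collapse = "")
  near <- paste0(substr(base, 1, 97), "AAA")     # ~97% identical
  far <- paste(rep("WLDNGHPCEV", 10), collapse = "")
  # exact duplicates at 0.99 -> one representative
  red <- reduce_redundancy(c(a = base, b = base, c = base), 0.99)
  expect_length(red$representatives, 1)
  expect_true(all(red$membership == names(red$representatives)))
  # A ~ B at 97%, C distant, threshold 0.95 -> two representatives
  red2 <- reduce_redundancy(c(A = base, B = near, C = far), 0.95)
  expect_length(red2$representatives, 2)
  expect_equal(red2$membership[["B"]], red2$membership[["A"]])
  # all below threshold -> everyone their own representative
  red3 <- reduce_redundancy(c(A = base, C = far), 0.999)
  expect_length(red3$representatives, 2)
  expect_error(reduce_redundancy(c(a = base), 0.3),
               class = "gtclan_input_error")
})

test_that("SSN edges are strictly above threshold; isolated nodes survive", {
  m <- matrix(c(0, 110, 50,
                110, 0, 200,
                50, 200, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- build_ssn(m, threshold = 110)
  expect_equal(igraph::ecount(g), 1)          # 110 is NOT above 110
  expect_equal(igraph::vcount(g), 3)
  g0 <- build_ssn(m, threshold = 0)
  expect_equal(igraph::components(g0)$no, 1)
  g_hi <- build_ssn(m, threshold = 1000)
  expect_equal(igraph::ecount(g_hi), 0)
  expect_equal(igraph::components(g_hi)$no, 3)
})

test_that("edge-list SSNs symmetrize by maximum and validate nodes", {
  edges <- data.frame(query = c("a", "b", "a"),
                      subject = c("b", "a", "a"),
                      bits = c(120, 90, 500))
  g <- build_ssn(edges, threshold = 100, nodes = c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$bits, 120)        # max of the two directions
  expect_equal(igraph::vcount(g), 3)          # c isolated, no self-edges
  expect_error(build_ssn(edges, 100, nodes = c("a", "c")),
               class = "gtclan_input_error")
  expect_error(build_ssn(edges, 100), class = "gtclan_input_error")
})

test_that("clusters are size-ordered components, ties by smallest id", {
  m <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  m["a", "b"] <- m["b", "a"] <- 200
  m["c", "d"] <- m["d", "c"] <- 200
  cs <- ssn_components(build_ssn(m, 110))
  expect_equal(lengths(cs$clusters), c(C1 = 2L, C2 = 2L, C3 = 1L))
  expect_equal(cs$clusters$C1, c("a", "b"))   # tie broken by smallest id
  expect_equal(cs$clusters$C2, c("c", "d"))
  expect_equal(unname(cs$membership["e"]), "C3")
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    ids <- sprintf("n%02d", seq_len(n))
    n_edges <- sample(0:(2 * n), 1)
    ij <- cbind(sample(n, n_edges, replace = TRUE),
                sample(n, n_edges, replace = TRUE))
    ij <- ij[ij[, 1] != ij[, 2], , drop = FALSE]
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[ij] <- 200; m[ij[, 2:1, drop = FALSE]] <- 200
    cs <- ssn_components(build_ssn(m, 110))
    oracle <- oracle_components(n, ij)
    # same partition (component counts and co-membership)
    expect_equal(length(cs$clusters), length(unique(oracle)))
    expect_equal(adjusted_rand_index(cs$membership[ids], oracle), 1)
  }
})

test_that("supercluster network keeps directionality and validates hits", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m["a", "b"] <- m["b", "a"] <- 200
  cs <- ssn_components(build_ssn(m, 110))   # C1={a,b}, C2={c}, C3={d}
  hits <- data.frame(query = c("C1", "C2", "C2", "C3"),
                     target = c("C2", "C1", "C3", "C2"),
                     score = c(170, 150, 170, 170))
  net <- build_supercluster_network(cs, hits, threshold = 160)
  expect_true(igraph::is_directed(net))
  expect_equal(igraph::ecount(net), 3)      # the 150 edge is dropped
  expect_equal(sort(igraph::V(net)$name), c("C1", "C2", "C3"))
  expect_error(build_supercluster_network(cs, data.frame(
    query = "C9", target = "C1", score = 500), 160),
    class = "gtclan_input_error")
  # all scores at/below threshold -> empty network
  net0 <- build_supercluster_network(cs, within(hits, score <- 160), 160)
  expect_equal(igraph::ecount(net0), 0)
})

test_that("family assignment follows the size rule", {
  mk_net <- function(sizes, edges) {
    cl <- paste0("C", seq_along(sizes))
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = cl))
    igraph::V(g)$members <- sizes
    g
  }
  # components {C1,C2} = 200+160, {C3,C4} = 100+40, {C5} = 10 isolated
  net <- mk_net(c(200, 160, 100, 40, 10),
                data.frame(from = c("C1", "C3"), to = c("C2", "C4"),
                           score = c(200, 200)))
  fam <- assign_families(net, min_family_size = 150)
  expect_equal(unname(fam$cluster_family[c("C1", "C2")]), c("F1", "F1"))
  expect_equal(unname(fam$cluster_family["C3"]), "unclassified")
  expect_equal(unname(fam$cluster_family["C5"]), "singleton")
  expect_equal(unname(fam$family_sizes["F1"]), 360)
  # no edges at all -> every small cluster is a singleton
  net0 <- mk_net(c(10, 10), data.frame(from = character(),
                                       to = character(),
                                       score = numeric()))
  fam0 <- assign_families(net0, 150)
  expect_true(all(fam0$cluster_family == "singleton"))
  # strict ">": a component of exactly min_family_size is not a family
  net1 <- mk_net(c(75, 75), data.frame(from = "C1", to = "C2", score = 999))
  expect_length(assign_families(net1, 150)$families, 0)
  net2 <- mk_net(c(76, 75), data.frame(from = "C1", to = "C2", score = 999))
  expect_length(assign_families(net2, 150)$families, 1)
})

test_that("requiring both directions prunes one-way support", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("C1", "C2", "C2"), to = c("C2", "C1", "C3"),
               score = c(200, 180, 200)),
    directed = TRUE, vertices = data.frame(name = c("C1", "C2", "C3")))
  igraph::V(g)$members <- c(100, 100, 100)
  one_way <- assign_families(g, 50, require_both_directions = FALSE)
  expect_equal(length(one_way$families), 1)   # all three connect
  both <- assign_families(g, 50, require_both_directions = TRUE)
  expect_equal(unname(both$cluster_family[["C3"]]), "singleton")
})

test_that("raising thresholds only refines, never merges", {
  bits <- fix_all_vs_all()$bits
  cs_lo <- ssn_components(build_ssn(bits, 110))
  cs_hi <- ssn_components(build_ssn(bits, 230))
  # every high-threshold cluster is inside one low-threshold cluster
  for (cl in cs_hi$clusters) {
    expect_equal(length(unique(cs_lo$membership[cl])), 1)
  }
  expect_gte(length(cs_hi$clusters), length(cs_lo$clusters))
})

test_that("the two-stage pipeline recovers planted families exactly", {
  g <- fix_proteins()
  res <- fix_two_stage()
  expect_equal(adjusted_rand_index(res$sequence_family[names(g$labels)],
                                   g$labels), 1)
  r <- res$report
  expect_equal(r$n_input, length(g$seqs))
  expect_equal(r$n_clusters, length(res$clusters$clusters))
  # every sequence in exactly one cluster; every cluster classified once
  expect_setequal(names(res$clusters$membership), names(g$seqs))
  expect_true(all(res$families$cluster_family %in%
                  c(names(res$families$families), "singleton", "unclassified")))
})

test_that("the pipeline is deterministic and order-invariant", {
  g <- fix_proteins()
  seqs <- g$seqs
  cfg <- two_stage_config(internal = TRUE, min_family_size = 10)
  res1 <- fix_two_stage()
  set.seed(99)
  res2 <- run_two_stage(seqs[sample(length(seqs))], cfg)
  f1 <- res1$sequence_family[sort(names(seqs))]
  f2 <- res2$sequence_family[sort(names(seqs))]
  expect_equal(adjusted_rand_index(f1, f2), 1)
})

test_that("single-sequence input degenerates gracefully", {
  res <- run_two_stage(c(only = strrep("MKTAYIAKQR", 10)),
                       two_stage_config(internal = TRUE))
  expect_equal(res$report$n_clusters, 1)
  expect_equal(igraph::ecount(res$supernet), 0)
  expect_match(unname(res$sequence_family["only"]), "singleton")
})
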