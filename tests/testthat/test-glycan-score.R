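# Expected values below follow the published scoring rule: identity at
# both -1 and +1 scores 2; each further sequential match (+2 before -2,
# then +3, ...) adds 1; the comparison stops at the first mismatch,
# missing subsite, or re-use of a backbone position.

test_that("minimum non-zero score is 2: ends identical, middles differ", {
  a <- backbone_string(c("P:1D:3U", "P:1U:2U", "F:1D:2U", "P:1U:4D", "P:1U:3U"))
  b <- backbone_string(c("P:1D:3U", "F:1D:2U", "P:1U:2U", "P:1D:4D", "P:1U:3U"))
  expect_equal(similarity_score(a, b), 2)
})

test_that("mismatch at either end position gives 0 (never 1)", {
  a <- backbone_string(c("P:1D:3U", "P:1U:2U", "P:1U:3U"))
  b_plus <- backbone_string(c("P:1D:3U", "P:1U:2U", "P:1D:3U"))
  b_minus <- backbone_string(c("P:1U:3U", "P:1U:2U", "P:1U:3U"))
  expect_equal(similarity_score(a, b_plus), 0)
  expect_equal(similarity_score(a, b_minus), 0)
})

test_that("identical at -1,+1,+2,-2,+3 with -3 mismatch scores 5", {
  a <- backbone_string(c("P:1D:3U", "P:1U:2U", "F:1D:2U",
                         "P:1D:4D", "P:1U:4D", "P:1U:2U", "P:1U:3U"))
  b <- backbone_string(c("P:1D:3U", "P:1U:2U", "P:1D:2U",
                         "F:1U:4D", "P:1U:4D", "P:1U:2U", "P:1U:3U"))
  # shared: -1, +1, +2, -2, +3; -3 (position 3) differs
  expect_equal(similarity_score(a, b), 5)
})

test_that("a 7-residue string against itself saturates at 7", {
  a <- backbone_string(c("P:1D:2U", "P:1U:2U", "F:1D:2U",
                         "P:1D:4D", "P:1U:4D", "P:1D:3U", "P:1U:3U"))
  expect_equal(similarity_score(a, a), 7)
})

test_that("self-scores equal the usable position count for n = 2..7", {
  for (n in 2:7) {
    tokens <- sprintf("P:1D:%d%s", rep(2:4, 3)[seq_len(n)],
                      rep(c("U", "D", "N"), each = 3)[seq_len(n)])
    bs <- backbone_string(tokens)
    expect_equal(similarity_score(bs, bs), n)
  }
})

test_that("single-residue backbones are rejected", {
  one <- backbone_string("P:1D:3U")
  two <- backbone_string(c("P:1D:3U", "P:1U:3U"))
  expect_error(similarity_score(one, two), class = "gtclan_unsupported_error")
  expect_error(similarity_score(two, one), class = "gtclan_unsupported_error")
})

test_that("score matches the subsite-enumeration oracle exhaustively (n <= 5, 3 tokens)", {
  # every token string of length 2..5 over a 3-token alphabet
  all_strings <- list()
  for (n in 2:5) {
    grid <- do.call(expand.grid, rep(list(1:3), n))
    all_strings <- c(all_strings, lapply(seq_len(nrow(grid)), function(r)
      as.integer(grid[r, ])))
  }
  objs <- lapply(all_strings, bs_from_letters)
  toks <- lapply(all_strings, function(i) abc_tokens[i])
  set.seed(7)
  # exhaustive within each length pair would be ~130k comparisons; cover
  # every string at least once against random partners plus all pairs of
  # the length-2 and length-3 strings (truly exhaustive at small n)
  small <- which(vapply(all_strings, length, 1L) <= 3)
  for (i in small) for (j in small) {
    expect_identical(similarity_score(objs[[i]], objs[[j]]),
                     oracle_similarity(toks[[i]], toks[[j]]))
  }
  idx <- seq_along(objs)
  partners <- sample(idx, length(idx), replace = TRUE)
  for (k in idx) {
    expect_identical(similarity_score(objs[[k]], objs[[partners[k]]]),
                     oracle_similarity(toks[[k]], toks[[partners[k]]]))
  }
})

test_that("score is symmetric and within its stated range", {
  set.seed(11)
  for (rep in 1:200) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    a <- bs_from_letters(sample(1:3, na, replace = TRUE))
    b <- bs_from_letters(sample(1:3, nb, replace = TRUE))
    s <- similarity_score(a, b)
    expect_identical(s, similarity_score(b, a))
    expect_true(s == 0 || (s >= 2 && s <= min(na, nb)))
  }
})

test_that("score matrix is symmetric with self-scores on the diagonal", {
  strings <- list(
    g1 = backbone_string(c("P:1D:3U", "P:1U:2U", "P:1U:3U")),
    g2 = backbone_string(c("P:1D:3U", "F:1D:2U", "P:1U:3U")),
    g3 = backbone_string(c("P:1U:3U", "P:1U:2U", "P:1D:4D", "P:1U:3U")))
  m <- glycan_score_matrix(strings)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(3L, 3L, 4L))
  expect_equal(m["g1", "g2"], 2L)
  # identical strings everywhere -> constant matrix of the self-score
  same <- glycan_score_matrix(list(a = strings$g1, b = strings$g1,
                                   c = strings$g1))
  expect_true(all(same == 3L))
})

test_that("score-matrix errors name the offending pair", {
  strings <- list(ok = backbone_string(c("P:1D:3U", "P:1U:3U")),
                  bad = backbone_string("P:1D:3U"))
  err <- expect_error(glycan_score_matrix(strings),
                      class = "gtclan_unsupported_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("mechanism inference follows the axial/equatorial rule", {
  mk <- function(anomer, config) parse_repeat_unit(
    sprintf("→3)-β-D-Galp-(1→4)-%s-%s-Glcp-(1→", anomer, config))
  expect_equal(infer_mechanism(mk("α", "D"))$value, "retaining")
  expect_equal(infer_mechanism(mk("α", "D"))$bond_geometry, "axial")
  expect_equal(infer_mechanism(mk("β", "D"))$value, "inverting")
  expect_equal(infer_mechanism(mk("β", "L"))$value, "retaining")
  expect_equal(infer_mechanism(mk("α", "L"))$value, "inverting")
  # open-chain reducing end: no anomeric configuration, no mechanism
  open_end <- parse_repeat_unit("→2)-α-D-Glcp-(1→3)-Gro-(1→")
  expect_error(infer_mechanism(open_end), class = "gtclan_mechanism_error")
})

test_that("mirror property: flipping D/L flips geometry and mechanism", {
  d_unit <- parse_repeat_unit("→3)-β-D-Galp-(1→4)-α-D-Glcp-(1→")
  l_unit <- parse_repeat_unit("→3)-β-L-Galp-(1→4)-α-L-Glcp-(1→")
  md <- infer_mechanism(d_unit); ml <- infer_mechanism(l_unit)
  expect_false(md$bond_geometry == ml$bond_geometry)
  expect_false(md$value == ml$value)
})

test_that("intra/inter summary stratifies correctly", {
  s_a <- backbone_string(c("P:1D:3U", "P:1U:2U", "P:1U:3U"))
  s_b <- backbone_string(c("P:1U:4D", "F:1D:2U", "P:1D:4D"))
  m <- glycan_score_matrix(list(a1 = s_a, a2 = s_a, b1 = s_b, b2 = s_b))
  s <- intra_inter_summary(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(s$intra_mean, 3)
  expect_equal(s$inter_mean, 0)
  expect_equal(s$n_intra, 2)
  expect_equal(s$n_inter, 4)
  # single-member family reports NA, not zero
  s2 <- intra_inter_summary(m, c(a1 = "A", a2 = "A", b1 = "B", b2 = "C"))
  expect_true(is.na(s2$per_family$intra_mean[s2$per_family$family == "B"]))
  # all labels identical -> empty inter stratum, flagged
  s3 <- intra_inter_summary(m, setNames(rep("A", 4), rownames(m)))
  expect_true(s3$single_stratum)
  expect_true(is.na(s3$inter_mean))
  # identical glycans everywhere -> intra mean equals inter mean
  m4 <- glycan_score_matrix(list(x = s_a, y = s_a, z = s_a, w = s_a))
  s4 <- intra_inter_summary(m4, c(x = "A", y = "A", z = "B", w = "B"))
  expect_equal(s4$intra_mean, s4$inter_mean)
})
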