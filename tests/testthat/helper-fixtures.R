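# Shared fixtures and independent reference implementations ("oracles").
# Expensive fixtures are memoised so the suite computes them once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# canonical worked glycan: one D-galactopyranose and two D-glucopyranoses,
# intramolecular beta-1,3 and alpha-1,4 bonds, polymerase bond alpha-1,3
fig_trisaccharide <- "→3)-β-D-Galp-(1→3)-α-D-Glcp-(1→4)-α-D-Glcp-(1→"

# a planted 3-family protein dataset at the stated world
# (3 x 20, within-identity 0.45, independent ancestors)
fix_proteins <- function() memo("proteins",
  generate_protein_families(n_families = 3, seqs_per_family = 20,
                            ancestor_length = 300, within_identity = 0.45,
                            seed = 42))

fix_all_vs_all <- function() memo("ava", all_vs_all(fix_proteins()$seqs))

fix_two_stage <- function() memo("two_stage",
  run_two_stage(fix_proteins()$seqs,
                two_stage_config(internal = TRUE, min_family_size = 10)))

# ---------------------------------------------------------------------------
# Oracle 1: backbone similarity by direct subsite enumeration.  Written
# independently of similarity_score(): it materialises the full test
# schedule of subsite pairs up front, maps subsites to residue indices,
# and walks the schedule with explicit used-index sets.
oracle_similarity <- function(ta, tb) {
  na <- length(ta); nb <- length(tb)
  stopifnot(na >= 2, nb >= 2)
  minus_idx <- function(n, k) if (k >= 1 && k <= n) k else NA_integer_
  plus_idx <- function(n, k) if (k >= 1 && k <= n) n - k + 1L else NA_integer_
  if (!identical(ta[minus_idx(na, 1)], tb[minus_idx(nb, 1)])) return(0L)
  if (!identical(ta[plus_idx(na, 1)], tb[plus_idx(nb, 1)])) return(0L)
  used_a <- c(minus_idx(na, 1), plus_idx(na, 1))
  used_b <- c(minus_idx(nb, 1), plus_idx(nb, 1))
  score <- 2L
  schedule <- list()
  for (k in 2:max(na, nb)) {
    schedule <- c(schedule, list(c("plus", k)), list(c("minus", k)))
  }
  for (s in schedule) {
    k <- as.integer(s[2])
    ia <- if (s[1] == "plus") plus_idx(na, k) else minus_idx(na, k)
    ib <- if (s[1] == "plus") plus_idx(nb, k) else minus_idx(nb, k)
    if (is.na(ia) || is.na(ib)) return(score)
    if (ia %in% used_a || ib %in% used_b) return(score)
    if (!identical(ta[ia], tb[ib])) return(score)
    score <- score + 1L
    used_a <- c(used_a, ia)
    used_b <- c(used_b, ib)
  }
  score
}

# token strings over a small alphabet, as backbone_string objects
abc_tokens <- c("P:1D:3U", "P:1U:4D", "F:1D:2U")
bs_from_letters <- function(letters_idx)
  backbone_string(abc_tokens[letters_idx])

# ---------------------------------------------------------------------------
# Oracle 2: Smith-Waterman by cubic dynamic programming with explicit
# gap-length loops (no affine-state machinery shared with the package).
oracle_sw <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      best <- H[i, j] + submat[ca[i], cb[j]]
      for (L in seq_len(j))
        best <- max(best, H[i + 1, j + 1 - L] - gap_open - L * gap_extend)
      for (L in seq_len(i))
        best <- max(best, H[i + 1 - L, j + 1] - gap_open - L * gap_extend)
      H[i + 1, j + 1] <- max(0, best)
    }
  }
  max(H)
}

# ---------------------------------------------------------------------------
# Oracle 3: connected components by union-find.
oracle_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (nrow(edges) > 0) for (e in seq_len(nrow(edges))) {
    ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, 1L)
}
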