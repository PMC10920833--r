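# The backbone similarity score for oligosaccharide repeat units, plus
# reaction-stereochemistry inference and the intra/inter-family summary.

#' Backbone similarity score between two repeat units
#'
#' Scores the structural similarity of two glycan repeat-unit backbones
#' around the polymerase bond.  The score is 0 unless the tokens at both
#' the -1 subsite (reducing end, donor side) and the +1 subsite
#' (non-reducing end, acceptor side) are identical, which yields the
#' minimum non-zero score of 2.  The comparison then extends outwards in
#' rounds k = 2, 3, ..., testing subsite +k before -k; each identical
#' token pair adds 1 and marks the underlying backbone residues of both
#' strings as used.  The entire comparison terminates at the first
#' non-identity, at a missing subsite, or when a test would re-use a
#' backbone residue already counted (which happens when the + and - walks
#' meet in the middle of a string).  The score is symmetric and lies in
#' \{0\} or \{2, ..., min(n_a, n_b)\}.
#'
#' @param a,b `backbone_string` objects with at least 2 backbone residues.
#' @return integer score.
#' @examples
#' x <- backbone_string(c("P:1D:3U", "P:1D:4D", "P:1U:3U"))
#' similarity_score(x, x)   # self-score 3
#' @export
similarity_score <- function(a, b) {
  stopifnot(inherits(a, "backbone_string"), inherits(b, "backbone_string"))
  na <- length(a$tokens); nb <- length(b$tokens)
  if (na < 2 || nb < 2)
    gt_stop("unsupported",
            sprintf("backbone similarity requires >= 2 backbone residues (got %d and %d)",
                    na, nb))
  ta <- a$tokens; tb <- b$tokens
  if (ta[1] != tb[1] || ta[na] != tb[nb]) return(0L)
  used_a <- logical(na); used_b <- logical(nb)
  used_a[c(1L, na)] <- TRUE
  used_b[c(1L, nb)] <- TRUE
  score <- 2L
  k <- 2L
  repeat {
    # +k (acceptor direction) first, then -k (donor direction)
    for (side in c("plus", "minus")) {
      if (side == "plus") {
        ia <- na - k + 1L; ib <- nb - k + 1L
      } else {
        ia <- k; ib <- k
      }
      if (ia < 1L || ib < 1L || ia > na || ib > nb) return(score)
      if (used_a[ia] || used_b[ib]) return(score)
      if (ta[ia] != tb[ib]) return(score)
      score <- score + 1L
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
    k <- k + 1L
  }
}

#' Pairwise backbone similarity matrix
#'
#' @param strings named list of `backbone_string` objects (names become
#'   the row/column ids).
#' @return symmetric integer matrix; the diagonal holds self-scores (the
#'   number of distinct backbone positions usable before the re-use rule
#'   triggers, at most the backbone length).
#' @export
glycan_score_matrix <- function(strings) {
  n <- length(strings)
  if (n == 0) gt_stop("input", "no backbone strings supplied")
  ids <- names(strings) %||% as.character(seq_len(n))
  if (anyDuplicated(ids)) gt_stop("input", "duplicate glycan ids")
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- tryCatch(similarity_score(strings[[i]], strings[[j]]),
                    gtclan_error = function(e)
                      gt_stop("unsupported",
                              sprintf("scoring pair (%s, %s): %s",
                                      ids[i], ids[j], conditionMessage(e))))
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Infer the polymerase reaction mechanism from the repeat unit
#'
#' Repeat units are attached to the Und-PP carrier through an axial bond
#' (alpha for D-sugars, beta for L-sugars).  If the new bond formed by the
#' polymerase is also axial the anomeric configuration is preserved and
#' the mechanism is retaining; an equatorial product bond means the
#' mechanism is inverting.
#'
#' @param unit a [parse_repeat_unit()] result.
#' @param table a [default_stereo_table()] (unused by the rule itself,
#'   accepted for interface symmetry with [translate_repeat_unit()]).
#' @return list with elements `value` ("retaining"/"inverting") and
#'   `bond_geometry` ("axial"/"equatorial").
#' @export
infer_mechanism <- function(unit, table = default_stereo_table()) {
  stopifnot(inherits(unit, "repeat_unit"))
  r <- unit$residues[[unit$und_pp_residue]]
  if (r$ring_form == "open" || r$anomeric == "none" || r$config == "none")
    gt_stop("mechanism",
            "reducing-end residue has no anomeric configuration; mechanism undetermined")
  geom <- bond_geometry_of(r$config, unit$polymerase_bond$anomeric)
  list(value = if (geom == "axial") "retaining" else "inverting",
       bond_geometry = geom)
}

#' Intra- versus inter-family summary of a glycan score matrix
#'
#' Stratifies the off-diagonal entries of a backbone similarity matrix by
#' whether the pair belongs to the same family, reporting the mean score
#' per family (NA for single-member families), the global intra mean, the
#' inter-family mean and the pair counts in each stratum.
#'
#' @param m symmetric score matrix with ids on the dimnames.
#' @param labels family label per row of `m` (recycled by name when
#'   `labels` is named).
#' @return list with `per_family` (data.frame: family, n_members, n_pairs,
#'   intra_mean), `intra_mean`, `inter_mean`, `n_intra`, `n_inter` and
#'   `single_stratum` (TRUE when all labels are identical so the inter
#'   stratum is empty).
#' @export
intra_inter_summary <- function(m, labels) {
  check_square_named(m, "score matrix")
  n <- nrow(m)
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  if (length(labels) != n)
    gt_stop("input", "labels do not align with the score matrix rows")
  labels <- as.character(labels)
  same <- outer(labels, labels, "==")
  off <- !diag(TRUE, n)
  fams <- sort(unique(labels))
  per <- lapply(fams, function(f) {
    idx <- labels == f
    vals <- m[idx, idx, drop = FALSE][off[idx, idx, drop = FALSE]]
    data.frame(family = f, n_members = sum(idx),
               n_pairs = length(vals) / 2,
               intra_mean = if (length(vals)) mean(vals) else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  intra_vals <- m[same & off]
  inter_vals <- m[!same & off]
  list(per_family = per,
       intra_mean = if (length(intra_vals)) mean(intra_vals) else NA_real_,
       inter_mean = if (length(inter_vals)) mean(inter_vals) else NA_real_,
       n_intra = length(intra_vals) / 2,
       n_inter = length(inter_vals) / 2,
       single_stratum = length(fams) < 2)
}
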