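# Pairwise local alignment, bit scores, and the Scoredist-variant distance
# feeding both the sequence similarity network and the tree algorithm.

.aa20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

# BLAST amino-acid background frequencies (Robinson & Robinson), used for
# the expected-random-score term of the Scoredist variant.
.aa_background <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Default substitution matrix
#'
#' BLOSUM62 (from Biostrings) restricted to the 20 standard residues plus
#' X, together with the Karlin-Altschul parameters of the standard gapped
#' regime (gap open 11 / extend 1): lambda = 0.267 nats per score unit and
#' K = 0.041, and the BLAST background residue frequencies.  These
#' reproduce BLAST-like bit-score scales so that network thresholds chosen
#' for imported BLAST data keep their meaning for internally computed
#' scores.
#'
#' @return list with elements `matrix`, `name`, `lambda`, `K`,
#'   `background`.
#' @export
default_submatrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  keep <- c(.aa20, "X")
  m <- e$BLOSUM62[keep, keep]
  list(matrix = m, name = "BLOSUM62", lambda = 0.267, K = 0.041,
       background = .aa_background)
}

# expected score per aligned position under background frequencies
# (negative for any sensible matrix); X is ignored by the expectation
expected_score_per_position <- function(m) {
  bg <- m$background[.aa20]
  as.numeric(t(bg) %*% m$matrix[.aa20, .aa20] %*% bg)
}

.check_seq <- function(s, id = "sequence") {
  if (!nzchar(s)) gt_stop("input", sprintf("%s is empty", id))
  ch <- strsplit(s, "")[[1]]
  bad <- !ch %in% c(.aa20, "X")
  if (any(bad))
    gt_stop("input", sprintf("%s: illegal residue '%s' at position %d",
                             id, ch[which(bad)[1]], which(bad)[1]))
  ch
}

#' Smith-Waterman local alignment
#'
#' Optimal affine-gap local alignment of two protein sequences.  A gap of
#' length L costs `gap_open + L * gap_extend` (BLAST convention).  An
#' empty alignment (score 0) is returned when no positive-scoring path
#' exists.
#'
#' @param a,b amino-acid strings (20-letter alphabet plus X).
#' @param m substitution matrix bundle from [default_submatrix()].
#' @param gap_open,gap_extend positive gap penalties,
#'   `gap_open >= gap_extend`.
#' @return an `alignment_result`: `raw_score`, `bit_score`,
#'   `identity_fraction` (exact matches over aligned residue pairs),
#'   `alignment_length` (aligned pairs plus gap positions), and the
#'   aligned position pairs.
#' @export
smith_waterman <- function(a, b, m = default_submatrix(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  ca <- .check_seq(a, "sequence a")
  cb <- .check_seq(b, "sequence b")
  S <- m$matrix[ca, cb, drop = FALSE]
  res <- local_align_cpp(S, gap_open, gap_extend)
  pa <- res$pairs_a
  pb <- res$pairs_b
  npairs <- length(pa)
  if (npairs > 0) {
    ident <- mean(ca[pa] == cb[pb])
    span_a <- pa[npairs] - pa[1] + 1L
    span_b <- pb[npairs] - pb[1] + 1L
    alen <- span_a + span_b - npairs
  } else {
    ident <- 0
    alen <- 0L
  }
  structure(list(raw_score = res$score,
                 bit_score = bit_score(res$score, m),
                 identity_fraction = ident,
                 alignment_length = alen,
                 pairs = cbind(a = pa, b = pb)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> raw %g, %.1f bits, %.1f%% identity over %d columns\n",
              x$raw_score, x$bit_score, 100 * x$identity_fraction,
              x$alignment_length))
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' `(lambda * raw - ln K) / ln 2` with the Karlin-Altschul parameters
#' carried on the substitution-matrix bundle.
#'
#' @param raw raw alignment score.
#' @param m substitution matrix bundle.
#' @return bit score (numeric).
#' @export
bit_score <- function(raw, m = default_submatrix()) {
  if (is.null(m$lambda) || is.null(m$K))
    gt_stop("config", "substitution matrix bundle lacks lambda/K")
  (m$lambda * raw - log(m$K)) / log(2)
}

#' Scoredist-variant evolutionary distance
#'
#' Logarithmic transform of the normalized alignment score into an
#' evolutionary distance, normalized to the shorter of the two sequence
#' lengths (not to the alignment length).  With sigma_r the expected
#' random score (`min(len_a, len_b)` times the matrix's expected
#' per-position score under background frequencies), the normalized score
#' is `sigma_n = raw - sigma_r`, its upper bound
#' `sigma_u = (self_a + self_b)/2 - sigma_r`, and the distance
#' `-100 * ln(sigma_n / sigma_u)`, capped at `d_max` when `sigma_n <= 0`
#' or the ratio underflows.  Identical sequences get distance 0.
#'
#' @param raw raw local alignment score of the pair.
#' @param self_a,self_b raw self-alignment scores.
#' @param len_a,len_b sequence lengths.
#' @param m substitution matrix bundle.
#' @param d_max saturation cap (default 300).
#' @param expected_per_pos override for the expected per-position random
#'   score (defaults to the matrix/background value).
#' @return nonnegative distance.
#' @export
scoredist_variant <- function(raw, self_a, self_b, len_a, len_b,
                              m = default_submatrix(), d_max = 300,
                              expected_per_pos = NULL) {
  eps <- expected_per_pos %||% expected_score_per_position(m)
  sigma_r <- min(len_a, len_b) * eps
  sigma_n <- raw - sigma_r
  sigma_u <- (self_a + self_b) / 2 - sigma_r
  if (sigma_u <= 0)
    gt_stop("degenerate", "self-scores do not exceed the expected random score")
  if (sigma_n <= 0) return(d_max)
  d <- -100 * log(sigma_n / sigma_u)
  if (!is.finite(d) || d > d_max) return(d_max)
  max(d, 0)
}

#' All-vs-all bit-score and distance matrices
#'
#' Runs [smith_waterman()] on every sequence pair and returns the
#' symmetric bit-score matrix (diagonal = self bit scores) and the
#' Scoredist-variant [scoredist_variant()] distance matrix (zero
#' diagonal).
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param m substitution matrix bundle.
#' @param gap_open,gap_extend gap penalties.
#' @param d_max distance saturation cap.
#' @return list with `bits` and `dist` matrices.
#' @export
all_vs_all <- function(seqs, m = default_submatrix(),
                       gap_open = 11, gap_extend = 1, d_max = 300) {
  n <- length(seqs)
  if (n < 2) gt_stop("input", "need at least 2 sequences")
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    gt_stop("input", "sequences must carry unique non-empty ids")
  lens <- nchar(seqs)
  selfs <- vapply(seqs, function(s)
    smith_waterman(s, s, m, gap_open, gap_extend)$raw_score, 0.0)
  eps <- expected_score_per_position(m)
  bits <- matrix(0, n, n, dimnames = list(ids, ids))
  dst <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(bits) <- bit_score(selfs, m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- smith_waterman(seqs[[i]], seqs[[j]], m, gap_open, gap_extend)
      bits[i, j] <- bits[j, i] <- aln$bit_score
      d <- scoredist_variant(aln$raw_score, selfs[i], selfs[j],
                             lens[i], lens[j], m, d_max, eps)
      dst[i, j] <- dst[j, i] <- d
    }
  }
  list(bits = bits, dist = dst)
}

#' Center-star multiple sequence alignment
#'
#' Desk-scale stand-in for an external MSA tool: picks the sequence with
#' the highest summed pairwise bit score as the center, aligns every
#' other sequence to it globally, and merges the pairwise alignments with
#' the "once a gap, always a gap" rule.  Row order follows the input.
#'
#' @param seqs named character vector (>= 1 sequence; a single sequence
#'   is returned as its own trivial alignment).
#' @param m substitution matrix bundle.
#' @param gap_open,gap_extend gap penalties.
#' @return named character vector of equal-length gapped rows.
#' @export
center_star_msa <- function(seqs, m = default_submatrix(),
                            gap_open = 11, gap_extend = 1) {
  n <- length(seqs)
  if (n == 0) gt_stop("input", "no sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  if (n == 1) return(seqs)
  bits <- all_vs_all(seqs, m, gap_open, gap_extend)$bits
  sums <- rowSums(bits) - diag(bits)
  center <- which.max(sums)
  cs <- .check_seq(seqs[[center]])
  lc <- length(cs)
  others <- setdiff(seq_len(n), center)
  # per-alignment gapped index vectors vs the center
  alns <- lapply(others, function(i) {
    co <- .check_seq(seqs[[i]])
    S <- m$matrix[cs, co, drop = FALSE]
    global_align_cpp(S, gap_open, gap_extend)
  })
  # gaps_before[j]: gap columns immediately before center position j
  # (j = lc + 1 is the right flank); master pattern takes the maximum
  gaps_before <- function(ga) {
    g <- integer(lc + 1)
    pos <- 1L
    for (v in ga) {
      if (v == 0L) g[pos] <- g[pos] + 1L else pos <- v + 1L
    }
    g
  }
  G <- Reduce(pmax, lapply(alns, function(a) gaps_before(a$gapped_a)),
              integer(lc + 1))
  pad_row <- function(ga, gb, chars) {
    out <- character(0)
    block <- character(0)   # residues of b accumulated in the current gap run
    pos <- 1L
    flush <- function(pos, block) {
      pad <- G[pos] - length(block)
      c(block, rep("-", pad))
    }
    for (k in seq_along(ga)) {
      if (ga[k] == 0L) {
        block <- c(block, if (gb[k] == 0L) "-" else chars[gb[k]])
      } else {
        out <- c(out, flush(pos, block))
        block <- character(0)
        out <- c(out, if (gb[k] == 0L) "-" else chars[gb[k]])
        pos <- ga[k] + 1L
      }
    }
    out <- c(out, flush(lc + 1L, block))
    paste(out, collapse = "")
  }
  rows <- vector("character", n)
  # center row: its own residues with the master gap pattern interleaved
  center_chars <- unlist(lapply(seq_len(lc + 1), function(j) {
    c(rep("-", G[j]), if (j <= lc) cs[j])
  }))
  rows[center] <- paste(center_chars, collapse = "")
  for (k in seq_along(others)) {
    i <- others[k]
    rows[i] <- pad_row(alns[[k]]$gapped_a, alns[[k]]$gapped_b,
                       .check_seq(seqs[[i]]))
  }
  names(rows) <- names(seqs)
  rows
}
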