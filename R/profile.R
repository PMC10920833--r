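# Per-cluster frequency profiles and directional profile-profile scoring —
# the desk-scale stand-in for the HMM/HHblits stage — plus adapters for
# real BLAST tabular output and pre-extracted profile-comparison scores.

#' Build a frequency profile from a multiple sequence alignment
#'
#' Per-column amino-acid frequencies with background-mix pseudocounts:
#' `f(a) = (count(a) + beta * bg(a)) / (n_residues + beta)`.  Gaps are
#' excluded from the residue count and reported as a per-column gap
#' fraction.  With `beta > 0` every frequency is strictly positive.
#'
#' @param msa named character vector of equal-length gapped rows.
#' @param beta pseudocount weight (default 5).
#' @param bg background frequency vector over the 20 residues.
#' @param id cluster id carried on the profile.
#' @return an object of class `gt_profile`.
#' @export
build_profile <- function(msa, beta = 5, bg = .aa_background, id = "profile") {
  if (length(msa) == 0) gt_stop("input", "empty alignment")
  if (length(unique(nchar(msa))) != 1)
    gt_stop("input", "alignment rows differ in length")
  bg <- bg[.aa20]
  if (anyNA(bg)) gt_stop("config", "background vector must cover the 20 residues")
  chars <- do.call(rbind, strsplit(unname(msa), ""))
  ncol_ <- ncol(chars)
  freqs <- matrix(0, nrow = 20, ncol = ncol_, dimnames = list(.aa20, NULL))
  gap_fraction <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    col <- chars[, j]
    gap_fraction[j] <- mean(col == "-")
    col <- col[col %in% .aa20]
    cnt <- table(factor(col, levels = .aa20))
    freqs[, j] <- (as.numeric(cnt) + beta * bg) / (length(col) + beta)
  }
  structure(list(id = id, freqs = freqs, gap_fraction = gap_fraction,
                 n_seq = length(msa), beta = beta, background = bg),
            class = "gt_profile")
}

#' @export
print.gt_profile <- function(x, ...) {
  cat(sprintf("<gt_profile> '%s': %d columns from %d sequences (beta=%g)\n",
              x$id, ncol(x$freqs), x$n_seq, x$beta))
  invisible(x)
}

#' Directional profile-profile comparison score
#'
#' Local alignment over profile column pairs with the column score
#' `s(q_i -> t_j) = sum_a f_q(a) * log2(f_t(a) / bg(a))` (bits) and affine
#' gap penalties in bits.  The score is asymmetric by construction: the
#' query's observed frequencies are scored against the target's
#' pseudocounted log-odds, so `score(q -> t)` generally differs from
#' `score(t -> q)`.  A comparison with no positive-scoring local path
#' reports score 0.
#'
#' @param query,target `gt_profile` objects sharing a background vector.
#' @param gap_open_bits,gap_extend_bits affine gap penalties in bits.
#' @return a `profile_hit`: query/target ids, `score`, and the aligned
#'   column spans on each profile.
#' @export
profile_score <- function(query, target, gap_open_bits = 3.0,
                          gap_extend_bits = 0.3) {
  stopifnot(inherits(query, "gt_profile"), inherits(target, "gt_profile"))
  if (ncol(query$freqs) == 0 || ncol(target$freqs) == 0)
    gt_stop("input", "empty profile")
  if (!isTRUE(all.equal(query$background, target$background)))
    gt_stop("config", "profiles built against different background vectors")
  bg <- target$background
  L <- log2(target$freqs / bg)        # 20 x nt target log-odds
  S <- crossprod(query$freqs, L)      # nq x nt column scores
  res <- local_align_cpp(S, gap_open_bits, gap_extend_bits)
  span <- function(p) if (length(p)) c(p[1], p[length(p)]) else c(NA_integer_, NA_integer_)
  structure(list(query = query$id, target = target$id,
                 score = res$score,
                 span_query = span(res$pairs_a),
                 span_target = span(res$pairs_b)),
            class = "profile_hit")
}

#' @export
print.profile_hit <- function(x, ...) {
  cat(sprintf("<profile_hit> %s → %s: %.1f\n", x$query, x$target, x$score))
  invisible(x)
}

#' Parse BLAST tabular (outfmt 6) output into a bit-score edge list
#'
#' Reads 12-column tab-separated rows (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Self-hits are retained; when a (query, subject) ordered pair occurs
#' more than once, the maximum bit score is kept.  Malformed rows are
#' skipped with a warning and counted in the parse report.
#'
#' @param path BLAST tabular file.
#' @return list with `edges` (data.frame query, subject, bits) and
#'   `report` (rows read/kept/skipped).
#' @export
parse_blast_tab <- function(path) {
  if (!file.exists(path)) gt_stop("input", sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f)
    length(f) >= 12 && !is.na(suppressWarnings(as.numeric(f[12]))), TRUE)
  n_skip <- sum(!ok)
  if (n_skip > 0)
    gt_warn(sprintf("%s: skipped %d malformed row(s)", path, n_skip))
  fields <- fields[ok]
  edges <- data.frame(
    query = vapply(fields, `[`, "", 1),
    subject = vapply(fields, `[`, "", 2),
    bits = as.numeric(vapply(fields, `[`, "", 12)),
    stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    key <- paste(edges$query, edges$subject, sep = "\r")
    edges <- edges[order(key, -edges$bits), ]
    edges <- edges[!duplicated(paste(edges$query, edges$subject, sep = "\r")), ]
    rownames(edges) <- NULL
  }
  list(edges = edges,
       report = list(n_rows = length(ok), n_kept = nrow(edges),
                     n_skipped = n_skip))
}

#' Parse a directional profile-score table
#'
#' Reads a TSV with columns `query`, `target`, `score` (e.g. extracted
#' from hhr output).  Hits are kept exactly as given — both directions of
#' a pair may be present with different scores and are never symmetrized
#' here.
#'
#' @param path TSV file.
#' @return data.frame with columns query, target, score.
#' @export
parse_profile_scores <- function(path) {
  df <- read_tsv_strict(path, c("query", "target", "score"))
  score_num <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score_num)) {
    bad <- which(is.na(score_num))[1]
    gt_stop("parse", sprintf("%s line %d: non-numeric score '%s'",
                             path, bad + 1L, df$score[bad]))
  }
  data.frame(query = as.character(df$query), target = as.character(df$target),
             score = score_num, stringsAsFactors = FALSE)
}
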