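# Translation of repeat units into backbone geometry tokens.
#
# Each backbone residue becomes one token
#
#     <ring class>:<donor carbon><donor orientation>:<acceptor carbon><acceptor orientation>
#
# e.g. "P:1D:3U" — a pyranose donating its anomeric C1 with the oxygen
# below the ring and accepting the next backbone bond at C3 with the
# oxygen above the ring.  Ring class is P (pyranose), F (furanose) or L
# (linear/open chain); orientations are U/D/N.  Chemical modifications and
# sidechain branches never reach the token.

.token_re <- "^([PFL]):([0-9]+)([UDN]):([0-9]+)([UDN])$"

.make_token <- function(ring_class, dc, do, ac, ao)
  sprintf("%s:%d%s:%d%s", ring_class, dc, do, ac, ao)

#' Construct a backbone string from tokens
#'
#' Builds a `backbone_string` directly from canonical token text (see
#' [translate_repeat_unit()] for the token syntax).  Mainly useful for
#' tests and for scoring token strings produced elsewhere.
#'
#' @param tokens character vector of tokens, reducing end first.
#' @return an object of class `backbone_string`.
#' @examples
#' backbone_string(c("P:1D:3U", "P:1D:4D", "P:1U:3U"))
#' @export
backbone_string <- function(tokens) {
  m <- regmatches(tokens, regexec(.token_re, tokens))
  bad <- vapply(m, length, 1L) == 0
  if (any(bad))
    gt_stop("parse", sprintf("malformed backbone token '%s'", tokens[bad][1]))
  units <- data.frame(
    ring_class = vapply(m, `[`, "", 2),
    donor_carbon = as.integer(vapply(m, `[`, "", 3)),
    donor_orient = vapply(m, `[`, "", 4),
    acceptor_carbon = as.integer(vapply(m, `[`, "", 5)),
    acceptor_orient = vapply(m, `[`, "", 6),
    stringsAsFactors = FALSE)
  structure(list(tokens = unname(tokens), units = units),
            class = "backbone_string")
}

#' @export
print.backbone_string <- function(x, ...) {
  cat(sprintf("<backbone_string> n=%d  [reducing] %s [non-reducing]\n",
              length(x$tokens), paste(x$tokens, collapse = " ")))
  invisible(x)
}

#' @export
length.backbone_string <- function(x) length(x$tokens)

#' Subsite accessors
#'
#' `minus_token(x, k)` is the token of the k-th backbone residue counted
#' from the reducing end (the donor side of the polymerase bond);
#' `plus_token(x, k)` counts from the non-reducing end (the acceptor
#' side), so `plus_token(x, k)` aliases `minus_token(x, n - k + 1)`.
#'
#' @param x a `backbone_string`.
#' @param k subsite index, 1-based.
#' @return token string, or `NA` if the subsite does not exist.
#' @export
minus_token <- function(x, k) {
  stopifnot(inherits(x, "backbone_string"))
  if (k < 1 || k > length(x$tokens)) return(NA_character_)
  x$tokens[k]
}

#' @rdname minus_token
#' @export
plus_token <- function(x, k) {
  stopifnot(inherits(x, "backbone_string"))
  n <- length(x$tokens)
  if (k < 1 || k > n) return(NA_character_)
  x$tokens[n - k + 1]
}

#' Translate a repeat unit into its backbone string
#'
#' Walks the backbone path of the repeat unit (reducing end to
#' non-reducing end) and emits one geometry token per backbone residue.
#' The reducing-end residue's donor fields come from the polymerase bond;
#' the non-reducing-end residue's acceptor fields come from the polymerase
#' bond's acceptor carbon.  Substituents and sidechain residues have no
#' effect on the tokens.
#'
#' @param unit a [parse_repeat_unit()] result.
#' @param table a [default_stereo_table()].
#' @return an object of class `backbone_string`.
#' @export
translate_repeat_unit <- function(unit, table = default_stereo_table()) {
  stopifnot(inherits(unit, "repeat_unit"))
  path <- extract_backbone(unit)
  n <- length(path)
  find_bond <- function(donor, acceptor) {
    for (b in unit$bonds)
      if (b$donor == donor && b$acceptor == acceptor) return(b)
    gt_stop("structural", "backbone bond missing from bond list")
  }
  tokens <- character(n)
  for (i in seq_len(n)) {
    r <- unit$residues[[path[i]]]
    ring_class <- c(p = "P", f = "F", open = "L")[[r$ring_form]]
    if (i == 1) {
      dc <- unit$polymerase_bond$donor_carbon
      dano <- unit$polymerase_bond$anomeric
    } else {
      b <- find_bond(path[i], path[i - 1])
      dc <- b$donor_carbon
      dano <- b$anomeric
    }
    do_ <- if (r$ring_form == "open") "N" else anomeric_orientation(r$config, dano)
    if (i == n) {
      ac <- unit$polymerase_bond$acceptor_carbon
    } else {
      ac <- find_bond(path[i + 1], path[i])$acceptor_carbon
    }
    ao <- stereo_orientation(table, r$parent, r$ring_form, ac, r$config)
    tokens[i] <- .make_token(ring_class, dc, do_, ac, ao)
  }
  backbone_string(tokens)
}
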