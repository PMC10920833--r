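# Parsing of oligosaccharide repeat units written in IUPAC-condensed-style
# notation, and extraction of their backbone residue path.
#
# Grammar ("->" may be used for the arrow; whitespace is ignored):
#
#   unit     :=  "→y)-" chain-EOF
#   chain    :=  [branch "-"]* residue linkage ...
#   linkage  :=  "-(" x "→" ( [branch "-"]* y ")" "-" chain   # in-chain bond
#              |  "-(" x "→" EOF                              # polymerase bond
#              |  "-(" x "→" y ")]"                           # end of branch
#   branch   :=  "[" chain-")]"                # bracketed sidechain whose last
#                                              # linkage "(x→y)" attaches it at
#                                              # carbon y of the next residue
#   residue  :=  [anomer "-"] [config "-"] name [ring] subst*
#   anomer   :=  "α" | "β" | "a" | "b"
#   config   :=  "D" | "L"
#   ring     :=  "p" | "f"                     # absent for open-chain polyols
#   subst    :=  digits letters                # e.g. "2Ac"; carried, not scored
#
# Residues are listed from the non-reducing end to the reducing end; the
# trailing "-(x→" is the anomeric bond formed by the polymerase between
# this unit's reducing-end residue (the one attached to Und-PP) and carbon
# y of the leading "→y)" marker on the next copy's first-listed residue.

`%||%` <- function(a, b) if (is.null(a)) b else a

.norm_glycan_text <- function(text) {
  text <- gsub("->", "→", text, fixed = TRUE)
  gsub("[[:space:]]+", "", text)
}

.glycan_state <- function(text) {
  st <- new.env(parent = emptyenv())
  st$text <- text
  st$chars <- strsplit(text, "")[[1]]
  st$pos <- 1L
  st$residues <- list()
  st$bonds <- list()
  st
}

.perr <- function(st, msg) {
  gt_stop("parse",
          sprintf("glycan parse error at position %d: %s (near '%s')",
                  st$pos, msg,
                  substr(st$text, st$pos, min(nchar(st$text), st$pos + 14))),
          position = st$pos)
}

.peek <- function(st, k = 1L)
  paste(st$chars[seq(st$pos, length.out = k)], collapse = "")

.eof <- function(st) st$pos > length(st$chars)

.eat <- function(st, lit) {
  n <- nchar(lit)
  if (st$pos + n - 1L > length(st$chars) || .peek(st, n) != lit)
    .perr(st, sprintf("expected '%s'", lit))
  st$pos <- st$pos + n
  invisible(st)
}

.try_eat <- function(st, lit) {
  n <- nchar(lit)
  if (st$pos + n - 1L <= length(st$chars) && .peek(st, n) == lit) {
    st$pos <- st$pos + n
    TRUE
  } else FALSE
}

.eat_int <- function(st) {
  j <- st$pos
  while (j <= length(st$chars) && st$chars[j] %in% as.character(0:9)) j <- j + 1L
  if (j == st$pos) .perr(st, "expected a carbon index")
  v <- as.integer(substr(st$text, st$pos, j - 1L))
  st$pos <- j
  v
}

.at_int <- function(st) !.eof(st) && st$chars[st$pos] %in% as.character(0:9)

.eat_residue <- function(st, table, sidechain) {
  start <- st$pos
  anomeric <- "none"
  ch <- if (!.eof(st)) st$chars[st$pos] else ""
  if (ch %in% c("α", "a")) anomeric <- "alpha"
  else if (ch %in% c("β", "b")) anomeric <- "beta"
  if (anomeric != "none") { st$pos <- st$pos + 1L; .eat(st, "-") }
  config <- "none"
  if (.peek(st, 2) %in% c("D-", "L-")) {
    config <- st$chars[st$pos]
    st$pos <- st$pos + 2L
  }
  rest <- substr(st$text, st$pos, nchar(st$text))
  name <- NULL
  for (nm in names(table$parents)[order(-nchar(names(table$parents)))])
    if (startsWith(rest, nm)) { name <- nm; break }
  if (is.null(name)) {
    tok <- regmatches(rest, regexpr("^[A-Za-z0-9]+", rest))
    gt_stop("unknown_residue",
            sprintf("glycan parse error at position %d: unknown parent sugar '%s'",
                    st$pos, if (length(tok)) tok else "?"),
            token = if (length(tok)) tok else "", position = st$pos)
  }
  st$pos <- st$pos + nchar(name)
  info <- table$parents[[name]]
  open <- isTRUE(info$open)
  ring <- "open"
  if (!open) {
    rc <- if (!.eof(st)) st$chars[st$pos] else ""
    if (!rc %in% c("p", "f"))
      .perr(st, sprintf("expected ring form 'p' or 'f' after '%s'", name))
    ring <- rc
    st$pos <- st$pos + 1L
  }
  subst <- info$subst
  repeat {                                    # trailing substituents: 2Ac, ...
    rest <- substr(st$text, st$pos, nchar(st$text))
    m <- regmatches(rest, regexpr("^[0-9]+[A-Za-z]+", rest))
    if (length(m) == 0) break
    subst <- c(subst, list(c(as.integer(sub("^([0-9]+).*", "\\1", m)),
                             sub("^[0-9]+", "", m))))
    st$pos <- st$pos + nchar(m)
  }
  if (open && anomeric != "none") {
    st$pos <- start
    .perr(st, sprintf("open-chain residue '%s' cannot carry an anomeric symbol", name))
  }
  if (!open && anomeric == "none") {
    st$pos <- start
    .perr(st, sprintf("cyclic residue '%s' requires an anomeric symbol", name))
  }
  if (!open && config == "none") {
    st$pos <- start
    .perr(st, sprintf("cyclic residue '%s' requires a D/L configuration", name))
  }
  st$residues[[length(st$residues) + 1L]] <- list(
    name = name, parent = info$parent, config = config, ring_form = ring,
    anomeric = anomeric, substituents = subst, sidechain = sidechain)
  length(st$residues)
}

.add_bond <- function(st, donor, donor_carbon, acceptor, acceptor_carbon, anomeric) {
  st$bonds[[length(st$bonds) + 1L]] <- list(
    donor = donor, donor_carbon = donor_carbon,
    acceptor = acceptor, acceptor_carbon = acceptor_carbon,
    anomeric = anomeric)
}

# Parse one chain.  `terminal` is "eof" for the main chain (ends at the
# dangling polymerase linkage "(x→<EOF>") or "bracket" for a sidechain
# (ends at "(x→y)]").  Returns list(last, x [, y]).
.eat_chain <- function(st, table, terminal, sidechain) {
  pending <- NULL       # bond waiting for its acceptor residue
  branches <- list()    # parsed sidechains waiting for their acceptor
  repeat {
    while (.try_eat(st, "[")) {
      b <- .eat_chain(st, table, "bracket", sidechain = TRUE)
      .eat(st, "-")
      branches <- c(branches, list(b))
    }
    idx <- .eat_residue(st, table, sidechain)
    res <- st$residues[[idx]]
    for (b in branches)
      .add_bond(st, b$last, b$x, idx, b$y, st$residues[[b$last]]$anomeric)
    branches <- list()
    if (!is.null(pending)) {
      .add_bond(st, pending$donor, pending$x, idx, pending$y, pending$anomeric)
      pending <- NULL
    }
    .eat(st, "-(")
    x <- .eat_int(st)
    .eat(st, "→")
    if (terminal == "eof" && .eof(st))
      return(list(last = idx, x = x))
    while (.try_eat(st, "[")) {               # branch inside the linkage
      b <- .eat_chain(st, table, "bracket", sidechain = TRUE)
      .eat(st, "-")
      branches <- c(branches, list(b))
    }
    if (!.at_int(st)) .perr(st, "expected acceptor carbon")
    y <- .eat_int(st)
    if (terminal == "bracket" && .try_eat(st, ")]")) {
      if (length(branches) > 0) .perr(st, "dangling branch at end of sidechain")
      return(list(last = idx, x = x, y = y))
    }
    .eat(st, ")")
    .eat(st, "-")
    pending <- list(donor = idx, x = x, y = y, anomeric = res$anomeric)
  }
}

#' Parse a glycan repeat unit
#'
#' Parses an IUPAC-condensed-style repeat-unit string with leading and
#' trailing polymerase-linkage markers (see the grammar in the README)
#' into a structured repeat unit: its residues, the intramolecular bond
#' tree and the polymerase bond.  Residues are written non-reducing end
#' first; the last main-chain residue is the reducing-end residue carried
#' on the Und-PP lipid anchor.
#'
#' @param text glycan string, e.g.
#'   `"→3)-β-D-Galp-(1→3)-α-D-Glcp-(1→4)-α-D-Glcp-(1→"` (ASCII `->` is
#'   accepted for the arrow).
#' @param table a [default_stereo_table()]; also supplies the residue-name
#'   vocabulary.
#' @return an object of class `repeat_unit` with fields `residues`,
#'   `bonds`, `und_pp_residue` and `polymerase_bond`.
#' @examples
#' u <- parse_repeat_unit("->3)-b-D-Galp-(1->3)-a-D-Glcp-(1->4)-a-D-Glcp-(1->")
#' length(u$residues)
#' @export
parse_repeat_unit <- function(text, table = default_stereo_table()) {
  raw <- text
  st <- .glycan_state(.norm_glycan_text(text))
  .eat(st, "→")
  y0 <- .eat_int(st)
  .eat(st, ")")
  .eat(st, "-")
  res <- .eat_chain(st, table, "eof", sidechain = FALSE)
  reducing <- res$last
  main_chain <- which(!vapply(st$residues, `[[`, TRUE, "sidechain"))
  out <- structure(list(
    residues = st$residues,
    bonds = st$bonds,
    und_pp_residue = reducing,
    polymerase_bond = list(
      anomeric = st$residues[[reducing]]$anomeric,
      donor_carbon = res$x,
      acceptor = main_chain[1],
      acceptor_carbon = y0),
    source = raw), class = "repeat_unit")
  .validate_repeat_unit(out)
  out
}

.bond_adjacency <- function(unit) {
  adj <- vector("list", length(unit$residues))
  for (b in unit$bonds) {
    adj[[b$donor]] <- c(adj[[b$donor]], b$acceptor)
    adj[[b$acceptor]] <- c(adj[[b$acceptor]], b$donor)
  }
  adj
}

.validate_repeat_unit <- function(unit) {
  n <- length(unit$residues)
  acc <- vapply(unit$bonds, function(b) paste(b$acceptor, b$acceptor_carbon), "")
  acc <- c(acc, paste(unit$polymerase_bond$acceptor,
                      unit$polymerase_bond$acceptor_carbon))
  if (anyDuplicated(acc))
    gt_stop("structural",
            sprintf("two bonds share an acceptor position (residue %s)",
                    acc[duplicated(acc)][1]))
  if (length(unit$bonds) != n - 1L)
    gt_stop("structural", "intramolecular bonds do not form a tree")
  adj <- .bond_adjacency(unit)
  seen <- logical(n); seen[1] <- TRUE; queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen))
    gt_stop("structural", "repeat unit bond graph is not connected")
  invisible(unit)
}

#' @export
print.repeat_unit <- function(x, ...) {
  pb <- x$polymerase_bond
  cat(sprintf("<repeat_unit> %d residues (%d sidechain), polymerase bond %s%d→%d\n",
              length(x$residues),
              sum(vapply(x$residues, `[[`, TRUE, "sidechain")),
              c(alpha = "α", beta = "β", none = "?")[pb$anomeric],
              pb$donor_carbon, pb$acceptor_carbon))
  invisible(x)
}

#' Extract the backbone residue path of a repeat unit
#'
#' The backbone is the unique path through the intramolecular bond tree
#' from the reducing-end (Und-PP-attached) residue to the residue that
#' accepts the polymerase bond; sidechain residues fall off the path.
#'
#' @param unit a [parse_repeat_unit()] result.
#' @return integer vector of residue indices, reducing end first.
#' @export
extract_backbone <- function(unit) {
  stopifnot(inherits(unit, "repeat_unit"))
  from <- unit$und_pp_residue
  to <- unit$polymerase_bond$acceptor
  if (from == to) return(from)
  adj <- .bond_adjacency(unit)
  n <- length(unit$residues)
  parent <- rep(NA_integer_, n)
  seen <- logical(n); seen[from] <- TRUE; queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      seen[w] <- TRUE; parent[w] <- v; queue <- c(queue, w)
    }
  }
  if (!seen[to])
    gt_stop("structural",
            "polymerase acceptor residue unreachable from the reducing end")
  path <- to
  while (path[1] != from) path <- c(parent[path[1]], path)
  path
}
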