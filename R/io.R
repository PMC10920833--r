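# Sequence and alignment file I/O (thin wrappers around Biostrings).

#' Read protein sequences from FASTA
#'
#' @param path FASTA file (wrapped lines and descriptions allowed; the id
#'   is the first whitespace-delimited token of the header).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) gt_stop("input", sprintf("file not found: %s", path))
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    gt_stop("input", sprintf("duplicate sequence id '%s' in %s",
                             names(seqs)[duplicated(names(seqs))][1], path))
  seqs
}

#' Write sequences (or a gapped alignment) to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or (single-block or multi-block) Stockholm format;
#' the format is chosen from the file contents.
#'
#' @param path alignment file.
#' @return named character vector of equal-length gapped rows.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) gt_stop("input", sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  rows <- if (startsWith(first, "# STOCKHOLM")) {
    lines <- readLines(path)
    body <- lines[!grepl("^(#|//|\\s*$)", lines)]
    if (length(body) == 0) gt_stop("parse", sprintf("%s: no alignment rows", path))
    parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)$", body))
    bad <- vapply(parts, length, 1L) != 3
    if (any(bad))
      gt_stop("parse", sprintf("%s: malformed Stockholm row '%s'",
                               path, body[bad][1]))
    ids <- vapply(parts, `[`, "", 2)
    sq <- vapply(parts, `[`, "", 3)
    tapply(sq, factor(ids, levels = unique(ids)), paste, collapse = "")
  } else read_fasta(path)
  rows <- setNames(as.character(gsub("[.]", "-", toupper(rows))), names(rows))
  if (length(unique(nchar(rows))) != 1)
    gt_stop("parse", sprintf("%s: alignment rows differ in length", path))
  rows
}
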