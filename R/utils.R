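# Shared helpers: classed errors, TSV conventions, small validators.

#' Signal a classed gtclan error
#'
#' All user-facing errors in the package carry a machine-readable condition
#' class of the form `gtclan_<class>_error`, so callers (and the CLI) can
#' dispatch on the failure mode rather than on message text.
#'
#' @param class short error class, e.g. "parse", "input", "structural".
#' @param msg human-readable message.
#' @param ... fields stored on the condition object.
#' @keywords internal
gt_stop <- function(class, msg, ...) {
  cond <- structure(
    class = c(paste0("gtclan_", class, "_error"), "gtclan_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

gt_warn <- function(msg) warning(msg, call. = FALSE)

#' Read a TSV file with mandatory header
#' @keywords internal
read_tsv_strict <- function(path, required = character()) {
  if (!file.exists(path)) gt_stop("input", sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    gt_stop("parse", sprintf("%s: missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a labelled square matrix as TSV with an id header row and column
#' @keywords internal
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv_strict(path, "id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  storage.mode(m) <- "double"
  m
}

check_square_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    gt_stop("input", sprintf("%s must be square", what))
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    gt_stop("input", sprintf("%s must carry identical row/col ids", what))
  invisible(m)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value for independent
#' random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) gt_stop("input", "label vectors differ in length")
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
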