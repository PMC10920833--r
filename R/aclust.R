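# Alignment-based clustering trees: classical distance-geometry embedding
# of a (possibly non-metric) distance matrix into orthogonal coordinates,
# nearest-neighbour joining with centroid averaging in that space, and
# recursive re-embedding of the root's subtrees.

#' Embed a distance matrix into orthogonal coordinates
#'
#' Classical (Torgerson) metric-matrix distance geometry: the squared
#' distance matrix is double-centered, `B = -1/2 * J D^2 J`, and the
#' coordinates are the eigenvectors of B scaled by the square roots of
#' their eigenvalues.  Dimensions with eigenvalues at or below
#' `tolerance * max(eigenvalue)` are dropped; negative eigenvalue mass
#' (from non-metric input such as Scoredist distances) is dropped and
#' reported, never reflected.
#'
#' @param d symmetric nonnegative distance matrix with zero diagonal and
#'   ids on the dimnames.
#' @param tolerance relative eigenvalue cutoff (default 1e-9).
#' @param max_dim dimensionality cap (default 20).
#' @return object of class `embedded_points`: `ids`, `coords`
#'   (points x dims), `eigenvalues` (descending, all retained ones),
#'   `negative_mass` (summed magnitude of dropped negative eigenvalues).
#' @export
embed_distances <- function(d, tolerance = 1e-9, max_dim = 20) {
  check_square_named(d, "distance matrix")
  if (max(abs(d - t(d))) > 1e-12)
    gt_stop("input", "distance matrix is not symmetric")
  if (any(diag(d) != 0))
    gt_stop("input", "distance matrix diagonal must be zero")
  n <- nrow(d)
  ids <- rownames(d)
  if (n == 1)
    return(structure(list(ids = ids, coords = matrix(0, 1, 0),
                          eigenvalues = numeric(0), negative_mass = 0),
                     class = "embedded_points"))
  D2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values
  neg_mass <- sum(abs(vals[vals < 0]))
  if (max(vals) <= 0) {
    coords <- matrix(0, n, 0)
    keep <- integer(0)
  } else {
    keep <- which(vals > tolerance * max(vals))
    keep <- utils::head(keep, max_dim)
    coords <- eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(vals[keep]), nrow = length(keep))
  }
  rownames(coords) <- ids
  structure(list(ids = ids, coords = coords, eigenvalues = vals[keep],
                 negative_mass = neg_mass),
            class = "embedded_points")
}

#' @export
print.embedded_points <- function(x, ...) {
  cat(sprintf("<embedded_points> %d points in %d dimensions (dropped negative mass %.3g)\n",
              length(x$ids), ncol(x$coords), x$negative_mass))
  invisible(x)
}

# tree nodes: list(leaf = id) or list(children = list(a, b),
# lengths = c(la, lb)); every node carries min_leaf for tie-breaking

.leaf_node <- function(id) list(leaf = id, min_leaf = id, count = 1L)

.tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  c(.tree_leaves(node$children[[1]]), .tree_leaves(node$children[[2]]))
}

#' Nearest-neighbour joining with centroid averaging
#'
#' Iteratively joins the pair of active nodes at minimal Euclidean
#' distance in the embedding space; the pair is replaced by its centroid
#' (leaf-count-weighted by default), and the branch length to each child
#' is the Euclidean distance from the child's centroid to the new one.
#' Ties in the minimal distance are broken in favour of the pair whose
#' id-sorted member ids are lowest.  The last centroid created is the
#' root.
#'
#' @param p an [embed_distances()] result (>= 2 points).
#' @param weighted leaf-count-weighted centroids (default TRUE); when
#'   FALSE the new centroid is the unweighted mean of the two children's
#'   centroids.
#' @return object of class `gt_tree` (rooted, strictly bifurcating, with
#'   nonnegative branch lengths).
#' @export
nnj_tree <- function(p, weighted = TRUE) {
  stopifnot(inherits(p, "embedded_points"))
  n <- length(p$ids)
  if (n < 2) gt_stop("input", "need at least 2 points to build a tree")
  nodes <- lapply(p$ids, .leaf_node)
  coords <- lapply(seq_len(n), function(i) p$coords[i, ])
  counts <- rep(1L, n)
  active <- seq_len(n)
  while (length(active) > 1) {
    # scan pairs in id-sorted order so distance ties pick the lowest pair
    ord <- active[order(vapply(nodes[active], `[[`, "", "min_leaf"))]
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(ord) - 1)) {
      for (j in (i + 1):length(ord)) {
        dd <- sqrt(sum((coords[[ord[i]]] - coords[[ord[j]]])^2))
        if (dd < best_d) { best_d <- dd; best <- c(ord[i], ord[j]) }
      }
    }
    a <- best[1]; b <- best[2]
    wa <- if (weighted) counts[a] else 1L
    wb <- if (weighted) counts[b] else 1L
    cen <- (wa * coords[[a]] + wb * coords[[b]]) / (wa + wb)
    la <- sqrt(sum((coords[[a]] - cen)^2))
    lb <- sqrt(sum((coords[[b]] - cen)^2))
    new_node <- list(children = list(nodes[[a]], nodes[[b]]),
                     lengths = c(la, lb),
                     min_leaf = min(nodes[[a]]$min_leaf, nodes[[b]]$min_leaf),
                     count = counts[a] + counts[b])
    nodes[[length(nodes) + 1L]] <- new_node
    coords[[length(coords) + 1L]] <- cen
    counts <- c(counts, counts[a] + counts[b])
    active <- c(setdiff(active, c(a, b)), length(nodes))
  }
  structure(list(root = nodes[[active]], ids = sort(p$ids)),
            class = "gt_tree")
}

#' @export
print.gt_tree <- function(x, ...) {
  cat(sprintf("<gt_tree> %d leaves\n", length(x$ids)))
  invisible(x)
}

#' Recursively re-embed and rebuild the root's subtrees
#'
#' Starting from the root split, each side with at least `min_leaves`
#' leaves is re-embedded from its own sub-distance-matrix, rebuilt with
#' [nnj_tree()] and refined recursively; smaller subtrees are kept as
#' built.  The root join between the two (possibly refined) subtrees is
#' recomputed from their leaf centroids in the embedding of the full
#' matrix at this level.  Re-embedding small subsets removes the
#' long-distance distortion that unrelated sequences impose on the
#' global embedding.
#'
#' @param t a [nnj_tree()] result built from `d`.
#' @param d the distance matrix the tree was built from.
#' @param min_leaves recursion floor (default 4; joining 3 or fewer
#'   points is already optimal).
#' @param weighted centroid weighting, as in [nnj_tree()].
#' @return refined `gt_tree`.
#' @export
recursive_refine <- function(t, d, min_leaves = 4, weighted = TRUE) {
  stopifnot(inherits(t, "gt_tree"))
  check_square_named(d, "distance matrix")
  if (!setequal(t$ids, rownames(d)))
    gt_stop("input", "tree leaves and distance matrix ids differ")
  refine_node <- function(node, dm) {
    if (!is.null(node$leaf) || length(.tree_leaves(node)) < 3) return(node)
    sides <- lapply(node$children, .tree_leaves)
    emb <- embed_distances(dm)
    cen <- list()
    new_children <- vector("list", 2)
    for (s in 1:2) {
      lv <- sides[[s]]
      child <- node$children[[s]]
      if (length(lv) >= min_leaves) {
        dsub <- dm[lv, lv, drop = FALSE]
        sub <- nnj_tree(embed_distances(dsub), weighted = weighted)
        child <- refine_node(sub$root, dsub)
      }
      new_children[[s]] <- child
      cen[[s]] <- colMeans(emb$coords[lv, , drop = FALSE])
    }
    w <- vapply(sides, length, 1L)
    if (!weighted) w <- c(1L, 1L)
    root_cen <- (w[1] * cen[[1]] + w[2] * cen[[2]]) / sum(w)
    list(children = new_children,
         lengths = c(sqrt(sum((cen[[1]] - root_cen)^2)),
                     sqrt(sum((cen[[2]] - root_cen)^2))),
         min_leaf = min(new_children[[1]]$min_leaf,
                        new_children[[2]]$min_leaf),
         count = sum(vapply(sides, length, 1L)))
  }
  d <- d[sort(rownames(d)), sort(rownames(d))]
  structure(list(root = refine_node(t$root, d), ids = t$ids),
            class = "gt_tree")
}

#' Build an Aclust tree from a distance matrix
#'
#' Convenience wrapper: embed, join, and (by default) refine.
#'
#' @param d distance matrix.
#' @param refine apply [recursive_refine()] (default TRUE).
#' @param min_leaves,weighted,tolerance passed through.
#' @return a `gt_tree`.
#' @export
aclust <- function(d, refine = TRUE, min_leaves = 4, weighted = TRUE,
                   tolerance = 1e-9) {
  t <- nnj_tree(embed_distances(d, tolerance), weighted = weighted)
  if (refine) t <- recursive_refine(t, d, min_leaves, weighted)
  t
}

.newick_label <- function(id) {
  if (grepl("[][():;,'[:space:]]", id))
    paste0("'", gsub("'", "''", id), "'")
  else id
}

#' Export a tree as newick text
#'
#' Standard newick with branch lengths; children are ordered by their
#' smallest leaf id so the rendering is deterministic; labels containing
#' reserved characters are single-quoted.
#'
#' @param t a `gt_tree`.
#' @param digits branch-length precision.
#' @return newick string (with terminating semicolon).
#' @export
to_newick <- function(t, digits = 10) {
  stopifnot(inherits(t, "gt_tree"))
  fmt <- function(node) {
    if (!is.null(node$leaf)) return(.newick_label(node$leaf))
    ord <- order(vapply(node$children, `[[`, "", "min_leaf"))
    parts <- vapply(ord, function(k)
      sprintf("%s:%s", fmt(node$children[[k]]),
              format(node$lengths[k], digits = digits, trim = TRUE,
                     scientific = FALSE)), "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(fmt(t$root), ";")
}
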