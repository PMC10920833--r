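# Two-stage family building: sequence similarity network at a strict
# bit-score threshold -> clusters; directional profile-score network over
# clusters -> superclusters; size-thresholded family assignment.

#' Greedy redundancy reduction
#'
#' Stand-in for CD-HIT-style clustering: sequences are processed
#' longest-first; each joins the first existing representative to which
#' its pairwise identity (exact matches over the shorter sequence length,
#' from a local alignment) reaches the threshold, otherwise it becomes a
#' new representative.
#'
#' @param seqs named character vector.
#' @param identity_threshold in \[0.5, 1\] (default 0.95).
#' @param m substitution matrix bundle.
#' @return list with `representatives` (named character vector) and
#'   `membership` (representative id per input sequence).
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.95,
                              m = default_submatrix()) {
  if (identity_threshold < 0.5 || identity_threshold > 1)
    gt_stop("input", "identity threshold must be in [0.5, 1]")
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  membership <- setNames(character(length(seqs)), names(seqs))
  for (i in ord) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (r in reps) {
      aln <- smith_waterman(seqs[[i]], seqs[[r]], m)
      nmatch <- if (nrow(aln$pairs) > 0)
        aln$identity_fraction * nrow(aln$pairs) else 0
      ident <- nmatch / min(nchar(seqs[[i]]), nchar(seqs[[r]]))
      if (ident >= identity_threshold) {
        membership[id] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      membership[id] <- id
    }
  }
  list(representatives = seqs[reps], membership = membership)
}

#' Build a sequence similarity network
#'
#' Nodes are sequences; an undirected edge joins two sequences iff their
#' pairwise bit score is strictly above the threshold.  Asymmetric
#' imported score pairs are symmetrized by the maximum.  Isolated nodes
#' are retained.
#'
#' @param scores either a symmetric bit-score matrix with ids on the
#'   dimnames, or a data.frame with columns query, subject, bits.
#' @param threshold bit-score threshold (edges require score > threshold).
#' @param nodes node ids (required for an edge-list input so isolated
#'   nodes survive; defaults to the matrix ids).
#' @return an igraph undirected graph with edge attribute `bits`.
#' @export
build_ssn <- function(scores, threshold, nodes = NULL) {
  if (is.matrix(scores)) {
    check_square_named(scores, "bit-score matrix")
    nodes <- nodes %||% rownames(scores)
    idx <- which(upper.tri(scores) & scores > threshold, arr.ind = TRUE)
    edges <- data.frame(query = rownames(scores)[idx[, 1]],
                        subject = colnames(scores)[idx[, 2]],
                        bits = scores[idx], stringsAsFactors = FALSE)
  } else {
    if (is.null(nodes))
      gt_stop("input", "edge-list input requires an explicit node id vector")
    scores <- scores[scores$query != scores$subject, , drop = FALSE]
    unknown <- setdiff(unique(c(scores$query, scores$subject)), nodes)
    if (length(unknown) > 0)
      gt_stop("input", sprintf("edge references unknown node '%s'", unknown[1]))
    a <- pmin(scores$query, scores$subject)
    b <- pmax(scores$query, scores$subject)
    key <- paste(a, b, sep = "\r")
    bits <- tapply(scores$bits, key, max)      # symmetrize by maximum
    ab <- do.call(rbind, strsplit(names(bits), "\r", fixed = TRUE))
    keep <- as.numeric(bits) > threshold
    edges <- data.frame(query = ab[keep, 1], subject = ab[keep, 2],
                        bits = as.numeric(bits)[keep], stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::E(g)$bits <- edges$bits
  g
}

#' Connected components of an SSN as ordered clusters
#'
#' Clusters are the connected components of the network, numbered by
#' decreasing member count with ties broken by the smallest member id.
#'
#' @param g an igraph graph from [build_ssn()].
#' @return list of class `cluster_set`: `clusters` (named list of member
#'   id vectors, names "C1", "C2", ...) and `membership` (cluster id per
#'   sequence).
#' @export
ssn_components <- function(g) {
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-vapply(groups, length, 1L),
               vapply(groups, `[`, "", 1))
  groups <- groups[ord]
  names(groups) <- paste0("C", seq_along(groups))
  membership <- setNames(rep(names(groups), lengths(groups)),
                         unlist(groups, use.names = FALSE))
  structure(list(clusters = groups, membership = membership[ids]),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d sequences; sizes: %s\n",
              length(x$clusters), length(x$membership),
              paste(utils::head(lengths(x$clusters), 10), collapse = " ")))
  invisible(x)
}

#' Build the directional supercluster network over SSN clusters
#'
#' Nodes are clusters (weighted by member count); a directed edge
#' query -> target exists iff the directional profile score is strictly
#' above the threshold.  Both directions may coexist.
#'
#' @param clusters a [ssn_components()] result.
#' @param hits data.frame with columns query, target, score (directional;
#'   e.g. from [profile_score()] or [parse_profile_scores()]).
#' @param threshold profile-score threshold.
#' @return a directed igraph graph with vertex attribute `members` and
#'   edge attribute `score`.
#' @export
build_supercluster_network <- function(clusters, hits, threshold) {
  stopifnot(inherits(clusters, "cluster_set"))
  cl_ids <- names(clusters$clusters)
  unknown <- setdiff(unique(c(hits$query, hits$target)), cl_ids)
  if (length(unknown) > 0)
    gt_stop("input", sprintf("profile hit references unknown cluster '%s'",
                             unknown[1]))
  hits <- hits[hits$query != hits$target & hits$score > threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    hits[, c("query", "target", "score")], directed = TRUE,
    vertices = data.frame(name = cl_ids,
                          members = lengths(clusters$clusters)))
  g
}

#' Assign clusters to families from the supercluster network
#'
#' Superclusters are connected components of the undirected support of
#' the directed network (by default one direction above threshold
#' suffices to connect; `require_both_directions = TRUE` keeps only
#' reciprocated edges).  A component whose summed sequence count is
#' strictly greater than `min_family_size` becomes a family, numbered by
#' decreasing total size (ties by smallest contained cluster id);
#' single-cluster components with no edges are singletons; everything
#' else is unclassified.
#'
#' @param net a [build_supercluster_network()] graph.
#' @param min_family_size strict minimum total sequence count (default
#'   150).
#' @param require_both_directions see above.
#' @return list of class `family_assignment`: `cluster_family` (family id,
#'   "singleton" or "unclassified" per cluster), `families` (named list of
#'   cluster ids), `family_sizes` (sequence counts).
#' @export
assign_families <- function(net, min_family_size = 150,
                            require_both_directions = FALSE) {
  if (min_family_size < 1) gt_stop("input", "min_family_size must be >= 1")
  members <- setNames(igraph::V(net)$members, igraph::V(net)$name)
  el <- igraph::as_data_frame(net, what = "edges")
  if (require_both_directions && nrow(el) > 0) {
    fwd <- paste(el$from, el$to)
    rev <- paste(el$to, el$from)
    el <- el[fwd %in% rev, , drop = FALSE]
  }
  support <- igraph::graph_from_data_frame(
    el[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = names(members)))
  comp <- igraph::components(support)
  groups <- split(names(members), comp$membership)
  sizes <- vapply(groups, function(g) sum(members[g]), 0)
  has_edge <- vapply(groups, function(g)
    any(igraph::degree(support, g) > 0), TRUE)
  ord <- order(-sizes, vapply(groups, function(g) sort(g)[1], ""))
  groups <- groups[ord]; sizes <- sizes[ord]; has_edge <- has_edge[ord]
  # an edgeless single cluster never joined a supercluster: it stays a
  # singleton whatever its member count; families come from superclusters
  is_singleton <- !has_edge & lengths(groups) == 1
  is_family <- !is_singleton & sizes > min_family_size
  fam_names <- character(length(groups))
  fam_names[is_family] <- paste0("F", seq_len(sum(is_family)))
  cluster_family <- setNames(rep("unclassified", length(members)),
                             names(members))
  for (k in seq_along(groups)) {
    lab <- if (is_family[k]) fam_names[k]
           else if (is_singleton[k]) "singleton"
           else "unclassified"
    cluster_family[groups[[k]]] <- lab
  }
  fams <- groups[is_family]
  names(fams) <- fam_names[is_family]
  structure(list(cluster_family = cluster_family,
                 families = fams,
                 family_sizes = setNames(sizes[is_family],
                                         fam_names[is_family])),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("<family_assignment> %d families (%s), %d singletons, %d unclassified clusters\n",
              length(x$families),
              paste(x$family_sizes, collapse = ", "),
              sum(x$cluster_family == "singleton"),
              sum(x$cluster_family == "unclassified")))
  invisible(x)
}

#' Default configuration for the two-stage pipeline
#'
#' The paper-scale thresholds (SSN bit score 110, profile score 160,
#' minimum family size 150) apply to adapter-imported BLAST/HHblits
#' scores.  The internal stand-in scorers use separately calibrated
#' defaults (`internal = TRUE`), documented in the methods vignette:
#' the internal SSN threshold keeps the BLAST-like 110-bit scale, but the
#' internal profile scorer produces smaller scores than HHblits, so its
#' supercluster threshold is lower.
#'
#' @param internal use the internal scorer calibration.
#' @param ... overrides for any config field.
#' @return named list of configuration values.
#' @export
two_stage_config <- function(internal = TRUE, ...) {
  cfg <- list(
    scorer = if (internal) "internal" else "imported",
    ssn_threshold = 110,
    super_threshold = if (internal) 30 else 160,
    min_family_size = 150,
    redundancy_threshold = NULL,
    gap_open = 11, gap_extend = 1,
    beta = 5,
    profile_gap_open = 3.0, profile_gap_extend = 0.3,
    require_both_directions = FALSE,
    blast_edges = NULL, profile_hits = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full two-stage clustering pipeline
#'
#' Optionally redundancy-reduces the input, builds the SSN (from internal
#' all-vs-all alignments or imported BLAST edges), takes connected
#' components as clusters, builds a center-star MSA and a frequency
#' profile per cluster, scores all ordered profile pairs, builds the
#' supercluster network and assigns families.  Deterministic given inputs
#' and config.
#'
#' @param seqs named character vector of protein sequences.
#' @param config a [two_stage_config()] list.
#' @return list of class `two_stage_result` with all intermediates
#'   (`ssn`, `clusters`, `msas`, `profiles`, `profile_hits`, `supernet`,
#'   `families`, `sequence_family`) and a `report` of per-stage counts.
#' @export
run_two_stage <- function(seqs, config = two_stage_config()) {
  if (length(seqs) < 1) gt_stop("input", "no sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    gt_stop("input", "sequences must carry unique ids")
  m <- default_submatrix()
  input_n <- length(seqs)
  red <- NULL
  if (!is.null(config$redundancy_threshold)) {
    red <- withCallingHandlers(
      reduce_redundancy(seqs, config$redundancy_threshold, m),
      error = function(e) gt_stop("input", paste("redundancy stage:",
                                                 conditionMessage(e))))
    seqs <- red$representatives
  }
  # stage 1: SSN
  if (identical(config$scorer, "internal")) {
    if (length(seqs) >= 2) {
      ava <- all_vs_all(seqs, m, config$gap_open, config$gap_extend)
      ssn <- build_ssn(ava$bits, config$ssn_threshold)
    } else {
      ssn <- build_ssn(matrix(0, 1, 1, dimnames = list(names(seqs), names(seqs))),
                       config$ssn_threshold)
    }
  } else {
    if (is.null(config$blast_edges))
      gt_stop("config", "imported scorer requires config$blast_edges")
    ssn <- build_ssn(config$blast_edges, config$ssn_threshold,
                     nodes = names(seqs))
  }
  clusters <- ssn_components(ssn)
  # stage 2: profiles over clusters
  msas <- lapply(clusters$clusters, function(ids)
    center_star_msa(seqs[ids], m, config$gap_open, config$gap_extend))
  profiles <- lapply(names(msas), function(cid)
    build_profile(msas[[cid]], beta = config$beta, id = cid))
  names(profiles) <- names(msas)
  if (identical(config$scorer, "internal") || is.null(config$profile_hits)) {
    cl_ids <- names(profiles)
    hits <- list()
    for (q in cl_ids) for (t in cl_ids) {
      if (q == t) next
      h <- profile_score(profiles[[q]], profiles[[t]],
                         config$profile_gap_open, config$profile_gap_extend)
      hits[[length(hits) + 1L]] <- data.frame(
        query = q, target = t, score = h$score, stringsAsFactors = FALSE)
    }
    hits <- if (length(hits)) do.call(rbind, hits)
            else data.frame(query = character(), target = character(),
                            score = numeric())
  } else {
    hits <- config$profile_hits
  }
  supernet <- build_supercluster_network(clusters, hits,
                                         config$super_threshold)
  families <- assign_families(supernet, config$min_family_size,
                              config$require_both_directions)
  seq_fam <- families$cluster_family[clusters$membership]
  # singleton/unclassified clusters keep distinct partition labels
  anon <- seq_fam %in% c("singleton", "unclassified")
  seq_fam[anon] <- paste0(seq_fam[anon], ":", clusters$membership[anon])
  names(seq_fam) <- names(clusters$membership)
  structure(list(
    ssn = ssn, clusters = clusters, msas = msas, profiles = profiles,
    profile_hits = hits, supernet = supernet, families = families,
    sequence_family = seq_fam,
    redundancy = red,
    config = config,
    report = list(
      n_input = input_n,
      n_representatives = length(seqs),
      n_ssn_edges = igraph::ecount(ssn),
      n_clusters = length(clusters$clusters),
      n_super_edges = igraph::ecount(supernet),
      n_superclusters = length(unique(
        igraph::components(igraph::as_undirected(supernet))$membership)),
      n_families = length(families$families),
      n_singletons = sum(families$cluster_family == "singleton"),
      n_unclassified = sum(families$cluster_family == "unclassified"))),
    class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("<two_stage_result> %d sequences -> %d clusters -> ",
                     "%d superclusters -> %d families (+%d singletons, %d unclassified)\n"),
              r$n_representatives, r$n_clusters, r$n_superclusters,
              r$n_families, r$n_singletons, r$n_unclassified))
  invisible(x)
}
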