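# Seeded generators: protein families with controlled identity, glycan
# repeat units with family-conserved ends, and hierarchical point clouds
# with a planted topology.  All generators are pure functions of their
# arguments (the caller's RNG state is left untouched).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# conditional substitution probabilities P(b | a), b != a, proportional to
# the BLOSUM62 half-bit target frequencies bg(b) * 2^(s(a,b)/2) — mutated
# positions land on plausible homolog residues, not uniform noise
.subst_conditional <- function(m = default_submatrix()) {
  s <- m$matrix[.aa20, .aa20]
  bg <- m$background[.aa20]
  P <- sweep(2^(s / 2), 2, bg, "*")
  diag(P) <- 0
  sweep(P, 1, rowSums(P), "/")
}

#' Generate synthetic protein families
#'
#' Per family, an ancestor is drawn from background amino-acid
#' frequencies and members are derived by seeded point mutation (BLOSUM62
#' conditional substitutions) plus occasional short indels.  Each member
#' independently mutates a fraction `1 - sqrt(within_identity)` of its
#' positions, so two members of a family share about `within_identity`
#' of their positions.  Families descend from independent ancestors, so
#' between-family identity sits near the random-alignment background
#' (roughly 5-15 percent locally); requesting more than that is not
#' supported.
#'
#' @param n_families number of families.
#' @param seqs_per_family members per family.
#' @param ancestor_length ancestor length (>= 50).
#' @param within_identity target within-family pairwise identity in
#'   (0, 1).
#' @param between_identity documented target for between-family identity;
#'   must be below `within_identity` and at most 0.25 (the generator only
#'   produces random-background divergence between families).
#' @param indel_rate per-position probability of an indel event
#'   (insertion or deletion of 1-3 residues).
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector), `labels` (family
#'   per sequence), `realized_within_identity` (measured on sampled
#'   pairs), and the generating `spec`.
#' @export
generate_protein_families <- function(n_families = 3, seqs_per_family = 20,
                                      ancestor_length = 300,
                                      within_identity = 0.45,
                                      between_identity = 0.10,
                                      indel_rate = 0.002, seed = 1) {
  if (ancestor_length < 50) gt_stop("config", "ancestor_length must be >= 50")
  if (within_identity <= 0 || within_identity >= 1)
    gt_stop("config", "within_identity must be in (0, 1)")
  if (between_identity >= within_identity || between_identity > 0.25)
    gt_stop("config",
            "between_identity must be below within_identity and <= 0.25")
  m <- default_submatrix()
  cond <- .subst_conditional(m)
  bg <- m$background[.aa20]
  p_mut <- 1 - sqrt(within_identity)
  with_seed(seed, {
    seqs <- character(0)
    labels <- character(0)
    for (f in seq_len(n_families)) {
      anc <- sample(.aa20, ancestor_length, replace = TRUE, prob = bg)
      for (s in seq_len(seqs_per_family)) {
        x <- anc
        hit <- which(stats::runif(length(x)) < p_mut)
        for (i in hit) x[i] <- sample(.aa20, 1, prob = cond[x[i], ])
        n_indel <- stats::rbinom(1, length(x), indel_rate)
        for (k in seq_len(n_indel)) {
          pos <- sample(length(x), 1)
          len <- sample(1:3, 1)
          if (stats::runif(1) < 0.5 && length(x) > len + 50) {
            x <- x[-(pos:min(pos + len - 1, length(x)))]
          } else {
            ins <- sample(.aa20, len, replace = TRUE, prob = bg)
            x <- append(x, ins, after = pos)
          }
        }
        id <- sprintf("F%d_s%02d", f, s)
        seqs[id] <- paste(x, collapse = "")
        labels[id] <- sprintf("F%d", f)
      }
    }
    # self-validation: realized identity on a sample of within-family pairs
    realized <- local({
      vals <- c()
      for (f in unique(labels)) {
        ids <- names(labels)[labels == f]
        if (length(ids) < 2) next
        take <- utils::head(utils::combn(ids, 2, simplify = FALSE), 10)
        vals <- c(vals, vapply(take, function(p)
          smith_waterman(seqs[[p[1]]], seqs[[p[2]]], m)$identity_fraction, 0))
      }
      mean(vals)
    })
    list(seqs = seqs, labels = labels,
         realized_within_identity = realized,
         spec = list(n_families = n_families,
                     seqs_per_family = seqs_per_family,
                     ancestor_length = ancestor_length,
                     within_identity = within_identity,
                     between_identity = between_identity,
                     indel_rate = indel_rate, seed = seed))
  })
}

# residue vocabulary for the glycan generator: common pyranose parents
# whose ring carbons 2-4 all carry a linkable oxygen in the stereo table
.glycan_parents <- c("Glc", "Gal", "Man", "Rha", "Fuc", "Xyl")

.random_glycan_residue <- function() {
  list(parent = sample(.glycan_parents, 1),
       config = sample(c("D", "L"), 1),
       anomeric = sample(c("alpha", "beta"), 1))
}

.render_glycan <- function(res, acc) {
  # res[[1]] = reducing end; acc[i] = acceptor carbon on residue i for the
  # bond arriving from residue i+1; acc[n] = polymerase acceptor carbon
  n <- length(res)
  fmt <- function(r) sprintf("%s-%s-%sp",
                             c(alpha = "a", beta = "b")[r$anomeric],
                             r$config, r$parent)
  parts <- sprintf("→%d)", acc[n])
  for (i in n:2) parts <- c(parts, sprintf("%s-(1→%d)", fmt(res[[i]]), acc[i - 1]))
  parts <- c(parts, sprintf("%s-(1→", fmt(res[[1]])))
  paste(parts, collapse = "-")
}

#' Generate synthetic glycan repeat-unit families
#'
#' Per family a template repeat unit is drawn (backbone length uniform in
#' `length_range`, pyranose residues, linkage carbons in 2-4); members
#' copy the template's end residues with probability `end_conservation`
#' and resample each interior residue with probability
#' `middle_variability` — emulating repeat units whose -1/+1 subsites are
#' conserved within a polymerase family while the middle varies.  The
#' reducing-end anomeric configuration (hence the polymerase bond
#' geometry and inferred mechanism) is always conserved within a family.
#'
#' @param n_families number of families.
#' @param units_per_family members per family.
#' @param length_range backbone length range, within \[2, 12\] (default
#'   3-7).
#' @param end_conservation probability that a member keeps the template's
#'   end residues and linkage carbons.
#' @param middle_variability per-residue resampling probability for
#'   interior positions.
#' @param seed RNG seed.
#' @return list with `units` (named character vector of parseable glycan
#'   strings), `labels`, and `spec`.
#' @export
generate_glycan_families <- function(n_families = 3, units_per_family = 10,
                                     length_range = c(3, 7),
                                     end_conservation = 0.9,
                                     middle_variability = 0.5, seed = 1) {
  if (length_range[1] < 2 || length_range[2] > 12 ||
      length_range[1] > length_range[2])
    gt_stop("config", "length_range must lie within [2, 12]")
  with_seed(seed, {
    units <- character(0)
    labels <- character(0)
    for (f in seq_len(n_families)) {
      n <- sample(length_range[1]:length_range[2], 1)
      t_res <- lapply(seq_len(n), function(i) .random_glycan_residue())
      t_acc <- sample(2:4, n, replace = TRUE)
      for (u in seq_len(units_per_family)) {
        res <- t_res
        acc <- t_acc
        if (stats::runif(1) > end_conservation) {
          # resample the end positions, preserving the polymerase bond
          # anomeric configuration carried by the reducing-end residue
          keep_anomer <- res[[1]]$anomeric
          keep_config <- res[[1]]$config
          res[[1]] <- .random_glycan_residue()
          res[[1]]$anomeric <- keep_anomer
          res[[1]]$config <- keep_config
          if (n > 1) res[[n]] <- .random_glycan_residue()
          acc[1] <- sample(2:4, 1)
          acc[n] <- sample(2:4, 1)
        }
        if (n > 2) for (i in 2:(n - 1)) {
          if (stats::runif(1) < middle_variability) {
            res[[i]] <- .random_glycan_residue()
            acc[i] <- sample(2:4, 1)
          }
        }
        id <- sprintf("G%d_u%02d", f, u)
        units[id] <- .render_glycan(res, acc)
        labels[id] <- sprintf("G%d", f)
      }
    }
    list(units = units, labels = labels,
         spec = list(n_families = n_families,
                     units_per_family = units_per_family,
                     length_range = length_range,
                     end_conservation = end_conservation,
                     middle_variability = middle_variability, seed = seed))
  })
}

#' Generate hierarchical point clouds with a planted topology
#'
#' Builds a random balanced binary hierarchy over
#' `n_clades * points_per_clade` leaves by recursive bisection: each
#' split displaces its two halves in opposite random directions, with the
#' displacement shrinking by the factor `separation` at every level.  The
#' result is an exactly Euclidean distance matrix whose true tree is
#' known, for testing embedding and joining.
#'
#' @param n_clades number of top-level clades (a power of 2 gives a
#'   perfectly balanced top level).
#' @param points_per_clade leaves per clade.
#' @param separation scale ratio between successive hierarchy levels
#'   (sibling separation over within-subtree spread); 10 gives clean
#'   recovery.
#' @param seed RNG seed.
#' @param dim ambient dimension (default 10, capped by the embedding).
#' @return list with `dist` (Euclidean distance matrix), `coords`,
#'   `newick` (planted topology with branch lengths), `labels` (clade of
#'   each leaf).
#' @export
generate_hierarchical_points <- function(n_clades = 3, points_per_clade = 8,
                                         separation = 10, seed = 1,
                                         dim = 10) {
  if (separation <= 1) gt_stop("config", "separation must exceed 1")
  n <- n_clades * points_per_clade
  with_seed(seed, {
    leaves <- sprintf("p%03d", seq_len(n))
    build <- function(names_, scale) {
      k <- length(names_)
      if (k == 1)
        return(list(coords = matrix(0, 1, dim, dimnames = list(names_, NULL)),
                    newick = names_[1]))
      half <- ceiling(k / 2)
      u <- stats::rnorm(dim)
      u <- u / sqrt(sum(u^2)) * scale / 2
      L <- build(names_[seq_len(half)], scale / separation)
      R <- build(names_[(half + 1):k], scale / separation)
      coords <- rbind(sweep(L$coords, 2, u, "+"),
                      sweep(R$coords, 2, u, "-"))
      list(coords = coords,
           newick = sprintf("(%s:%g,%s:%g)", L$newick, scale / 2,
                            R$newick, scale / 2))
    }
    # top level: clade centers on one axis at geometrically increasing
    # spacing, so nearest clades always merge left-first and the planted
    # left-nested chain is the unique nearest-neighbour topology
    clades <- split(leaves, rep(seq_len(n_clades), each = points_per_clade))
    sub <- lapply(clades, function(cl) build(cl, 1))
    coords <- do.call(rbind, lapply(seq_len(n_clades), function(i) {
      center <- c(separation * 3^i, rep(0, dim - 1))
      sweep(sub[[i]]$coords, 2, center, "+")
    }))
    coords <- coords[leaves, , drop = FALSE]
    nwk <- sub[[1]]$newick
    for (i in seq_len(n_clades)[-1])
      nwk <- sprintf("(%s:%g,%s:%g)", nwk, separation,
                     sub[[i]]$newick, separation)
    d <- as.matrix(stats::dist(coords))
    dimnames(d) <- list(leaves, leaves)
    list(dist = d, coords = coords,
         newick = paste0(nwk, ";"),
         labels = setNames(rep(sprintf("clade%d", seq_len(n_clades)),
                               each = points_per_clade), leaves))
  })
}
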