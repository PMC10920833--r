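# Stereochemistry table: ring-substituent orientations used to translate
# monosaccharides into backbone geometry tokens.
#
# Convention: orientations are read off the standard Haworth projection of
# the D-sugar (ring oxygen at the back right, C1 rightmost).  A hydroxyl
# that sits on the right in the D-Fischer projection points below the ring
# plane in Haworth ("D"); on the left, above ("U").  Exocyclic carbons
# (e.g. C6 of a hexopyranose) are conformationally flexible and map to
# "N".  L-sugars are the mirror image: every U/D flips, N is unchanged.

# D-Fischer OH orientations for the parent aldoses, carbons 2..4,
# expressed directly as Haworth U/D of the D-form.
.fischer_ud <- list(
  #        C2   C3   C4
  Glc = c("D", "U", "D"),
  Gal = c("D", "U", "U"),
  Man = c("U", "U", "D"),
  All = c("D", "D", "D"),
  Alt = c("U", "D", "D"),
  Gul = c("D", "D", "U"),
  Ido = c("U", "D", "U"),
  Tal = c("U", "U", "U"),
  Rha = c("U", "U", "D"),   # 6-deoxy-Man
  Fuc = c("D", "U", "U"),   # 6-deoxy-Gal
  Qui = c("D", "U", "D"),   # 6-deoxy-Glc
  Xyl = c("D", "U", "D"),
  Ara = c("U", "D", "D"),
  Rib = c("D", "D", "D"),
  Lyx = c("U", "U", "D")
)

.hexoses  <- c("Glc", "Gal", "Man", "All", "Alt", "Gul", "Ido", "Tal")
.deoxyhex <- c("Rha", "Fuc", "Qui")
.pentoses <- c("Xyl", "Ara", "Rib", "Lyx")

# Residue names accepted by the parser, mapped to the stereo parent whose
# ring geometry they share, plus the substituents implied by the name.
# Substituents are carried on the residue record but never influence
# backbone tokens.
.parent_map <- local({
  m <- list()
  for (p in names(.fischer_ud)) m[[p]] <- list(parent = p, subst = list())
  uronic <- function(p) list(parent = p, subst = list(c(6L, "A")))
  amino  <- function(p) list(parent = p, subst = list(c(2L, "N")))
  nac    <- function(p) list(parent = p, subst = list(c(2L, "NAc")))
  m$GlcA <- uronic("Glc"); m$GalA <- uronic("Gal"); m$ManA <- uronic("Man")
  m$GlcN <- amino("Glc");  m$GalN <- amino("Gal");  m$ManN <- amino("Man")
  m$GlcNAc <- nac("Glc"); m$GalNAc <- nac("Gal"); m$ManNAc <- nac("Man")
  m$FucNAc <- nac("Fuc"); m$QuiNAc <- nac("Qui")
  # open-chain polyols occurring in phosphodiester-containing backbones
  m$Gro <- list(parent = "Gro", subst = list(), open = TRUE)
  m$Rbo <- list(parent = "Rbo", subst = list(), open = TRUE)
  m
})

.build_ring_entries <- function() {
  rows <- list()
  add <- function(parent, ring, carbon, orient)
    rows[[length(rows) + 1L]] <<- data.frame(
      parent_sugar = parent, ring_form = ring, carbon = carbon,
      config = "D", orientation = orient, stringsAsFactors = FALSE)
  for (p in c(.hexoses, .deoxyhex)) {
    ud <- .fischer_ud[[p]]
    for (k in 2:4) add(p, "p", k, ud[k - 1L])
    if (p %in% .hexoses) add(p, "p", 6L, "N")   # exocyclic
    # hexofuranose: ring closes at C4; C2, C3 keep Fischer geometry,
    # C5 and C6 hang off the ring
    for (k in 2:3) add(p, "f", k, ud[k - 1L])
    add(p, "f", 5L, "N")
    if (p %in% .hexoses) add(p, "f", 6L, "N")
  }
  for (p in .pentoses) {
    ud <- .fischer_ud[[p]]
    for (k in 2:4) add(p, "p", k, ud[k - 1L])
    for (k in 2:3) add(p, "f", k, ud[k - 1L])
    add(p, "f", 5L, "N")                        # exocyclic in the furanose
  }
  do.call(rbind, rows)
}

#' Built-in stereochemistry table
#'
#' Returns the orientation table used to translate sugar residues into
#' backbone geometry tokens: for each (parent sugar, ring form, carbon,
#' absolute configuration) the orientation of the attached oxygen relative
#' to the ring plane — `U` (above), `D` (below) or `N` (neither, i.e.
#' conformationally flexible exocyclic positions and open-chain polyols).
#' Only D-form entries are stored; L-sugar lookups mirror U and D.
#'
#' @param override_tsv optional path to a TSV with columns
#'   `parent_sugar`, `ring_form`, `carbon`, `config`, `orientation`;
#'   rows replace or extend the built-in entries.
#' @return an object of class `stereo_table`.
#' @export
default_stereo_table <- function(override_tsv = NULL) {
  ring <- .build_ring_entries()
  if (!is.null(override_tsv)) {
    ov <- read_tsv_strict(override_tsv,
      c("parent_sugar", "ring_form", "carbon", "config", "orientation"))
    bad <- !ov$orientation %in% c("U", "D", "N")
    if (any(bad))
      gt_stop("parse", sprintf("stereo override: bad orientation '%s'",
                               ov$orientation[which(bad)[1]]))
    # L-form overrides are stored mirrored so the lookup stays D-keyed
    flip <- ov$config == "L"
    ov$orientation[flip] <- chartr("UD", "DU", ov$orientation[flip])
    ov$config <- "D"
    key <- function(df) paste(df$parent_sugar, df$ring_form, df$carbon)
    ring <- rbind(ring[!key(ring) %in% key(ov), ], ov)
  }
  structure(list(ring = ring, parents = .parent_map), class = "stereo_table")
}

#' @export
print.stereo_table <- function(x, ...) {
  cat(sprintf("<stereo_table> %d ring-position entries, %d residue names\n",
              nrow(x$ring), length(x$parents)))
  invisible(x)
}

# orientation of the oxygen at `carbon` of a residue; errors carry the
# (sugar, carbon) pair per the module contract
stereo_orientation <- function(table, parent, ring_form, carbon, config) {
  if (ring_form == "open") return("N")
  hit <- table$ring$parent_sugar == parent &
    table$ring$ring_form == ring_form & table$ring$carbon == carbon
  if (!any(hit))
    gt_stop("stereotable",
            sprintf("no stereochemistry entry for %s%s carbon %d",
                    parent, ring_form, carbon),
            sugar = parent, carbon = carbon)
  o <- table$ring$orientation[which(hit)[1]]
  if (identical(config, "L")) o <- chartr("UD", "DU", o)
  o
}

# orientation of the anomeric oxygen: alpha-D is below the ring, beta-D
# above; L mirrors
anomeric_orientation <- function(config, anomeric) {
  if (identical(anomeric, "none")) return("N")
  stopifnot(anomeric %in% c("alpha", "beta"))
  o <- if (anomeric == "alpha") "D" else "U"
  if (identical(config, "L")) o <- chartr("UD", "DU", o)
  o
}

# axial/equatorial geometry of a glycosidic bond at the anomeric carbon:
# alpha is axial for D-sugars, beta is axial for L-sugars
bond_geometry_of <- function(config, anomeric) {
  if (identical(anomeric, "none") || identical(config, "none"))
    gt_stop("mechanism",
            "bond geometry undefined without an anomeric configuration")
  axial <- (anomeric == "alpha" && config == "D") ||
           (anomeric == "beta"  && config == "L")
  if (axial) "axial" else "equatorial"
}
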