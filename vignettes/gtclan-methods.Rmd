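---
title: "Methods: clustering divergent polysaccharide polymerases and scoring their glycans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering divergent polysaccharide polymerases and scoring their glycans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtclan)
```

# The problem

Bacterial polysaccharide polymerases (Wzy-type BP-Pols) polymerize
lipid-linked oligosaccharide repeat units into O-antigens and capsules.
They are integral membrane proteins with highly variable numbers of
transmembrane helices, and their sequences diverge so far — identities
below 20% even within one species — that neither global alignment nor a
single similarity cutoff produces defensible families. gtclan
implements a classification stack for this regime: a two-stage
clustering that combines a strict sequence similarity network with
profile-level comparison of the resulting clusters, a tree algorithm
robust to long inter-group distances, and a reduced-alphabet similarity
score for the repeat units the enzymes act on, including inference of
the reaction stereochemistry.

# Two-stage clustering

**Stage 1 (SSN).** All-vs-all local alignments give pairwise bit scores
`(λ·raw − ln K)/ln 2`; sequences are nodes and an edge joins a pair iff
its bit score is *strictly above* the SSN threshold. Clusters are the
connected components, numbered by decreasing size (ties by smallest
member id). A strict threshold deliberately over-fragments: each
cluster is homogeneous enough for a trustworthy MSA.

**Stage 2 (profiles).** Each cluster gets a center-star MSA and a
frequency profile with background-mix pseudocounts,
`f_j(a) = (n_j(a) + β·bg(a)) / (n_j + β)` with β = 5 by default; gaps
are excluded from the residue count and tracked as a per-column gap
fraction. Ordered cluster pairs are scored by local alignment over
column pairs with the score
`s(q_i→t_j) = Σ_a f_q(a) log2(f_t(a)/bg(a))` in bits (affine gaps, 3.0
open / 0.3 extend bits). The score is directional by construction —
the query's frequencies against the target's log-odds — mirroring the
asymmetry of profile-HMM comparison tools; symmetrization is left to
the network layer. A directed edge requires the score strictly above
the supercluster threshold; superclusters are components of the
undirected support (one direction suffices by default;
`require_both_directions = TRUE` keeps only reciprocated edges).
Superclusters whose summed sequence count strictly exceeds
`min_family_size` become families; an edgeless single cluster is a
*singleton* whatever its size (families only ever arise from
superclusters); everything else is unclassified.

**Thresholds.** For adapter-imported BLAST/HHblits scores the defaults
are the established working points for this enzyme class: SSN > 110
bits, profile score > 160, family size > 150. The internal stand-in
scorers are calibrated separately (`two_stage_config(internal = TRUE)`):
the internal Smith–Waterman uses BLOSUM62 with gap open 11 / extend 1
and the standard gapped Karlin–Altschul parameters (λ = 0.267,
K = 0.041), so its bit scale matches BLAST and the 110-bit SSN default
carries over; the internal profile scorer, however, produces
column-log-odds totals far smaller than HHblits scores, so its
supercluster default is 30 bits. That constant was fixed once against
the synthetic world described below (same-family cluster pairs score in
the tens-to-hundreds of bits, unrelated families ≤ ~6) and is a
calibration of this package, not a literature value.

**Redundancy reduction.** A greedy longest-first pass mimics CD-HIT:
each sequence joins the first representative with identity (matches
over the shorter sequence length) at or above the threshold (default
0.95), else founds a new representative.

# The Aclust tree algorithm

1. *Distances.* A Scoredist-style transform of the local alignment
   score, normalized to the shorter sequence length rather than the
   alignment length: with σ_r = min(len_a, len_b) × (expected
   per-position score of BLOSUM62 under background frequencies),
   σ_n = raw − σ_r and σ_u = (self_a + self_b)/2 − σ_r, the distance is
   −100·ln(σ_n/σ_u), capped at d_max = 300 when σ_n ≤ 0. Scoredist's
   1.337 calibration factor is deliberately omitted (the distance is a
   "variation of Scoredist" without it). These distances need not obey
   the triangle inequality, and nothing downstream assumes they do.
2. *Embedding.* Classical metric-matrix distance geometry:
   `B = −½ J D² J`, eigendecomposition, coordinates = eigenvectors
   scaled by √eigenvalue. Dimensions with eigenvalues ≤ 1e-9 × the
   largest are dropped (cap: 20 dimensions); negative eigenvalue mass —
   the signature of non-metric input — is dropped, never reflected, and
   reported on the result. Consequence worth knowing: if the input
   mixes scales across more than ~4 orders of magnitude, genuinely
   Euclidean fine structure below the relative cutoff is discarded too;
   the embedding is exact (round-trip ≤ 1e-8) for well-conditioned
   Euclidean matrices, and the recursion below is what restores local
   accuracy in the mixed-scale case.
3. *Joining.* Nearest-neighbour joining in the coordinate space: the
   closest active pair is replaced by its leaf-count-weighted centroid;
   branch lengths are the Euclidean child-to-centroid distances (hence
   never negative); distance ties break toward the lowest id-sorted
   pair, making the tree a deterministic function of the input. The
   last centroid created is the root. The weighted centroid was chosen
   so that an internal node sits at the centroid of *all* its leaves,
   which makes the single-pass and recursive constructions agree on
   balanced data; an unweighted mode is available.
4. *Recursion.* The root's two leaf sets are re-embedded from their own
   sub-matrices, rebuilt, and refined recursively; subtrees with fewer
   than `min_leaves = 4` leaves are kept (joining ≤ 3 points is already
   optimal). The root join between refined subtrees is recomputed from
   the subtree leaf centroids in the full embedding at that level —
   branch lengths come from coordinate geometry, not from re-reading
   the distance matrix. Refinement is idempotent. The recursion
   terminates on the size bound, not a convergence test: each level
   strictly reduces the leaf set, and below 4 leaves nothing changes.

# Glycan backbone translation and score

**Grammar.** Repeat units are written non-reducing end first, e.g.
`→3)-β-D-Galp-(1→3)-α-D-Glcp-(1→4)-α-D-Glcp-(1→`; the trailing `(1→`
is the bond the polymerase forms from the reducing-end residue (the one
on the Und-PP carrier) to the carbon named in the leading `→3)` of the
next unit. Sidechains sit in square brackets; their final linkage names
the attachment carbon on the residue that follows. Substituent
suffixes (`2Ac`, …) and amino/uronic name variants (GlcNAc, GlcA, …)
are parsed and carried but never scored. `->`, `a-`, `b-` are accepted
ASCII spellings.

**Translation.** The backbone is the unique bond-tree path from the
Und-PP residue to the polymerase-bond acceptor; each backbone residue
becomes one token `class:carbon orient:carbon orient` — ring class P/F/L,
the donor (anomeric) carbon with its oxygen orientation, and the
acceptor carbon with its orientation. Orientations follow a fixed,
documented convention: in the Haworth projection of the D-sugar (ring
oxygen back right, C1 rightmost) an oxygen on the Fischer right points
down (D), on the left up (U); L-sugars mirror every U/D; exocyclic
carbons (C6 of a pyranose, C5/C6 of a furanose) and open-chain polyols
(glycerol, ribitol) are N, encoding their conformational flexibility.
The anomeric orientation is α-D→D, β-D→U, α-L→U, β-L→D. The full
published convention for these tokens is not yet available, so the
built-in table is explicit and overridable via TSV
(`default_stereo_table(override_tsv=)`); two residues only ever score
as identical when their *entire* tokens match. Phosphodiester-linked
linear residues count as backbone positions of class L with N
orientations; the phosphate itself is not a position — these groups are
tolerated backbone variability, not stereocenters.

**Score.** Let −k count backbone positions from the reducing end and
+k from the non-reducing end. If the −1 or +1 tokens differ the score
is 0; otherwise it starts at 2 with those residues marked used, and
extension proceeds in rounds k = 2, 3, …, testing +k *then* −k; each
identical token adds 1 and marks the underlying residues of both
strings used. The whole comparison terminates at the first mismatch,
missing subsite, or attempted re-use of an already-used residue (the +
and − walks meeting mid-string). Hence the score lies in {0} ∪ {2, …,
min(n_a, n_b)}, is symmetric, equals n for an n-residue string against
itself, and can never be 1. An alternative reading — continuing the −
direction after a + failure — exists; the implemented global
termination is the one that reproduces the published worked values
(2, 5 and 7) and is the only mode offered. Backbones of length 1 are
rejected (`unsupported` error): the score is defined around a bond with
two sides.

**Mechanism.** Repeat units sit on Und-PP through an axial anomeric
bond (α for D, β for L sugars). If the bond the polymerase forms is
also axial, configuration is preserved — retaining; if equatorial —
inverting. An open-chain reducing-end residue has no anomeric center
and yields an `undetermined-mechanism` error rather than a guess.

# Synthetic data: what it emulates, and what a green test does not show

`generate_protein_families()` draws one ancestor per family from
background residue frequencies and mutates each member independently:
a fraction `1 − √w` of positions substituted according to
BLOSUM62-compatible conditional frequencies (so mutated positions look
like homologous drift, and pairwise member identity lands near the
target `w`), plus rare short indels (default 0.002/position, 1–3
residues). Defaults — 3 families × 20 members, length 300, within
identity 0.45 — represent the regime the classification addresses:
clearly homologous within a family, random-background similarity
(~5–15% local identity) between families. It does **not** emulate
shared transmembrane architecture, compositional bias, or the residual
inter-family similarity that real BP-Pol clans show; a perfect ARI on
this world demonstrates the pipeline's mechanics (thresholding,
components, profile merging), not its discrimination at the hard
boundary the real data occupy.

`generate_glycan_families()` draws a template backbone per family
(length 3–7, pyranose residues, linkage carbons 2–4) and copies ends
with probability `end_conservation` (default 0.9) while resampling
middles with probability `middle_variability` (default 0.5) — the
conserved-ends/variable-middle pattern expected when the enzyme grips
only the residues flanking the bond it makes. The reducing-end
anomeric configuration is always family-conserved, so the inferred
mechanism is constant per family by construction; the corresponding
test checks the inference plumbing, not a biological discovery.

`generate_hierarchical_points()` builds a balanced random bisection
hierarchy whose displacement shrinks by the `separation` factor
(default 10) per level, with clade centers collinear at geometrically
increasing spacing — by construction the planted tree is the unique
nearest-neighbour topology and the distance matrix is exactly
Euclidean. Real Scoredist matrices are neither; the non-metric path is
exercised separately via the negative-eigenvalue accounting.

All generators restore the caller's RNG state and are pure functions of
their arguments.

# Numerical choices and degenerate inputs

- Thresholds are strict (`>`) everywhere, including `min_family_size`.
- Gap cost convention: a gap of length L costs open + L·extend
  (BLAST-style), identically in the residue, profile and oracle DPs.
- Local alignments with no positive-scoring path report score 0 and an
  empty aligned-pair set; identity is counted over aligned residue
  pairs only.
- `scoredist_variant()` errors (`degenerate`) when the mean self-score
  does not exceed the expected random score; σ_n ≤ 0 saturates at
  d_max = 300.
- A single point embeds to a 0-dimensional coordinate set; coincident
  points likewise (not an error).
- Distance and similarity ties break on sorted ids; the whole pipeline
  is deterministic for a fixed input order, and family recovery is
  input-order invariant.
- All classed errors carry a `gtclan_<class>_error` condition class;
  the CLI maps them to a single `class: message` line on stderr and a
  nonzero exit status.

# Known limitations

- The profile scorer is a frequency-profile stand-in: no transition
  probabilities, no context-specific pseudocounts, so its scores are
  not comparable to HHblits numbers (hence the separate internal
  threshold). Real HHblits output should be imported through
  `parse_profile_scores()` when available.
- The glycan grammar covers the IUPAC-condensed subset needed for
  repeat units of the common parents (hexoses, 6-deoxyhexoses,
  pentoses, their amino/uronic derivatives, glycerol/ribitol); it is
  not a general glycan parser (no ketoses, no sialic acids, no
  repeating branches).
- Branched sidechains are parsed but never scored; two units differing
  only in sidechains are identical to the score by design.
- The center-star MSA is a desk-scale device; for production MSAs use
  an external aligner and feed the alignment in via `read_msa()`.
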