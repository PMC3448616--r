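---
title: "Methods: pharmacophore screening, field rescoring and scaffold-novelty analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore screening, field rescoring and scaffold-novelty analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytophore)
```

This vignette is the package's own account of its models and numerical
choices: what each stage of the screening funnel computes, which
parameters matter and why their defaults were chosen, what the
synthetic fixtures do and do not demonstrate, and where the design was
genuinely open.

## The screening model

The engine implements a four-stage virtual-screening funnel for
DPP-IV-inhibitor candidates. The object passed down the funnel is the
molecule; a molecule survives a stage if *at least one* of its
conformers or docked poses passes that stage's filter, and survivor id
sets are nested by construction.

### Pharmacophore matching

A pharmacophore here is a set of typed feature points — kinds
`positive_or_donor`, `acceptor`, `hydrophobic_or_aromatic` — each with a
3D center, a spherical matching tolerance, and a mandatory flag, plus a
set of excluded-volume spheres derived from receptor heavy atoms. The
DPP-IV-style model has two mandatory features (the positive/donor anchor
for the Glu205/Glu206 dyad and the S1-pocket ring) and five optional
ones (two acceptors, three rings). Acceptance requires every mandatory
feature and at least one optional feature to be matched.

Ligand features are perceived by rule: one feature per aromatic ring at
its centroid (aromaticity by a Hückel-style π-electron count on
5/6-membered rings of C/N/O/S), `positive_or_donor` on positively
charged or H-bearing N/O atoms, `acceptor` on N/O atoms that are not
positively charged and do not donate their lone pair into an aromatic
ring. The perception order is deterministic (kind, then atom index).

Matching enumerates kind-compatible feature correspondences
depth-first, pruned by pairwise-distance compatibility (the gap between
intra-model and intra-ligand feature distances must not exceed the two
tolerances combined — exact in static mode, admissible in reorienting
mode). For each complete correspondence the least-squares rigid
superposition (Kabsch, SVD with reflection guard) is solved — or the
identity transform is kept in the no-reorientation mode used for docked
poses — and the correspondence is accepted if every matched pair lands
within its feature tolerance and no ligand heavy atom falls strictly
inside an excluded sphere. Among accepted correspondences the best is
chosen by most features matched, then lowest RMSD, then a lexicographic
tie-break for full determinism.

Defaults: feature tolerance 2.0 Å (the conventional matching radius of
structure-based screening tools), excluded-sphere radius 1.5 Å. Both
are per-feature data in the definition file, not hidden constants.
"Steric collision" is operationalized as a heavy-atom *center* inside a
sphere; an alternative reading (van-der-Waals-inflated spheres) would
only rescale the shipped radii.

### Shape similarity

Shape uses the standard analytic Gaussian-overlap formulation: each
heavy atom is a spherical Gaussian of amplitude $p = 2.7$ with exponent
$\alpha_i = \pi\,(3p/4\pi R_i^3)^{2/3}$, chosen so the Gaussian
integrates to the atom's hard-sphere van der Waals volume (Bondi
radii). First-order pairwise overlaps give
$V_{AB} = \sum_{i \in A}\sum_{j \in B} p^2 (\pi/(\alpha_i+\alpha_j))^{3/2}
\exp(-\tfrac{\alpha_i\alpha_j}{\alpha_i+\alpha_j} d_{ij}^2)$ and the
shape Tanimoto $ST = V_{AB}/(V_{AA}+V_{BB}-V_{AB})$, which is 1 exactly
for identical shapes. The closed form is cross-checked in the test
suite against numeric 3D quadrature of the Gaussian products (≤ 1%
on ≤ 5-atom systems).

### Electrostatic similarity

The electrostatic Tanimoto compares potential fields sampled on a
common regular grid: $ET = O_{AB}/(O_{AA}+O_{BB}-O_{AB})$ with
$O_{XY}$ the voxel-wise inner product. It is 1 for identical fields,
scale-invariant under a common positive factor, and negative when
positive and negative regions overlap. The potential is a Coulomb sum
$V(\mathbf{x}) = \sum_i q_i/(\varepsilon(r_i)\,r_i)$ with the
distance-dependent dielectric $\varepsilon(r) = 4r$ — a standard fast
continuum surrogate. A full Poisson–Boltzmann solver would change the
absolute field values but not the comparison contract (identity = 1,
opposition < 0), and the grid/scoring interface accepts any
externally computed `field_grid`, so a PB backend can be plugged in.

Numerical choices: grid spacing 0.5 Å, padding 4 Å around the union of
both molecules, distances clamped at 1.0 Å in the denominator, and
voxels closer than 1.2 Å to any nucleus of either molecule masked from
the comparison. Clamping and masking remove the nuclear singularity,
which would otherwise dominate the inner products with arbitrarily
large, physically meaningless values.

### Thresholds

The funnel's final filter keeps a molecule when some pose satisfies
`ET_pb ≥ 0.468` and `ST ≥ 0.237` (inclusive comparisons). These shipped
defaults are the published operating point of the DPP-IV screen and are
deliberately *not* re-derived under this package's field model — the
original values came from a different electrostatics engine.
`calibrate_thresholds()` re-derives an operating point as the panel
minimum of scores of known-inhibitor poses against the reference: the
most permissive thresholds that still accept every known inhibitor,
which is the natural operational reading of calibrating "from a panel".
Whether the original calibration used the minimum, a percentile, or
hand adjustment is not documented; the panel minimum is the
reproducible choice.

### Partial charges and protonation

Input preparation assigns the dominant protonation state at pH 7 by
rule: protonate aliphatic amines and the imine nitrogen of
amidines/guanidines, deprotonate carboxylic and sulfonic acids; no
tautomer enumeration. Anilines, amides and azaaromatic nitrogens are
left untouched. This replaces a commercial preparation tool with the
minimal chemistry the screen needs: a defensible charged-state call for
the donor/positive pharmacophore feature and the field signs.

Partial charges default to Open Babel's MMFF94 assignment. MMFF94 was
chosen over the also-available Gasteiger scheme because the Gasteiger
implementation is σ-only and does not conserve the net formal charge of
ions (a benzylammonium cation sums to ≈ 0 rather than +1), while charge
conservation is an invariant this package enforces — every charge
vector is additionally renormalized by a uniform shift so its sum
equals the net formal charge exactly. Gasteiger and EEM remain
selectable.

### Conformers and 3D structure

Coordinates are built deterministically from internal coordinates:
planar regular polygons for rings (fused rings share edges in-plane),
hybridization-ideal angles elsewhere, covalent-radius bond lengths.
Conformers come from a systematic torsion driver over rotatable bonds
(120° grid, deterministically subsampled through the seed when the
grid exceeds 729 combinations), ranked by a capped pairwise
steric-repulsion score; the default cap of 200 conformers per molecule
mirrors common screening practice of raising the tool default.
Identical inputs give byte-identical coordinates — reproducibility was
preferred over force-field-quality geometry, which the matching and
scoring stages (tolerances ≥ 2 Å, Gaussian-smoothed shapes) do not
require. Bridged and spiro ring systems are rejected with a
per-molecule error rather than embedded badly.

## Scaffold clustering

MOLPRINT2D fingerprints encode, for every heavy atom, its type
(element + aromaticity) and the sorted counts of neighbour types at
topological distances 1 and 2; each environment string is hashed with a
32-bit FNV-1a and the fingerprint is the *set* of hashes — matching the
cited "32-bit precision" option semantics, with hash collisions
accepted. Set (not count) Tanimoto is the cited convention.

Clustering is agglomerative on `1 − Tanimoto`; the linkage is not
documented in the original analysis, so the default is group-average —
standard for fingerprint clustering and well-behaved under Kelley
selection — with complete and single linkage selectable. Inputs are
sorted by molecule id before agglomeration, making the dendrogram
invariant to input order.

The Kelley criterion scans the partitions with $k = 2 \dots n-1$
clusters: for each, the spread is the mean over multi-member clusters
of their mean pairwise distance; spreads are min–max normalized onto
$[1, N_{\text{levels}}]$ and the level minimizing
$\text{normalized spread} + k$ is chosen, ties toward fewer clusters.
When every level has the same spread the normalization degenerates and
the penalty reduces to $1 + k$, again selecting the coarsest level.
The all-singleton and single-cluster partitions carry no comparable
spread and are excluded from the scan. Novelty flags are the exact
complement test: a cluster is novel iff it contains no reference-set
member.

## Synthetic fixtures: what they show and what they do not

`make_funnel_library` builds molecules *directly in the model frame*
with planted outcomes: passers carry an aromatic ring, an amine
nitrogen and a carbonyl oxygen exactly on (jittered within 0.12 Å of)
the model's feature centers with reference-like charges; stage-1
failures present only the two mandatory sites; static failures are
rigidly displaced docked poses of otherwise-passing molecules; and
threshold failures have their planted charge pattern negated, which
drives `ET_pb` below zero while leaving the shape score untouched —
charge scaling, not geometry, is the lever, so the two threshold
conditions are tested independently. Because fixtures are built
in-frame, the docking stage is exercised through the provider interface
without any external docking tool.

`make_scaffold_collection` decorates tricyclic cores from well-
separated chemotype classes (aza-aromatic, N/O/S-aliphatic) with a
single varying head atom behind a constant ethylene linker. This makes
every within-family pair differ by a constant-size environment set, so
within-family distances are uniform — for the two leading cores exactly
equal — which keeps the Kelley spread profile flat across fine levels
and the family partition optimal. The generator asserts at build time
that within-family similarity strictly exceeds every between-family
similarity and refuses non-separable requests. Two fingerprint
pathologies drove this design and are worth knowing about: set-based
environment fingerprints collapse homologous n-alkyl decorations
(pentyl and hexyl give identical hash sets), and benzo-fused aromatics
share their far-ring environments almost entirely.

What passing these suites shows: the filters, scores, accounting and
level selection behave exactly as specified on inputs with known
ground truth. What it does not show: performance on real phytochemical
space — real conformer ensembles are larger and noisier, real charge
distributions are not planted, real scaffold families are not
equidistant, and real docking poses carry docking error. The funnel
counts of the original campaign are documented as non-reproducible
(proprietary inputs, commercial engines) and are not a test surface.

## Problem sizes

The shipped test suite exercises funnel libraries up to 100 molecules
across five seeds, quadrature oracles on ≤ 5-atom systems with 0.15 Å
grids, clustering oracles at n ≤ 8 against an O(n³) re-implementation,
and scaffold collections of 2–5 families; the full suite runs in well
under a minute on one CPU. These sizes were chosen to keep every oracle
exhaustive (brute-force enumeration stays exact) while covering the
combinatorial paths of the matcher and the funnel.

## Known limitations

- The rule-based 3D builder targets screening-grade, reproducible
  geometry; torsion strain and ring puckering are approximate, and
  bridged/spiro systems are not embedded.
- The Coulomb/4r field is a surrogate for Poisson–Boltzmann
  electrostatics; absolute `ET_pb` values are not comparable across
  field models, which is why the shipped thresholds are documented as
  the published operating point rather than re-derived.
- Aromaticity perception covers 5/6-membered C/N/O/S rings; exotic
  ring systems fall back to non-aromatic treatment.
- The pharmacophore definition shipped under `inst/extdata` is a
  synthetic stand-in with the published topology; users screening
  against a real receptor should derive feature coordinates from their
  own structure and `derive_excluded_volumes()` from its PDB file.
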