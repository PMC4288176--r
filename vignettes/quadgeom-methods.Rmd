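---
title: "Geometric analysis of G-quadruplex structures with quadgeom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric analysis of G-quadruplex structures with quadgeom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadgeom)
library(dplyr)
```

## The problem

A DNA G-quadruplex (G4) is a four-stranded fold built from stacked
G-quartets: planar, cyclic arrangements of four guanines in which each
guanine donates two Hoogsteen hydrogen bonds (N1-H...O6 and N2-H...N7)
to its neighbour, with monovalent cations (typically K+) sandwiched on
the central axis between quartet planes. Promoter quadruplexes such as
the one in the *c-KIT* oncogene are drug-design targets, and the
questions a structural analyst asks of a new crystal form, NMR bundle or
simulation ensemble are remarkably repetitive: where are the quartets
and how many layers stack; which loop type connects which corner of the
core; which extra-helical bases point up, down or out, and which stack
on a quartet face; what do the backbone torsions do in the loops; which
residues are flexible; and, for an ensemble, which conformational
states exist and how do they interconvert.

`quadgeom` implements that analysis layer as composable functions over
one tidy currency: an **atom table** -- a tibble with one row per atom
per model (`model`, `chain`, `resno`, `resname`, `atom`, `elem`, `x`,
`y`, `z`, `occ`, `b`, `hetero`) -- read from PDB or mmCIF files via
`read_structures()` (parsing is delegated to **bio3d**), or built from
scratch by the synthetic generators.

## Quartet detection and the core frame

`detect_quartets()` is purely geometric. A directed graph is built over
all guanines with an edge `g -> h` when both heavy-atom Hoogsteen
contacts hold, `d(N1_g, O6_h) <= 3.5` Å and `d(N2_g, N7_h) <= 3.5` Å,
and every directed 4-cycle is a candidate quartet. Candidates are
filtered by planarity (RMS deviation of the four bases' ring atoms from
a common best-fit plane, at most 1.0 Å) and made disjoint greedily,
most planar first. Three choices matter:

* **Hydrogen-free criterion.** Crystal structures carry no hydrogens,
  so the criterion is a donor-acceptor heavy-atom distance with no
  angle term; 3.5 Å is the conventional upper bound for an N/O
  hydrogen bond and is an explicit argument.
* **No sequence information.** Cycles are found in space, not along the
  chain, so a guanine outside any G-tract that folds back into the core
  (a *snapback* guanine, like G10 of the c-KIT fold) is detected like
  any other.
* **Greedy disambiguation.** When candidate cycles share a guanine the
  most planar wins; the published material does not discuss overlapping
  candidates, so the tie-break is documented config rather than
  hard-coded magic.

`build_core()` orders quartets along the best-fit line through their
centroids, enforces a stacking window (consecutive centroid separations
of 2.8-4.5 Å, outside which a structure is reported as a stacking
break rather than silently accepted), and anchors the axis direction at
the layer containing the 5'-most core guanine. That anchoring is what
makes "up" and "down" reproducible across depositions: the bottom face
is defined by sequence, not by file orientation.

`assign_ions()` classifies a monatomic cation as a channel ion when its
axial projection falls between the terminal layer centroids (padded by
half a rise) and it sits within 2.5 Å of the axis; everything else is
external, annotated with its nearest nucleotide.

`classify_topology()` groups core guanines into four columns by
stacking contact across layers (a 4x4 assignment problem solved
exactly per layer pair), derives strand sense from the axial
progression of C1' atoms between sequence-consecutive column members,
and types each loop from the faces of its two anchoring core guanines:
opposite faces make a propeller (double-chain-reversal) loop, the same
face makes a lateral loop between angularly adjacent columns and a
diagonal loop between opposite ones. Snapback guanines are core members
with no sequence neighbour inside their own column.

## Torsions

`backbone_torsions()` reports the seven standard nucleic-acid torsions
(alpha through zeta plus glycosidic chi; purine chi is O4'-C1'-N9-C4,
pyrimidine chi is O4'-C1'-N1-C2), in degrees on (-180, 180] -- degrees
are the unit everywhere in the package. An angle whose atoms are absent
is `NA`, never an error: a 5'-terminal residue without a phosphate has
no alpha or beta, exactly as published torsion tables leave those cells
blank. `torsion_table()` lays several structures side by side, one
residue-by-angle row per cell, for loop-conformation comparisons across
crystal forms.

The sign convention was pinned against an independent implementation
(gemmi's dihedral, via its Python interface) during development, and
the test suite carries its own triple-product/atan2 oracle written
separately from the kernel.

## Base orientations and cleft widths

For the extra-helical bases the package re-derives the published
four-way vocabulary -- up, down, out, stacked -- from explicit
geometry, because the prose description carries no numbers. A base
stacks on a partner (core guanine or another loop base) when the ring
centroids are within 2.5 Å laterally and 3.0-4.2 Å axially with ring
planes within 30 degrees: canonical pi-stacking geometry. A non-stacked
base is classified by the elevation angle of its ring centroid relative
to the nearest quartet layer: above +30 degrees is up, below -30
degrees is down, in between is out. Up/down are global-axis calls
(whether the published convention is per-face or global is not stated;
the global convention is deterministic across files and is documented
here as the package's choice). All five thresholds are arguments, so
sensitivity scans are one `purrr::map()` away; the tests verify that a
base planted far from every decision boundary never flips under a
plus/minus 20% threshold perturbation.

`orientation_summary()` repeats the classification across ensemble
members and tabulates percent occupancy per base and category, with
optional per-member weights so that cluster medoids can be weighted by
cluster populations. `cleft_width()` measures the inter-strand P...P
distance that sizes the putative ligand-binding cleft, reported both
exactly and at the 1-decimal granularity used in print.

## Flexibility profiles

`residue_bfactors()` averages atomic isotropic B factors per residue
(all atoms or base-only scope). `ensemble_rmsf()` computes per-residue
RMS fluctuations about the ensemble mean after least-squares
superposition on a fit selection; the mean structure is refined once
(mean, fit, re-mean, re-fit), a fixed and documented choice -- full
iteration to convergence changes third-decimal values at most on the
ensembles this package targets. Fitting on the stable core guanines
rather than on all atoms keeps loop flexibility from being absorbed
into the fit. `rmsf_to_bfactor()` applies the isotropic conversion
`B = (8 pi^2 / 3) rmsf^2`.

"Normalized" profiles are z-scores with the population (divide-by-n)
standard deviation, so a two-point profile [0, 2] maps to [-1, +1]; the
published figures say "normalized" without a formula, and min-max
scaling is available behind `method = "minmax"` for figure-style
replots. Averaging happens before normalisation (the alternative order
is not distinguishable from the published description; one had to be
chosen and this one is tested). `compare_profiles()` aligns profiles
from different sources by sequential residue index and reports Spearman
rank correlations, the quantitative form of "the same residues come
out flexible".

## Ensemble clustering and transition graphs

`distance_matrix()` computes pairwise fitted RMSD over an atom
selection; frame labels carry the trajectory identity. Superposition is
the package's own Kabsch implementation (SVD with determinant sign
correction -- reflections are forbidden because DNA is chiral).

`cluster_medoids()` minimises the k-medoid objective (summed
dissimilarity of every frame to its cluster medoid; every medoid is a
physical frame). Published work in this area names only "a robust
clustering algorithm" with at most 10 clusters, medoid representatives
and same-trajectory transition counting; this package adopts PAM-style
k-medoids as the documented stand-in that preserves that observable
contract. Small instances (up to 5000 medoid subsets) are solved
*exactly* by enumeration; larger ones use a seeded k-medoids++-style
initialisation, alternating assignment/update, a PAM swap phase and
five deterministic restarts. The tests re-verify the per-cluster medoid
property by brute force and, for n of 8 or fewer frames, the global
optimum itself. `select_k()` picks the cluster count by mean silhouette
over k = 2..10 (ties to smaller k) and flags best silhouettes below
0.25 as weak structure.

`transition_graph()` increments a directed count for every pair of
consecutive frames *within the same trajectory* whose labels differ;
pairs spanning trajectory boundaries contribute nothing, so no
artificial transitions are created between independent runs.
`isolated_clusters()` reports clusters with undirected degree at most
one. At the published production scale (150,000 frames) a dense RMSD
matrix is out of reach for a desk analysis; the implementation targets
ensembles up to a few thousand frames, with a `stride` option in
`analysis_config()` for decimation.

## The synthetic generators, and what passing tests mean

Every analysis stage is exercised against generators whose ground truth
is known by construction:

* `build_quadruplex()` assembles an idealized parallel (or, on request,
  antiparallel) quadruplex from an embedded guanine template taken from
  the standard chemical-component dictionary. The in-plane placement of
  the guanine is solved numerically so that the four 90-degree-rotated
  copies close the Hoogsteen cycle at 2.8 / 3.1 Å (N1-O6 / N2-N7) --
  with a rigid ideal base the achievable cycle geometries are discrete,
  and these targets select the branch with outward sugars and no
  steric overlap between symmetry copies. Layers are stacked at a
  configurable twist (default 30 degrees) and rise (default 3.3 Å,
  the canonical quartet stacking distance); channel K+ sit midway
  between layers; loop bases are planted at positions that realise a
  prescribed orientation category with margin. Defaults emulate the
  three-layer parallel c-KIT-like fold.
* `build_chain()` / `ic_nucleotide_chain()` build Cartesian coordinates
  from internal coordinates by natural extension (NeRF), so backbone
  torsions are known exactly -- the round-trip through
  `backbone_torsions()` reproduces prescribed angles to machine
  precision (the tests assert 1e-6 degrees).
* `perturb_ensemble()` adds seeded i.i.d. Gaussian noise per coordinate
  with a per-residue sigma, so the expected RMSF is sigma sqrt(3);
  recovery within 5% at 500 members is asserted.
* `generate_trajectories()` emits frames around planted centers
  following a per-trajectory schedule, so the true partition (for ARI
  against the clustering) and the true switch count (for transition
  totals) are known.

What passing these tests does *not* show: the generators are geometric
emulations, not physics. Loop backbones are plausible but not
energy-minimised, perturbations are isotropic and uncorrelated (real
thermal motion is anisotropic and collective), planted cluster centers
are well separated (real ensembles have overlapping basins), and the
synthetic quartet is flatter and more regular than any crystallographic
one. The deposited-structure checks in `tests/testthat/test-acceptance.R`
-- cleft widths, published torsion tables, water counts, fold-topology
regressions, NMR-bundle compactness -- complement them and run whenever
the corresponding PDB entries (2O3M, 3QXR, 4WO2, 4WO3) are available in
`fetch_structure()`'s cache; on a machine without network access and
without a pre-populated cache those tests fail at the data-loading
step.

## Numerical choices and degenerate inputs

* Angles are degrees on (-180, 180] at every module boundary; radians
  never cross one.
* `dihedral_angle()` raises a domain error for coincident or collinear
  consecutive points rather than returning a value from an unstable
  formula; `backbone_torsions()` converts those to `NA` cells.
* Superposition forbids reflections (determinant +1 enforced by sign
  correction on the smallest singular vector).
* Alternate locations resolve to the highest occupancy, ties to file
  order; hydrogens are dropped on read so crystal and NMR inputs face
  identical geometry code.
* Constant profiles z-score to all zeros rather than 0/0.
* `analyze()` writes JSON with fixed key order and 4-decimal floats,
  so re-runs under the same config and seed are byte-identical; every
  generator restores the caller's RNG state.

## A worked example

```{r example}
q <- build_quadruplex(place_channel_ions = TRUE)
quartets <- detect_quartets(q)
core <- build_core(quartets)
core

topo <- classify_topology(core, q)
glance(topo)

assign_ions(core, q) |> select(resno, role, layer_gap, radial)

classify_base_orientation(q, core) |>
  select(label, category, elevation)
```

```{r cluster-example}
centers <- lapply(1:3, function(i) {
  subset(perturb_ensemble(q, 1.5, 2, seed = 100 + i), model == 1)
})
tr <- generate_trajectories(centers,
                            list(c(1, 1, 2, 2, 3), c(3, 3, 1)),
                            sigma = 0.05, seed = 11)
dm <- distance_matrix(tr)
cl <- cluster_medoids(dm, k = select_k(dm, seed = 1), seed = 1)
glance(cl)
tidy(transition_graph(cl))
```

## Known limitations

* Dimer interfaces across crystallographic symmetry mates are not
  analysed; that needs symmetry expansion, which is out of scope.
* Mixed (non-guanine) quartets are not detected, and candidate A:G
  pairs in stem loops are not hydrogen-bond-typed.
* No sugar pucker pseudorotation or BI/BII backbone classification.
* Cluster populations are frame counts; if trajectories of unequal
  length should weigh equally, resample before clustering.
* The dense RMSD matrix bounds ensemble size to desk scale (a few
  thousand frames).
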