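---
title: "Dynamic structure-based pharmacophores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic structure-based pharmacophores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynopharm)
library(dplyr)
```

## The problem

A pharmacophore model derived from a single crystal or docking pose
captures one snapshot of a protein-ligand complex. Molecular dynamics
shows that interactions blink in and out: a hydrogen bond present in 95%
of frames is a different constraint than an aromatic stack present in
30%. `dynopharm` builds pharmacophore models *from the trajectory*: it
perceives interactions frame by frame, keeps statistics over an analysis
window, merges the most frequently recurring per-frame models into a
per-ligand model, aligns and merges the per-ligand models of several
inhibitors into one consensus query, surrounds it with exclusion volumes
marking protein-occupied space, and validates the query by screening a
labelled library with ROC/enrichment statistics.

The package was written with homotetrameric ion-channel pore blockers in
mind -- a C4-symmetric cavity lined by aromatic, hydroxyl and
hydrophobic side chains, and cationic amphiphilic blockers sitting under
the selectivity filter -- but every step operates on generic atom
records and generic typed features.

## Interaction model

Ligand features are perceived by an open rule set (there is no
proprietary perception engine behind it, so results are reproducible
from the source):

* **AR** -- every aromatic ring (bond flags, a kekulized alternating
  pattern, or, for ligands lifted out of PDB files without bond orders,
  a planar 5/6-ring of C/N atoms within 0.1 Å RMS) gives one feature at
  the ring centroid with the ring normal as direction.
* **PI** -- nitrogen with formal charge +1 (quaternary ammoniums
  inferred from four heavy-atom bonds when connectivity is
  distance-derived), or a neutral sp3 amine with an available hydrogen
  and no adjacent carbonyl. Inputs are expected pre-protonated at
  physiological pH; the amine heuristic is a fallback.
* **HBD / HBA** -- N/O with an explicit or inferable hydrogen; N/O with
  a free lone pair. Hydroxyls count as both.
* **H** -- each connected fragment of two or more carbons/halogens none
  of which touches N, O or S, one feature at the fragment centroid.
  This granularity makes a long aliphatic tail one feature rather than
  a bead chain.
* **XBD** -- Cl/Br/I bonded to carbon, with the C→X direction
  (fluorine excluded; chlorophenyl-type halogen bonding is the use
  case).

Protein residues are mapped to typed groups (rings of Phe/Tyr/Trp/His
with planarity checked at 0.1 Å RMS; Ser/Thr/Tyr hydroxyls as
donor+acceptor; backbone C=O / N-H; Lys/Arg positive, Asp/Glu negative;
tabulated apolar side-chain carbons as individual hydrophobic points).
Only residues within 8 Å of the ligand (per frame, with a ±1 Å
static-band shortcut) are perceived.

Frame-wise interactions are then called from geometry:

| interaction | criterion | default |
|---|---|---|
| hydrogen bond | donor-acceptor heavy distance; D-H...A angle when H present | 3.5 Å / 130° |
| hydrophobic | H-feature centroid to apolar atom | 4.5 Å |
| aromatic | centroid distance and interplanar angle ≤ parallel or ≥ T-shaped | 5.5 Å, 30°, 60° |
| cation-π (reported as PI) | charged center to ring centroid | 6.0 Å |
| ionic (reported as PI) | opposite charges | 5.5 Å |
| halogen bond | X...A distance, C-X...A angle | 3.8 Å / 140° |

The literature anchor for pore blockers is parallel-displaced stacking
near 5 Å, comfortably inside the aromatic bound; the remaining values
follow standard interaction-geometry surveys and are all configurable
through `geometric_rules()`. When hydrogens are absent (the common case
for heavy-atom trajectories) the hydrogen-bond angle criterion is
skipped and the call is distance-only.

## From frames to a consensus model

Each analyzed frame yields a set of interaction records; its *signature*
is the sorted set of (type, chain, residue) items. Signatures ignore
coordinates deliberately -- with thermal jitter every frame would
otherwise be unique. Statistics over the analysis window (by default the
last 20% of the 500 evenly distributed frames kept from a production
run, i.e. the last 20 ns of a 100 ns simulation) produce:

* the **occurrence table** -- per (residue, type), the percentage of
  window frames containing that interaction;
* the **model histogram** -- how often each unique signature occurs
  (counts sum to the window size; interaction-free frames contribute an
  empty signature which is reported but never selected);
* the **four most frequent models** (ties broken by more features, then
  lexicographically), each given representative geometry by averaging
  its per-frame ligand feature centers.

Note one deliberate API deviation: representative geometry cannot be
reconstructed from the histogram alone, so `select_frequent_models()`
consumes the interaction-record table (which carries per-frame feature
centers) rather than the histogram object.

The frequent models of one complex are merged by single-linkage
clustering of same-type features with a 1.5 Å tolerance; a cluster
becomes one feature at its centroid with radius `max(member radii,
cluster spread)`. Per-ligand merged models of different inhibitors are
then mutually aligned: candidate feature-pair triplets (forced to
include the positive-ionizable pair when both models have one) seed a
Kabsch superposition that is extended greedily by mutually nearest
same-type pairs; success requires at least 3 pairs within 1.5 Å RMSD.
Failure is a *result*, not an error -- an inhibitor with a genuinely
different binding mode (the quinidine situation) is excluded from the
consensus and reported with its diagnostics.

The final model is devectorized (all direction vectors dropped, spheres
only) and flagged: the positive-ionizable feature and the hydrophobic
feature nearest to it are **essential**; the next two hydrophobic
features form an **either-group**; everything else is optional. On the
either-group semantics we follow the substance of the
one-essential-one-optional hydrophobic pair: *at least one* member must
be matched, and the second may also match. A strict exactly-one rule
would reject the very ligands whose models contributed both features.

Exclusion volumes are spheres (default radius 1.2 Å) on every protein
heavy atom whose window-mean position lies within 8 Å of the ligand's
mean envelope, except atoms within 2 Å of a model feature center. When
several per-ligand models are merged their pooled spheres are collapsed
by single-linkage clustering at 0.75 Å.

## Screening and validation

`match_conformer()` searches rigid placements: triplets anchored on the
PI (or largest-radius essential) feature seed Kabsch fits, refined by
greedy mutual-nearest pairing within each model feature's radius. A
placement is valid if all essential features match (zero omitted
features by default), every either-group has a matched member, and no
heavy atom of the conformer sits inside an exclusion sphere (when
enabled). Conformers are used as provided -- the package embeds no
geometry. The pharmacophore-fit score is

$$S = 10\,M - 3\,\mathrm{RMSD}_{feat}$$

with `M` matched features. The formula is this package's own
definition; only the induced *ranking* is a validated contract, not the
absolute value.

`enrichment_metrics()` ranks matched molecules by descending score
(unmatched ones after all matched ones, ties in stable input order) and
reports

$$EF_f = \frac{a_f / n_f}{A / N}, \qquad n_f = \max(1, \lfloor f N \rfloor),$$

plus the ROC AUC computed by trapezoid over score-tie groups, which is
numerically identical to the tie-corrected Mann-Whitney statistic (a
property the test suite asserts to 1e-9). The floor-based bin
definition matters: for a 463-compound library the 1% bin is exactly 4
compounds, and 2 actives in it give EF = 15.4.

## The synthetic study system

No public trajectories or compound lists accompany the analysis this
package operationalizes, so `dynopharm` ships a generator that *is* the
test bed, not a fixture:

* `pocket_spec()` -- a C4-symmetric pore: four chains each contributing
  SER436 (hydroxyl into the pore), TYR464 (inward aromatic ring above
  the cavity), ALA465 (hydrophobic CB) and PHE468 (stacking ring),
  with backbone atoms placed outward to line the pocket for exclusion
  volumes and to carry C-alpha atoms for RMSF.
* `synthetic_ligand()` -- a quaternary ammonium core with four arms
  (benzene, hydroxyl, propyl tail, chloroalkyl), each with an engaged
  pose satisfying its target interaction with at least 0.4 Å margin
  and a disengaged pose violating every criterion by a clear margin.
  Dropped arms become methyl stubs so the nitrogen stays quaternary.
* `generate_complex_trajectory()` -- draws each arm's engagement per
  frame from its scheduled Bernoulli probability, adds isotropic
  Gaussian jitter (default σ = 0.05 Å), and *resamples* any frame in
  which jitter pushed some criterion within 0.05 Å (or the angle
  equivalent) of its decision boundary, flipped a scheduled
  interaction, or (first frame) degraded ring planarity / bond
  inference. The default σ was chosen so that resampling is rare and
  first-frame topology perception is reliable; it is a visualization of
  thermal noise, not a thermodynamic model.

Ground truth is produced by an evaluator inside the generator that
enumerates the planted features and groups from the templates and
applies the rule thresholds with its own array arithmetic -- it shares
the rule *values* with the detection engine but none of its code
(no perception, no tidy joins). With σ = 0 the detector reproduces this
ground truth exactly, frame by frame; with the default jitter the
guard band keeps the two in exact agreement as well, which the
acceptance suite checks over 500 frames.

The library generator builds actives by placing feature-bearing
fragments at the model's feature centers joined by alkyl linkers
(variants drop optional arms, extend the tail, and apply ≤ 0.12 Å
seeded displacements), and decoys that are property-matched to their
parent active (heavy atoms ±2, ring count and formal charge exact,
donors/acceptors ±1) but topologically rearranged so that *only one*
apolar fragment exists -- after the essential hydrophobic feature
consumes it, the either-group can never be satisfied, in any conformer.
"Different 2D topology" is enforced as element-colored graph
non-isomorphism against the parent; a fingerprint-similarity criterion
would add a dependency without changing what the tests can conclude.

### What the generator does and does not emulate

It reproduces the *statistical structure* of a trajectory -- prescribed
interaction occupancies, coordinate noise, a crowded pocket with
incidental contacts (the engaged phenyl also touches TYR464
hydrophobically, as stacked rings do) -- and the *shape* of a
DUD-E-style labelled library. It does not emulate force-field physics,
correlated motions, water-mediated contacts, conformational strain or
realistic torsion distributions; linker geometries in generated
molecules are idealized. Passing tests therefore demonstrate that the
analysis machinery is correct and self-consistent under known ground
truth, not that any particular real system will show these occupancy
values.

## Trajectory metrics

`align_to_first_frame()` superposes every frame onto the first by a
least-squares rigid fit (SVD-based Kabsch with determinant correction;
an independent quaternion-method oracle in the tests agrees to 1e-8) on
the protein C-alpha selection, moving the ligand with the same
transform. RMSF is computed per residue on C-alpha atoms. The pairwise
ligand RMSD matrix is computed in that common frame *without* per-pair
re-superposition -- this keeps binding-mode drift visible as block
structure and makes the matrix a true metric (symmetric, zero diagonal,
triangle inequality), which the suite verifies on random instances.
Ring-centroid distance series (e.g. the stacked aromatic pair of each
subunit) report side-chain rotation events as level shifts.

## Numerical choices and edge cases

* Downsampling keeps frames at `floor(i (F-1) / (n-1))`, so the first
  and last frames always survive.
* Single-linkage merging uses `stats::hclust(method = "single")` with
  `cutree(h = tol)`; determinism under input reordering comes from
  canonical sorting of the merged feature table.
* Degenerate rigid fits (collinear selections, rank < 2) are rejected
  with a classed error rather than silently producing reflections; all
  fitted rotations have determinant +1.
* Model alignment and conformer matching iterate candidates in a fixed
  deterministic order and break score ties toward the earlier
  candidate, so repeated runs are byte-identical.
* Trajectories validate atom identity and ordering across frames at
  construction; ligand-less models and inconsistent models fail with
  `ligand-not-found` / `frame-mismatch` before any geometry is read.
* Unparsable library records are skipped and counted, never fatal --
  mirroring routine library curation.

## Problem sizes used in the shipped checks

The packaged tests run the generator at 15-500 frames and libraries of
up to 765 molecules; the occupancy-recovery study uses 100 seeded
replicates of 500 frames each at planted probabilities 0.1 / 0.5 / 0.9,
and the RMSF calibration uses 5000 frames. These sizes were chosen to
give the binomial and Monte-Carlo tolerances quoted above (3σ bands,
±5% on RMSF) real statistical teeth while keeping a full run of the
suite in the minutes range on a single core.

## Known limitations

* Feature perception is heuristic and heavy-atom oriented; tautomers,
  charged carboxylates on ligands, and fused aromatic systems beyond
  simple rings are out of scope (fused rings are perceived ring by
  ring only when each ring closes a ≤ 6-cycle).
* Water-mediated hydrogen bonds are not modelled.
* The conformer matcher searches triplet-seeded rigid placements; a
  conformer whose only valid placements disagree with every seed
  triplet by more than the feature radii can be missed. With ≤ 16
  features per model the seed set is effectively exhaustive.
* Screening treats conformers as rigid; no on-the-fly embedding or
  minimization is performed, matching the preprocessed-library
  workflow.
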