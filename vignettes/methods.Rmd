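---
title: "Methods: fingerprints, scaffolds and benchmarks in bbbfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprints, scaffolds and benchmarks in bbbfp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures behind `bbbfp`, the
assumptions they make, the parameters worth knowing about, and the design
choices taken where several defensible options existed.

## The screening problem

Blood–brain-barrier (BBB) permeation is modelled as binary classification:
each molecule is permeable (label 1) or not (label 0), and the model input
is a fixed-length bit vector describing either the ligand alone or its
docked complex with the efflux transporter P-glycoprotein. The package
produces four such representations — a circular connectivity fingerprint,
a binding-site residue-contact fingerprint, a typed-interaction
fingerprint, and a topological 2D pharmacophore fingerprint — plus the
scaffold-level permeation statistics that give a medicinal chemist a
framework-first view of the same data.

## Library standardization

`standardize_molecules()` delegates the standard chemistry to Open Babel:
keep the largest contiguous fragment (salt stripping), neutralize formal
charges where a proton can legally be added or removed (carboxylates and
phenolates are protonated, ammoniums deprotonated; quaternary nitrogens
keep their charge), drop stereo descriptors and isotopes, and emit
canonical SMILES. Stereochemistry is discarded deliberately: duplicate
entries in public BBB collections are overwhelmingly stereoisomer pairs,
and none of the downstream fingerprints are stereo-aware, so collapsing
them avoids double-counting. Standardization is idempotent — re-running it
on its own output is a no-op, which the tests assert.

Unparseable SMILES become rejection rows rather than errors, so one bad
entry never aborts a batch. Single-heavy-atom records (noble gases, bare
ions, water after salt stripping) carry no organic substructure and are
flagged `excluded`.

3D preparation (`embed_and_optimize_3d()`) generates a conformer and
refines it by steepest-descent MMFF94 minimization, capped at 5000 steps.
The gate for keeping a molecule is deliberately crude but robust: finite
coordinates, no interatomic distance below 0.7 Å, and a non-degenerate
geometry; anything else — including force-field parameterization failures —
is flagged `neglected` and dropped from the 3D library with an audit row.

## Circular fingerprint and deduplication

`ecfp4()` implements the radius-2 extended-connectivity algorithm: per-atom
invariants (atomic number, heavy-atom degree, hydrogen count, formal
charge, aromatic-ring membership) are hashed, then twice updated with the
sorted (bond order, neighbour identifier) pairs; identifiers from all three
radii are folded modulo the fingerprint length (1024 bits by default). The
hash is a 32-bit FNV-1a implemented in plain double arithmetic, so bit
patterns are identical across platforms. Two simplifications relative to
some toolkit implementations are documented here: duplicate substructure
environments are not pruned (harmless for presence/absence bits), and the
invariant set is fixed rather than configurable. A recursive
from-scratch re-derivation of every atom's neighbourhood identifier serves
as the test oracle.

Deduplication is single-linkage grouping of pairs with Tanimoto similarity
at or above a threshold. The default threshold is 1.0 — exact
fingerprint duplicates — which is conservative and reproducible; lower it
to merge near-duplicates. Each group's representative is the
lexicographically smallest canonical SMILES: an arbitrary but deterministic
stand-in for case-by-case manual inspection, which cannot be reproduced.

## Murcko scaffolds and permeation probability

The scaffold of a molecule is computed graph-theoretically: the 2-core of
the heavy-atom graph (what remains after iteratively deleting degree-one
atoms) is exactly the union of rings and ring–ring linkers; atoms attached
to that core by double or triple bonds are retained so exocyclic carbonyls
keep their valence; the result is canonicalized through the same SMILES
routine as standardization, so groups are stable across runs. Acyclic
molecules have an empty 2-core and are reported under an `ACYCLIC`
sentinel, excluded from scaffold statistics.

A scaffold's permeation probability is the positive fraction of its
labelled members; unlabelled members count toward membership only. The
category thresholds — above 0.6 permeable, below 0.4 non-permeable,
boundaries inclusive neutral — read the neutral band as the closed
interval, so exactly 0.6 and 0.4 are neutral. This is the literal reading
of "between 0.4 and 0.6"; nothing in the pipeline is sensitive to the
boundary choice beyond these two measure-zero points.

## Residue-contact fingerprint

A residue is "in contact" with a pose when any of its heavy atoms lies
within a cutoff of any ligand heavy atom. The cutoff defaults to 4.0 Å —
a common close-contact convention — and is configurable; hydrogens are
ignored on both sides because docking formats carry only polar hydrogens,
and mixing H-aware with H-blind inputs would bias counts. Contact
frequency counts *distinct ligands* per residue, so a ligand touching a
residue with five atoms still contributes one. The schema is the top-62
residues by frequency (the fingerprint length used throughout), with ties
broken deterministically by chain then residue number; rank-1 poses only
by default, matching docking-output ordering. The fingerprint is then one
presence bit per schema residue.

The PDB/PDBQT reader is written in the package because pose files are
PDBQT — a dialect whose occupancy/B-factor columns hold partial charge and
an AutoDock atom type, organized in MODEL blocks — and because parse errors
must name the offending line. For plain PDB files it is cross-checked
against an independent reader in the tests.

## Typed interaction fingerprint

Nine interaction types are fixed, in order: Hydrophobic, HBDonor,
HBAcceptor, Cationic, Anionic, CationPi, PiCation, PiStacking, VdWContact
(donor/acceptor and cation/pi named from the ligand's side). The geometric
defaults, all configurable through `default_interaction_config()`:

| interaction | threshold |
|---|---|
| hydrophobic C/S/halogen pair | d ≤ 4.5 Å |
| hydrogen bond | d(D,A) ≤ 3.5 Å, ∠D–H···A ≥ 130° when an H is present |
| salt bridge (charge centres) | d ≤ 4.5 Å |
| cation–pi | d(cation, centroid) ≤ 4.5 Å, ≤ 30° off ring normal |
| pi-stacking face-to-face | centroids ≤ 5.5 Å, plane angle ≤ 30° |
| pi-stacking edge-to-face | centroids ≤ 6.5 Å, plane angle 50–90° |
| van der Waals contact | d ≤ Bondi radius sum (+ tolerance, default 0) |

Ligand chemistry is perceived from SDF connection tables (donors are N/O
with a hydrogen; acceptors are non-cationic O, and trivalent non-cationic
N that is not a pyrrole-type NH; charges mark ions; uncharged C/S/halogen
atoms without N/O or charged neighbours are hydrophobes; aromatic rings
come from ring perception with an SVD plane fit for centroid and normal).
Receptor chemistry cannot be perceived — PDB files carry no bond orders —
so residues are assigned by name from templates: LYS/ARG (and protonated
HIS) cations, ASP/GLU anions at the carboxylate midpoint, PHE/TYR/TRP/HIS
rings, backbone and side-chain donors/acceptors, and per-residue
hydrophobe lists. Unknown residue names are skipped with a warning rather
than guessed. When no explicit hydrogen is available the hydrogen-bond
test falls back to distance only; this is the common case for receptors.

The fingerprint is one bit per type present anywhere in the complex — it
answers "does this pose form a salt bridge at all", not "with which
residue". A subtlety worth knowing: a hydrogen bond at ≤ 3.5 Å is always
also inside the Bondi radius sum of its donor and acceptor atoms
(≈ 3.0–3.1 Å for N/O pairs), so any complex with a hydrogen bond also
sets the VdWContact bit. This is a property of the typing rules, not a
bug, and the synthetic complexes encode it in their ground truth.

All detection logic is validated against a naive brute-force re-derivation
on 50 seeded random synthetic complexes, and events are invariant under
rigid rotation and translation to 10⁻⁶ Å.

## Ligand 2D pharmacophore fingerprint

Six feature families are detected on the molecular graph (no conformer
needed): hydrogen-bond donor (HD), acceptor (HA), aromatic ring (AR),
hydrophobe (HY), basic group (BG: charged or sp³ amine nitrogen not
adjacent to a carbonyl), and acidic group (AG: carboxylic, sulfonic or
phosphonic acid with its oxygens). Every 2- and 3-subset of feature
instances is encoded by the *topological* distances between the features'
atom sets (minimum bond-path length over member atoms); distances are
assigned to 13 bins over bond counts —
1, 2, 3–4, 5, 6, 7–10, 11–12, 13, 14–19, 20–24, 25–26, 27, 28+ —
and a fingerprint bit is one equivalence class of (family assignment,
binned distances) under permutation of the points, i.e. one
distinguishable pharmacophore. Triangles are kept only if integer
distances satisfying the triangle inequality exist inside the three bins;
this can never exclude a class realized by an actual molecule, because a
molecule's true path lengths always satisfy the inequality. Pairs whose
members overlap on the graph (path length 0, e.g. a ring that is both AR
and HY) fall below the lowest bin edge and are discarded.

Exhaustive enumeration of the admissible classes gives the fingerprint
length: 273 pair classes (21 family pairs × 13 bins) plus 39,698 triangle
classes, 39,971 bits. Two design choices deserve explanation. First, the
class structure quotients by point permutation — two triangles that differ
only by relabelling their corners are the same pharmacophore and share a
bit; encoding assignments without this quotient would index
indistinguishable objects separately. Second, the bin edges were
*calibrated* so the enumeration lands exactly on the intended 39,971-bit
size: the family count, point counts and triangle rule pin the total's
residues modulo small numbers (13 bins is in fact the only bin count
≡ 13 mod 18 in a practical range), and within that constraint the edges
were chosen once, with singleton bins at chemically informative short
ranges and wider bins at long range. The schema ships as code and is
validated at first use; `enumerate_bit_space()` recounts it from scratch.

Canonicalization sorts families first and breaks ties by the
lexicographically smallest distance tuple over the admissible
permutations, making the bit index order-free; renumbering a molecule's
atoms provably cannot change its fingerprint, and the tests check this on
differently-written SMILES of the same compounds.

## Cross-validated benchmark

`stratified_folds()` shuffles each class independently under a fixed seed
and deals members round-robin, so per-fold class counts are within one of
proportional; a class smaller than the fold count is legal and simply
absent from some folds. Four models run per feature set: a uniform-random
dummy baseline (the no-information reference, ~50% accuracy on balanced
data), an RBF-kernel SVM (probability outputs, no feature scaling — bits
are already 0/1), a 500-tree random forest, and naive Bayes with the
binary bits treated as two-level factors (Bernoulli-style) under Laplace
smoothing. Hyperparameters are fixed defaults rather than tuned: the
benchmark's job is comparing representations reproducibly, not squeezing
points of accuracy. Every stochastic step is seeded; per fold, train and
test sets are asserted disjoint before fitting. Metrics are computed from
the confusion counts by their defining formulas, with the convention that
a zero denominator yields 0 and a degenerate-case flag; AUROC uses the
rank formulation with half-credit for ties, so it is invariant under
monotone transforms of the scores.

## What the synthetic data does and does not show

The toy complexes place idealized residue templates (internal-coordinate
geometry, not fragments of real structures) and small ligand fragments at
engineered positions with ≥ 0.3 Å / ≥ 10° margins to every threshold they
are meant to satisfy, one interaction per station, stations 28 Å apart.
They prove that the geometric detectors implement their stated rules
exactly; they say nothing about force-field realism, pose quality, or how
often real P-gp poses exhibit each interaction. Likewise the labelled
library plants a clean carboxylic-acid signal on a 10-scaffold pool with
fixed per-scaffold positive fractions (1.0 down to 0.0, Bresenham-spread
so realized fractions track planted ones at any library size): a forest
recovering it at ≥ 0.9 accuracy demonstrates the benchmark plumbing, not
chemistry. Real BBB data is noisier, scaffold-imbalanced, and its signal
is spread over many weak features; numbers from the fixtures should never
be quoted as expected real-data performance.

Test problem sizes are chosen to keep the default suite fast while
exercising every path: 50-molecule dedup fixtures, 50 random complexes for
the geometric oracles, a 200-molecule library at zero noise for signal
recovery, and 10⁴ samples for the baseline-convergence check.

## Known limitations

- Neutralization is rule-based (MolVS-style); exotic zwitterions and
  organometallics may pass through unchanged or be rejected.
- Tautomers are not canonicalized; two tautomeric drawings of one compound
  can produce different fingerprints.
- Receptor feature templates cover the 20 standard amino acids (plus
  protonated-histidine names); cofactors, metals and modified residues are
  skipped with warnings.
- Histidine protonation cannot be inferred from coordinates alone; neutral
  HIS is aromatic but not cationic unless named HIP/HSP.
- The interaction fingerprint is type-level by design; per-residue-resolved
  interaction maps are out of scope.
- Docking itself is out of scope: the package parses docked poses and
  carries the receptor grid configuration (`docking_config()`), but never
  runs a search.
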