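---
title: "Fragment seeding by structural-environment matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment seeding by structural-environment matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frasebot)
```

## The problem

Many disease-relevant proteins — scaffolding and signalling proteins,
transcription factors — have no pocket sculpted for an endogenous small
molecule and no known ligands to learn from. `frasebot` addresses hit
finding for such targets by transferring 3D information from the corpus of
solved protein–ligand complexes: if a patch of the target's surface
arranges residues the way some known complex arranges them around a ligand
fragment, that fragment is a candidate binder for the target, at the pose
implied by the geometric correspondence.

The workflow is: build a database of fragments-in-environments (FRASEs),
screen it against the target by residue-triplet matching, transplant
matched fragments, score each pose's "nativeness" with a learned
classifier, filter geometrically, and compress the surviving fragments
into a pharmacophore query for compound-database screening.

## FRASE construction

A FRASE pairs a ligand fragment with every protein residue having at
least one heavy atom within **4.5 Å** of the fragment (whole residues are
kept). Fragments are enumerated by deleting subsets of *acyclic single
bonds* — ring bonds are never broken, so any ring intersecting a fragment
is wholly inside it — and retained when their molecular weight falls in
**[50, 300] Da**. When a cut detaches a substituent from a cyclic
fragment, the substituent's first atom (α-atom) is kept as a carbon-like
attachment marker: it contributes to the molecular weight (as a
methyl-equivalent) but carries no atom types, so it never contributes to
interaction fingerprints. The number of simultaneous cuts is capped
(`max_cuts = 3`, configurable) to bound the enumeration; fragments are
deduplicated by atom set.

## Residue triplet fingerprints

The screening unit is a triple of residues whose Cα atoms form an
approximately equilateral triangle with all three edges in **[8, 12] Å**.
"Approximately equilateral" is implemented as exactly this per-edge
window and nothing else: the window itself bounds the edge ratio at 1.5,
and adding an aspect-ratio test would silently change the hit set.

Each residue contributes an 11-bit many-hot string — positions 1–3 a size
thermometer, 4–6 a hydrophobicity thermometer, then single bits for
H-bond acceptor, H-bond donor, positive ionizable, negative ionizable and
aromatic. The shipped 20-row table
(`inst/extdata/residue_bits.tsv`) is built from standard physicochemical
classifications:

* **size**: side-chain heavy-atom count, thermometer thresholds ≥ 2, ≥ 5,
  ≥ 8 atoms, so glycine is `000` and tryptophan `111`;
* **hydrophobicity**: the Fauchère–Pliška side-chain π scale with
  thresholds ≥ 0.2, ≥ 1.0, ≥ 1.8. This scale was chosen over the
  Kyte–Doolittle scale because it places tryptophan at the maximum
  (π = 2.25) and glycine at zero, matching the encoding's anchor cases,
  whereas Kyte–Doolittle ranks tryptophan mid-scale;
* **flags** from side-chain chemistry; histidine is encoded as a neutral
  aromatic donor/acceptor, not positive ionizable, reflecting its dominant
  state at pH 7.4. The table is a plain TSV, so an alternative encoding
  can be dropped in.

The three 11-bit strings are concatenated under all 3! orderings into six
33-bit fingerprints, which makes matching invariant to residue order.
Matching is *exact binary equality*: the encoding is deliberately coarse,
and precision is deferred to the scoring step. The database index keys on
the lexicographically smallest of the six, which guarantees order
invariance without double counting. An edge-compatibility gate
(corresponding edges within 2 Å, configurable) discards bit-equal but
geometrically incompatible pairs before alignment, since the fingerprint
carries no geometry beyond the window itself.

## Alignment

A matched permutation defines a 3-point correspondence between database
and target Cα atoms. The fragment is transplanted by least-squares rigid
superposition (Kabsch/SVD) restricted to **proper rotations**
(det R = +1): reflections would transplant mirror-image chemistry. Note
that for three labeled points — which are always coplanar — a mirrored
triangle remains properly congruent, so the constraint manifests as the
solver never returning a determinant of −1 rather than as a nonzero
residual; the test suite checks exactly that. Degenerate (collinear)
triangles cannot occur inside the edge window. Duplicate poses of the
same FRASE are merged when fragment centroids fall within 0.5 Å.

## Interaction fingerprint and nativeness model

A seeded pose with its target environment is featurized as

$$ f_{mn} = \sum_{i \in \text{lig}} \sum_{j \in \text{prot}}
  \delta_{mi}\,\delta_{nj}\,w(d_{ij}), \qquad
  w(d) = \begin{cases} e^{-(d-3)^2} & d \le 10\ \text{Å} \\ 0 & d > 10\ \text{Å}\end{cases} $$

over a fixed vocabulary of 29 ligand × 13 protein atom types
(377 features; element *l* = (m−1)·13 + n). The weight peaks at the 3 Å
contact optimum and decays smoothly to the 10 Å cutoff. A hard-count
variant (each pair within 5 Å counts 1) is available behind the
`hard_count` flag; the distance-weighted form is the canonical featurizer
because it is the more precisely specified of the two and degrades
gracefully at pose errors.

Atoms may carry several types (a benzene carbon is both "Aromatic" and
"Aromatic Carbon") and then contribute to every matching element — the
Kronecker-delta sum accommodates this naturally. Ligand typing is
implemented as documented graph rules over elements, bond orders and
perceived rings (no SMARTS engine is required at runtime); the "Hetero"
type is taken to cover all non-carbon heavy atoms (N, O, S, P), the more
conservative reading. Protein typing is a per-residue template lookup on
PDB atom names (`inst/extdata/protein_atom_types.tsv`) with backbone
wildcard rows; atoms without a template row (e.g. CYS SG, for which the
13-type vocabulary has no label) simply contribute nothing. Hydrogens are
ignored throughout — deposited structures are typically hydrogen-free and
all radii/thresholds here are heavy-atom conventions.

The classifier is a dense network 377 → 32 (ReLU) → 16 (ReLU) → 1
(sigmoid), trained with Adam (learning rate 10⁻³, the optimizer default;
batch size 50) on binary cross-entropy, with per-feature z-scaling fitted
on the training pool and stored with the model. The operating default is
500 epochs; the test suite trains at 50 epochs, which already saturates
accuracy on the synthetic sets. Training is deterministic under the seed:
initialization, the train/holdout split (90/10 by FRASE) and batch order
all draw from one seeded generator.

**Decoys** pair each true environment with a fragment drawn uniformly
from a *different* FRASE, rigidly translated so its centroid coincides
with the native fragment's centroid (default multiplicity 2). Recentring
without rotation preserves pocket occupancy while scrambling the
chemistry–geometry registration, which is precisely the signal the
classifier must learn; an optional random-rotation flag exists. Decoys
are not filtered for clashes — a clashing decoy is simply an easy
negative.

## Filters

Three pure predicates, applied in order for funnel logging:

| filter | rule | default |
|---|---|---|
| collision | min fragment–protein heavy-atom distance | ≥ 1.0 Å |
| buriedness | mean protein heavy atoms within 5 Å per fragment atom | ≥ 5.0 |
| fitness | nativeness score | ≥ 0.4 |

All bounds are inclusive; buriedness is an *average* over fragment atoms,
not a per-atom minimum. Because the predicates are independent, the
surviving set does not depend on application order, and it shrinks
monotonically as any threshold tightens.

## Pharmacophore clustering

Surviving fragments yield features of six types: Ar at aromatic-ring
centroids, Hyd at centroids of connected aliphatic-carbon groups, HBD and
HBA on qualifying atoms, Pos on positive-ionizable atoms, and Neg at the
centroid of each negative-ionizable group (one feature per carboxylate,
not per oxygen). Features are clustered *per type* — clustering "by type
and 3D coordinates" is realized exactly by running k-means independently
within each type, avoiding any arbitrary type-vs-distance weighting — and
the number of clusters is emergent: for each type, k increases from 1
(10 restarts per k, seeded) until every cluster's maximum member-member
distance is ≤ 3 Å. "Maximum distance between cluster members" is read as
the cluster diameter, not distance-to-centroid. Clusters are ranked by
size, ties broken by compactness. Query assembly from selected centroids
is an explicit user choice (pocket adjacency is a judgment call); the
exported tolerance radius defaults to 1.5 Å, half the diameter bound.

## Synthetic fixtures: what they do and do not show

The fixture module generates every input the tests need:

* **planted proteins** place triplet Cα atoms at exact edge lengths and
  rejection-sample filler residues so that all filler–filler and
  filler–planted Cα distances exceed 12.5 Å — unintended qualifying
  triplets are geometrically impossible, giving an exact ground-truth
  count;
* a **planted complex** surrounds a para-cresol-like ligand with a
  TRP/GLY/ARG triplet, a LYS donor at ~3 Å from the hydroxyl, a stacked
  PHE and LEU packing, so that database construction, self-screening,
  burial and scoring all have non-trivial positives;
* the **separable FRASE set** plants donor–acceptor and aromatic
  contacts at 2.8–3.6 Å in true FRASEs; fragment-shuffled decoys lose the
  geometric registration. The classes are separable by construction — the
  planted contact features are enriched several-fold in the true class —
  and the classifier reaches ≥ 0.99 held-out accuracy at 50 epochs, while
  label-permuted (balanced) data sits at chance;
* **feature blobs** (σ = 0.5 Å, centers ≥ 8 Å apart) give k-means a
  recoverable ground truth.

Side chains in fixtures are minimal proxies (correctly named atoms laid
out along a direction vector), not rotamers. Passing tests therefore
demonstrate algorithmic correctness — oracle equivalence, invariances,
exact thresholds, determinism — on geometry the algorithms fully
determine. They do not demonstrate that the nativeness signal learned
from real crystal structures transfers to a particular real target, nor
realistic protein geometry; conclusions about a real screening campaign
require a database built from real complexes.

## Numerical choices and degenerate inputs

* Distances are heavy-atom Euclidean; squared-distance matrices are
  clamped at zero before the square root.
* The feature index map is fixed and documented (ligand-type major);
  fingerprints are named so misalignment is detectable.
* k-means receives coincident points specially: when the number of
  distinct coordinates is at most k, each distinct point becomes its own
  cluster (diameter 0) without invoking `stats::kmeans`.
* An empty environment makes a target FRASE unscorable; such poses are
  excluded from scoring and counted in the funnel.
* A ligand with no breakable bonds yields itself if inside the MW window,
  otherwise nothing; a featureless fragment yields an empty feature set,
  not an error.
* Z-scaling uses σ = 1 for constant features; the all-zero fingerprint
  maps to a single fixed score for a given model.
* JSON reports round floating point to 10 digits so that byte-identical
  reruns are a meaningful determinism contract.

## Problem sizes used in the test suite

Oracle-equivalence suites run on 50 random typed FRASEs (fingerprints),
40-residue proteins (triplet enumeration, ~10⁴ triples) and ≤ 100
triplets per side (matching). The classifier suite uses 500 true + 1000
decoy FRASEs at 50 epochs; the end-to-end suite uses the planted complex
(11 residues, 4 FRASEs) with a 120-FRASE training set. These sizes keep
the whole suite under a minute of compute while exercising every code
path at scales where the brute-force references remain exact.

## Known limitations

* Exact-equality fingerprint matching cannot find near-miss triplets; the
  optional Tanimoto relaxation is deliberately off by default.
* Bond perception for ligands read from PDB (rather than SDF) is
  distance-based with single orders; supply an SDF for correct bond
  orders when typing matters.
* Aromaticity perception is pragmatic (explicit aromatic bond orders, or
  5/6-rings with the usual alternation count), not a full electron model.
* The residue-bit table and protein templates are fixed physicochemical
  choices; both are plain data files and can be replaced wholesale.
* No protonation-state prediction, no structure repair, and no
  flexible-protein matching.
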