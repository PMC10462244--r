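# frasebot

Fragment-based ligand discovery for proteins without known binders.
`frasebot` seeds ligand fragments into a target protein structure by
matching **residue-triplet fingerprints** against a database of
**FRA**gments in **S**tructural **E**nvironments (FRASEs), scores every
seeded pose with a neural **nativeness** classifier over a
distance-weighted protein–ligand interaction fingerprint, filters the
poses geometrically, and turns the survivors into a clustered
**pharmacophore query** for virtual screening.

The package is aimed at computational chemists working on hard-to-drug
targets (signalling proteins, transcription factors) that lack a natural
small-molecule pocket: it transfers 3D binding information from known
protein–ligand complexes into the target without any explicit binding-site
detection or family alignment.

## Method

**FRASE database.** Each source complex ligand is fragmented by breaking
subsets of acyclic single bonds (rings are never broken; when a cut
detaches a substituent from a cyclic fragment, the substituent's α-atom is
retained). Fragments of 50–300 Da are stored together with their
structural environment — every protein residue with at least one heavy
atom within 4.5 Å of the fragment.

**Triplet screening.** Every triple of residues whose Cα atoms form an
approximately equilateral triangle with edges in [8, 12] Å is encoded as a
33-bit fingerprint: three concatenated 11-bit many-hot residue strings
(positions 1–3 size, 4–6 hydrophobicity, then H-bond acceptor/donor,
positive/negative ionizable, aromatic). Six order-permuted fingerprints
make the match invariant to residue order. A matched triplet defines a
3-point rigid (Kabsch) superposition that transplants the database
fragment into the target frame.

**Nativeness scoring.** A seeded pose and its target environment are
featurized as

f<sub>mn</sub> = Σ<sub>i∈ligand</sub> Σ<sub>j∈protein</sub>
δ<sub>mi</sub> δ<sub>nj</sub> w(d<sub>ij</sub>),  w(d) = exp(−(d−3)²) for
d ≤ 10 Å, else 0

over 29 ligand atom types × 13 protein atom types = **377 features**. A
dense network (377 → 32 ReLU → 16 ReLU → 1 sigmoid; Adam, batch 50,
binary cross-entropy) is trained to separate true FRASEs from decoys made
by shuffling fragments between FRASEs; its output in (0, 1) is the
nativeness score.

**Filtering and pharmacophores.** Poses must not collide with the protein
(every fragment atom ≥ 1 Å from protein atoms), must be buried (on
average ≥ 5 protein atoms within 5 Å per fragment atom), and must score
≥ 0.4. Surviving fragments are converted to typed pharmacophoric features
(HBD, HBA, Pos, Neg, Ar, Hyd) and k-means-clustered per type under a 3 Å
maximum member-distance; the largest cluster centroids form the query.

## Worked example

All inputs are generated by the package's fixture module, so the example
runs anywhere in seconds:

```r
library(frasebot)

cx    <- make_planted_complex(seed = 3)          # toy pocket + ligand
db    <- build_frase_db(list(cx))                # fragment + environment records
ss    <- make_separable_frase_set(120, multiplicity = 2, seed = 11)
model <- train_model(ss$true, ss$decoys, epochs = 30, seed = 5)
report <- run_pipeline(cx$protein, db, model, run_config(seed = 2))
print(report)
```

```
run_report funnel:
  target_triplets  13
  seeded           40
  scored           36
  post_collision   32
  post_buriedness  8
  post_score       4
  features         10
  clusters         4
```

13 qualifying Cα triplets in the target matched database triplets and
seeded 40 fragment poses; 36 had a non-empty 4.5 Å environment and were
scored; collision, buriedness and the 0.4 score threshold reduced them to
4 native-like poses, whose 10 pharmacophoric features clustered into 4
centroids. The assembled query:

```r
print(as.data.frame(report$query))
```

```
  ftype         x        y        z radius cluster_id
1    Ar -3.618525 2.871596 3.109085    1.5          1
2   HBD -2.560760 0.490026 2.230587    1.5          2
3   HBA -2.560760 0.490026 2.230587    1.5          3
4   Hyd -4.730139 5.374409 4.032307    1.5          4
```

Each row is one typed feature centroid (Å) with its tolerance radius —
the file `export_query()` writes is directly usable as a pharmacophore
screening query. A thin command-line wrapper over the same functions is
in `inst/cli/frasebot.R` (`build-db`, `screen`, `train`, `run`).

## Scope

The package covers database construction, screening, scoring, filtering
and query assembly. Pharmacophore *search* of compound catalogues,
docking, MM-PBSA rescoring and assay triage are downstream steps outside
its scope.
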