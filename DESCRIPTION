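Package: frasebot
Title: Fragment Seeding into Protein Structures via Residue-Triplet
    Matching and Neural Pose Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeds ligand fragments into a target protein structure by
    matching residue-triplet fingerprints against a database of fragments
    in structural environments (FRASEs), scores each seeded pose with a
    small neural classifier over a distance-weighted protein-ligand
    interaction fingerprint (29 ligand x 13 protein atom types, 377
    features), filters poses by collision, buriedness and fitness score,
    and converts the surviving fragments into a clustered pharmacophore
    query for virtual screening. Includes a synthetic-fixture generator
    with planted ground truth so every stage is testable without external
    structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
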