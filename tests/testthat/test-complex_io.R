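test_that("residue encoding matches the documented anchors and is total", {
  trp <- encode_residue("TRP")
  expect_identical(trp[1:3], c(1L, 1L, 1L))   # size thermometer saturated
  expect_identical(trp[4:6], c(1L, 1L, 1L))   # hydrophobicity saturated
  gly <- encode_residue("GLY")
  expect_identical(gly, rep(0L, 11))
  expect_identical(encode_residue("ARG")[9], 1L)  # positive ionizable
  expect_identical(encode_residue("ASP")[10], 1L) # negative ionizable
  expect_identical(encode_residue("PHE")[11], 1L) # aromatic
  for (res in standard_residues()) {
    bits <- encode_residue(res)
    expect_length(bits, 11)
    expect_true(all(bits %in% c(0L, 1L)))
  }
  expect_error(encode_residue("XXX"), "unknown residue")
})

test_that("type vocabularies have the fixed sizes and typing stays in-vocabulary", {
  expect_length(ligand_type_vocab(), 29)
  expect_length(protein_type_vocab(), 13)
  M <- assign_ligand_atom_types(make_biphenyl_acetic())
  expect_identical(colnames(M), ligand_type_vocab())
  P <- assign_protein_atom_types(fixture_residue("LYS", c(0, 0, 0)))
  expect_identical(colnames(P), protein_type_vocab())
})

test_that("ligand atom typing follows the documented substructure rules", {
  benz <- assign_ligand_atom_types(make_benzene())
  for (i in 1:6) {
    expect_setequal(colnames(benz)[benz[i, ]], c("Aromatic", "Aromatic Carbon"))
  }
  # chlorobenzene: halogen substituent
  cb <- make_benzene()
  cb$atoms <- rbind(cb$atoms, data.frame(element = "CL", x = 2.9, y = 0, z = 0,
                                         is_alpha = FALSE))
  cb$bonds <- rbind(cb$bonds, data.frame(a1 = 1, a2 = 7, order = 1))
  Mcb <- assign_ligand_atom_types(frase_mol(cb$atoms, cb$bonds))
  expect_true(all(c("Halogen", "Cl") %in% colnames(Mcb)[Mcb[7, ]]))
  # acetate oxygens: expected label set derived by hand from the rules
  Mac <- assign_ligand_atom_types(make_acetate())
  for (oi in 3:4) {
    labs <- colnames(Mac)[Mac[oi, ]]
    expect_true(all(c("Carboxylate Oxygen", "Negative Ionizable",
                      "H-bond Acceptor", "Hetero") %in% labs))
  }
  # methyl carbon is aliphatic, not aromatic
  expect_true(Mac[1, "Aliphatic Carbon"])
  expect_false(Mac[1, "Aromatic"])
})

test_that("protein atom typing uses residue templates with backbone fallback", {
  lys <- fixture_residue("LYS", c(0, 0, 0))
  M <- assign_protein_atom_types(lys)
  nz <- which(lys$elety == "NZ")
  expect_setequal(colnames(M)[M[nz, ]],
                  c("Positive Ionizable", "H-bond Donor", "Amine Nitrogen"))
  ala <- fixture_residue("ALA", c(0, 0, 0))
  Ma <- assign_protein_atom_types(ala)
  expect_identical(colnames(Ma)[Ma[which(ala$elety == "CB"), ]],
                   "Aliphatic Carbon")
  phe <- fixture_residue("PHE", c(0, 0, 0))
  Mp <- assign_protein_atom_types(phe)
  expect_setequal(colnames(Mp)[Mp[which(phe$elety == "CG"), ]],
                  c("Aromatic", "Aromatic Carbon"))
  # backbone amide nitrogen via wildcard template
  expect_setequal(colnames(Ma)[Ma[which(ala$elety == "N"), ]],
                  c("H-bond Donor", "Amide Nitrogen"))
})

test_that("complex round-trip preserves counts and coordinates at PDB precision", {
  cx <- make_planted_complex(seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex(cx, path)
  cx2 <- read_complex(path, ligand_selector = "LIG")
  expect_identical(nrow(cx2$protein), nrow(cx$protein))
  expect_identical(nrow(cx2$ligand$atoms), nrow(cx$ligand$atoms))
  expect_lt(max(abs(cx2$protein$x - cx$protein$x)), 1e-3)
  expect_lt(max(abs(cx2$ligand$atoms$z - cx$ligand$atoms$z)), 1e-3)
  expect_identical(residue_table(cx2$protein)$resid,
                   residue_table(cx$protein)$resid)
})

test_that("waters are excluded and non-standard residues are flagged", {
  cx <- make_planted_complex(seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_complex(cx, path)
  # append a water and a selenomethionine residue
  lines <- readLines(path)
  extra <- c(
    "HETATM 9901  O   HOH W 901      99.000  99.000  99.000  1.00  0.00           O",
    "ATOM   9902  CA  MSE A 902      90.000  90.000  90.000  1.00  0.00           C")
  writeLines(c(lines[lines != "END"], extra, "END"), path)
  cx2 <- read_complex(path, ligand_selector = "LIG")
  expect_false("HOH" %in% cx2$protein$resid)
  expect_true("MSE" %in% cx2$protein$resid)
  rt <- residue_table(cx2$protein)
  expect_false(rt$standard[rt$resid == "MSE"])
  # non-standard residues never enter triplet enumeration
  tts <- enumerate_triplets(rt)
  for (tt in tts) expect_false("MSE" %in% tt$residues$resid)
})
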