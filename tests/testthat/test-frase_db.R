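test_that("fragment enumeration honours the molecular-weight window", {
  ethane <- frase_mol(data.frame(element = c("C", "C"),
                                 x = c(0, 1.5), y = 0, z = 0),
                      data.frame(a1 = 1, a2 = 2, order = 1))
  expect_length(fragment_ligand(ethane), 0)   # 30 Da, below the 50 Da floor
  # para-cresol fixture: all retained fragments inside [50, 300]
  frags <- fragment_ligand(fixture_ligand())
  expect_gt(length(frags), 0)
  for (f in frags) {
    expect_gte(f$mw, 50)
    expect_lte(f$mw, 300)
  }
})

test_that("alpha atoms are retained on cyclic fragments", {
  tol <- make_toluene()
  frags <- fragment_ligand(tol)
  # cutting the methyl-ring bond leaves the ring plus the alpha carbon
  ring_frag <- Filter(function(f) length(f$parent_atoms) == 6, frags)
  expect_length(ring_frag, 1)
  f <- ring_frag[[1]]
  expect_identical(nrow(f$atoms), 7L)            # 6 ring C + 1 marker
  expect_identical(sum(f$atoms$is_alpha), 1L)
  expect_equal(f$mw, 92.14, tolerance = 1e-2)    # toluene-equivalent mass
  # the marker carries no atom types
  M <- assign_ligand_atom_types(f)
  expect_false(any(M[which(f$atoms$is_alpha), ]))
})

test_that("fragment enumeration equals the brute-force cut-subset oracle", {
  mol <- make_biphenyl_acetic()
  got <- fragment_ligand(mol, min_mw = 50, max_mw = 300, max_cuts = 4)
  keys <- sort(vapply(got, function(f) paste(f$parent_atoms, collapse = ","), ""))
  expect_identical(keys, oracle_fragments(mol, 50, 300, max_cuts = 4))
  # alpha-marker and weight agreement on every fragment
  for (f in got) {
    of <- extract_fragment_oracle(
      mol, f$parent_atoms, in_ring(mol),
      integer())
    expect_true(all(f$atoms$element[!f$atoms$is_alpha] ==
                    of$atoms$element[!of$atoms$is_alpha]))
  }
})

test_that("fragmentation never breaks rings and inherits coordinates", {
  for (s in 1:5) {
    mol <- random_mol(n_atoms = 7, with_ring = TRUE, seed = s)
    ring_bond_ids <- setdiff(seq_len(nrow(mol$bonds)),
                             acyclic_single_bonds(mol))
    frags <- fragment_ligand(mol, min_mw = 10, max_mw = 1000)
    for (f in frags) {
      core <- f$atoms[!f$atoms$is_alpha, , drop = FALSE]
      expect_true(all(f$parent_atoms %in% seq_len(nrow(mol$atoms))))
      expect_equal(core$x, mol$atoms$x[f$parent_atoms])
      expect_equal(core$z, mol$atoms$z[f$parent_atoms])
      # every ring bond with both ends in the fragment is present in it
      for (k in ring_bond_ids) {
        if (all(c(mol$bonds$a1[k], mol$bonds$a2[k]) %in% f$parent_atoms)) {
          i <- match(mol$bonds$a1[k], f$parent_atoms)
          j <- match(mol$bonds$a2[k], f$parent_atoms)
          expect_true(any((f$bonds$a1 == i & f$bonds$a2 == j) |
                          (f$bonds$a1 == j & f$bonds$a2 == i)))
        }
      }
    }
  }
})

test_that("environment extraction applies the 4.5 A residue shell exactly", {
  frag <- make_stub("C", c(0, 0, 0))
  mk <- function(resno, dist) {
    df <- fixture_residue("ALA", c(dist + 1.5, 30, 0), "A", resno)
    df[df$elety == "CB", c("x", "y", "z")] <- list(dist, 0, 0)
    df
  }
  inside <- do.call(rbind, lapply(1:7, function(i) mk(i, 4.4 - 0.3 * i)))
  outside <- do.call(rbind, lapply(8:12, function(i) mk(i, 4.6 + 0.5 * i)))
  prot <- rbind(inside, outside)
  env <- extract_environment(prot, frag, 4.5)
  expect_setequal(unique(env$resno), 1:7)
  # boundary: 4.4 in, 4.6 out
  env2 <- extract_environment(rbind(mk(1, 4.4), mk(2, 4.6)), frag, 4.5)
  expect_identical(unique(env2$resno), 1L)
  # monotone in radius
  env6 <- extract_environment(prot, frag, 6)
  expect_true(all(unique(env$resno) %in% unique(env6$resno)))
})

test_that("database build yields one FRASE per fragment with a shell", {
  cx <- make_planted_complex(seed = 4)
  db <- build_frase_db(list(cx))
  n_frags <- length(fragment_ligand(cx$ligand))
  expect_identical(length(db$frases), n_frags)  # pocket encloses the ligand
  for (fr in db$frases) {
    expect_gt(nrow(fr$environment), 0)
    expect_identical(fr$label, "true")
  }
  expect_identical(length(build_frase_db(list())$frases), 0L)
})

test_that("database SDF round-trip is lossless for counts, labels and coordinates", {
  cx <- make_planted_complex(seed = 4)
  db <- build_frase_db(list(cx))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_db(db, path)
  db2 <- read_db(path)
  expect_identical(length(db2$frases), length(db$frases))
  for (i in seq_along(db$frases)) {
    a <- db$frases[[i]]; b <- db2$frases[[i]]
    expect_identical(b$id, a$id)
    expect_identical(b$label, a$label)
    expect_identical(nrow(b$fragment$atoms), nrow(a$fragment$atoms))
    expect_identical(b$fragment$atoms$is_alpha, a$fragment$atoms$is_alpha)
    expect_lt(max(abs(b$fragment$atoms$x - a$fragment$atoms$x)), 1e-4)
    expect_identical(nrow(b$environment), nrow(a$environment))
    expect_lt(max(abs(b$environment$z - a$environment$z)), 1e-4)
  }
  expect_identical(sort(ls(db2$index$keys)), sort(ls(db$index$keys)))
})
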