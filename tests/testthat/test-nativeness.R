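# minimal one-ligand-atom / one-protein-atom frase at a given separation
pair_frase <- function(d) {
  frag <- make_stub("C", c(0, 0, 0))             # types: {Aliphatic Carbon}
  prot <- fixture_residue("ALA", c(d + 30, 0, 0))
  prot <- prot[prot$elety == "CB", , drop = FALSE]
  prot[, c("x", "y", "z")] <- list(d, 0, 0)      # CB: {Aliphatic Carbon}
  new_frase(frag, prot, label = "true")
}

test_that("the distance weight peaks at 3 A, decays, and cuts off at 10 A", {
  expect_identical(distance_weight(3), 1)
  d <- seq(3, 10, by = 0.25)
  w <- distance_weight(d)
  expect_true(all(diff(w) < 0))
  expect_identical(distance_weight(10.001), 0)
  expect_gt(distance_weight(10), 0)
})

test_that("a single typed pair at 3 A produces exactly one unit feature", {
  fp <- interaction_fingerprint(pair_frase(3.0))
  expect_length(fp, 377)
  l <- which(fp != 0)
  expect_length(l, 1)
  expect_equal(unname(fp[l]), 1.0, tolerance = 1e-12)
  expect_identical(names(fp)[l], "Aliphatic Carbon | Aliphatic Carbon")
  # index layout: l = (m-1)*13 + n
  m <- match("Aliphatic Carbon", ligand_type_vocab())
  n <- match("Aliphatic Carbon", protein_type_vocab())
  expect_identical(unname(l), (m - 1L) * 13L + n)
  # beyond the cutoff the fingerprint is identically zero
  expect_true(all(interaction_fingerprint(pair_frase(11.0)) == 0))
})

test_that("the fingerprint equals the brute-force double loop on random fixtures", {
  for (s in 1:12) {
    fr <- random_typed_frase(s)
    expect_equal(unname(interaction_fingerprint(fr)), oracle_fingerprint(fr),
                 tolerance = 1e-9)
  }
})

test_that("fingerprints are additive over ligand atoms and rigid-motion invariant", {
  fr <- random_typed_frase(3)
  # additivity: two stub ligand atoms vs the sum of the singletons
  env <- fr$environment
  a1 <- make_stub("C", c(0, 0, 0)); a2 <- make_stub("O", c(2, 1, 0))
  both <- frase_mol(rbind(a1$atoms, a2$atoms))
  fp_both <- interaction_fingerprint(new_frase(both, env))
  fp_sum <- interaction_fingerprint(new_frase(a1, env)) +
    interaction_fingerprint(new_frase(a2, env))
  expect_equal(fp_both, fp_sum, tolerance = 1e-12)
  # rigid motion applied to fragment and environment together
  set.seed(5); R <- random_rot3(); tr <- c(1, -3, 2)
  fr2 <- fr
  fr2$fragment <- frasebot:::apply_transform_mol(fr$fragment, R, tr)
  xyz <- as.matrix(fr$environment[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, tr, "+")
  fr2$environment$x <- xyz[, 1]; fr2$environment$y <- xyz[, 2]
  fr2$environment$z <- xyz[, 3]
  expect_equal(interaction_fingerprint(fr2), interaction_fingerprint(fr),
               tolerance = 1e-9)
})

test_that("decoy generation shuffles fragments, preserves counts and is seeded", {
  ss <- make_separable_frase_set(6, multiplicity = 2, seed = 21)
  expect_length(ss$decoys, 12)   # multiplicity x true count exactly
  sig <- function(mol) paste(round(mol$atoms$x, 6), round(mol$atoms$y, 6),
                             collapse = ";")
  for (i in seq_along(ss$decoys)) {
    dec <- ss$decoys[[i]]
    native <- ss$true[[ceiling(i / 2)]]
    expect_identical(dec$label, "decoy")
    # environment kept, fragment replaced
    expect_identical(dec$environment, native$environment)
    expect_false(identical(sig(dec$fragment), sig(native$fragment)))
    # centroid preserved by the recentring rule
    cent <- function(m) colMeans(as.matrix(m$atoms[, c("x", "y", "z")]))
    expect_equal(cent(dec$fragment), cent(native$fragment), tolerance = 1e-9)
  }
  d2 <- generate_decoys(ss$true, multiplicity = 2, seed = 22)
  d3 <- generate_decoys(ss$true, multiplicity = 2, seed = 22)
  expect_equal(d2, d3)
  same <- list(ss$true[[1]], ss$true[[1]])
  expect_error(generate_decoys(same, 1, seed = 1), "identical")
})

test_that("training is deterministic and scoring is rigid-motion invariant", {
  ss <- make_separable_frase_set(40, multiplicity = 2, seed = 33)
  X <- t(vapply(c(ss$true, ss$decoys), interaction_fingerprint, numeric(377)))
  m1 <- train_model(ss$true, ss$decoys, epochs = 5, seed = 9, fingerprints = X)
  m2 <- train_model(ss$true, ss$decoys, epochs = 5, seed = 9, fingerprints = X)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$holdout_accuracy, m2$holdout_accuracy)
  # scores live in (0, 1) and only depend on the fingerprint
  sc <- score_frases(m1, ss$true[1:5])
  expect_true(all(sc > 0 & sc < 1))
  fr <- ss$true[[1]]
  set.seed(2); R <- random_rot3()
  fr2 <- fr
  fr2$fragment <- frasebot:::apply_transform_mol(fr$fragment, R, c(4, 4, 4))
  xyz <- as.matrix(fr$environment[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, c(4, 4, 4), "+")
  fr2$environment$x <- xyz[, 1]; fr2$environment$y <- xyz[, 2]
  fr2$environment$z <- xyz[, 3]
  expect_equal(score_frases(m1, fr2), score_frases(m1, fr), tolerance = 1e-6)
  # the all-zero fingerprint maps to one fixed score
  z1 <- score_frases(m1, fingerprints = matrix(0, 1, 377))
  z2 <- score_frases(m1, fingerprints = matrix(0, 1, 377))
  expect_identical(z1, z2)
  expect_error(score_frases(m1, fingerprints = matrix(0, 1, 10)), "match")
})

test_that("model serialization round-trips scores exactly", {
  ss <- make_separable_frase_set(20, multiplicity = 1, seed = 44)
  m <- train_model(ss$true, ss$decoys, epochs = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(score_frases(m2, ss$true[1:3]), score_frases(m, ss$true[1:3]),
               tolerance = 1e-12)
})
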