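res_at <- function(names, coords) {
  do.call(rbind, lapply(seq_along(names), function(i)
    fixture_residue(names[i], coords[i, ], "A", i)))
}

test_that("triplet enumeration enforces the 8-12 A edge window", {
  eq <- res_at(c("TRP", "GLY", "ARG"),
               rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(75), 0)))
  tts <- enumerate_triplets(residue_table(eq))
  expect_length(tts, 1)
  expect_equal(unname(tts[[1]]$edges), c(10, 10, 10), tolerance = 1e-9)
  # one edge below the lower bound disqualifies the triple
  short <- res_at(c("TRP", "GLY", "ARG"),
                  rbind(c(0, 0, 0), c(7.9, 0, 0), c(3.95, 9.19, 0)))
  expect_length(enumerate_triplets(residue_table(short)), 0)
  expect_length(enumerate_triplets(residue_table(eq)[1:2, ]), 0)
})

test_that("triplet enumeration equals the brute-force O(n^3) reference", {
  set.seed(31)
  n <- 30
  coords <- matrix(runif(3 * n, 0, 25), ncol = 3)
  prot <- res_at(sample(standard_residues(), n, replace = TRUE), coords)
  rt <- residue_table(prot)
  tts <- enumerate_triplets(rt)
  keys <- sort(vapply(tts, function(t) paste(sort(t$residues$resno),
                                             collapse = "-"), ""))
  expect_identical(keys, oracle_triplets(rt))
  expect_gt(length(tts), 0)  # the fixture must actually exercise the window
})

test_that("six permutation fingerprints are emitted with length 33", {
  eq <- res_at(c("TRP", "GLY", "ARG"),
               rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(75), 0)))
  tt <- enumerate_triplets(residue_table(eq))[[1]]
  fps <- triplet_fingerprints(tt)
  expect_length(fps, 6)
  expect_true(all(nchar(fps) == 33))
  expect_length(unique(fps), 6)   # three distinct residues
  # expected set: all 6 concatenations of the member bitstrings
  bits <- vapply(c("TRP", "GLY", "ARG"), function(r)
    paste(encode_residue(r), collapse = ""), "")
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  expected <- vapply(perms, function(p) paste(bits[p], collapse = ""), "")
  expect_setequal(fps, expected)
  # identical residues collapse the six onto one string
  ala <- res_at(c("ALA", "ALA", "ALA"),
                rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(75), 0)))
  fps_ala <- triplet_fingerprints(enumerate_triplets(residue_table(ala))[[1]])
  expect_length(unique(fps_ala), 1)
  expect_length(fps_ala, 6)
})

test_that("matching is invariant to residue order and equals all-pairs search", {
  cx <- make_planted_complex(seed = 5)
  db <- build_frase_db(list(cx))
  # target with the planted triplet in a different residue order
  tri <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(75), 0))
  for (ord in list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))) {
    tgt <- res_at(c("TRP", "GLY", "ARG")[ord], tri[ord, , drop = FALSE])
    tts <- enumerate_triplets(residue_table(tgt))
    m <- match_triplets(tts, db)
    expect_gt(length(m), 0)
  }
  # oracle equivalence on a mixed fixture
  set.seed(7)
  n <- 12
  coords <- matrix(runif(3 * n, 0, 18), ncol = 3)
  tgt <- res_at(sample(c("TRP", "GLY", "ARG", "ALA", "LEU"), n, replace = TRUE),
                coords)
  tts <- enumerate_triplets(residue_table(tgt))
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  got <- character()
  for (ti in seq_along(tts)) {
    for (x in match_triplets(tts[ti], db)) {
      pr <- which(apply(perms, 1, function(p) all(p == x$perm)))
      got <- c(got, paste(ti, x$frase_id, pr, sep = ":"))
    }
  }
  expect_identical(sort(got), oracle_matches(tts, db))
})

test_that("3-point superposition is exact, proper and optimal", {
  set.seed(11)
  src <- matrix(rnorm(9, sd = 4), 3)
  # self-alignment
  fit0 <- kabsch_3pt(src, src)
  expect_lt(fit0$rmsd, 1e-6)
  expect_equal(fit0$rot, diag(3), tolerance = 1e-9)
  # recovery of a planted rigid motion
  R <- random_rot3(); tr <- c(3, -2, 7)
  dst <- sweep(src %*% t(R), 2, tr, "+")
  fit <- kabsch_3pt(src, dst)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rot, R, tolerance = 1e-6)
  expect_equal(fit$trans, tr, tolerance = 1e-6)
  expect_equal(det(fit$rot), 1, tolerance = 1e-9)
  # reflections are excluded: the returned transform is always a proper
  # rotation, even when the source is mirrored (three labeled points are
  # planar, so a mirrored triangle is still properly congruent - the
  # constraint shows up as det(R) = +1, never -1)
  fitm <- kabsch_3pt(src, dst %*% diag(c(-1, 1, 1)))
  expect_equal(det(fitm$rot), 1, tolerance = 1e-9)
  # optimality against random proper rotations
  obj <- function(Rot) {
    A <- sweep(src, 2, colMeans(src)); B <- sweep(dst, 2, colMeans(dst))
    sqrt(mean(rowSums((A %*% t(Rot) - B)^2)))
  }
  best <- min(vapply(1:100, function(i) obj(random_rot3()), 1))
  expect_lte(fit$rmsd, best + 1e-12)
})

test_that("screening recovers a planted pose and moves rigidly with the target", {
  cx <- make_planted_complex(seed = 6)
  db0 <- build_frase_db(list(cx))
  db <- db0
  db$frases <- db0$frases[1]
  db$index <- build_triplet_index(db)
  seeded <- screen(cx$protein, db)
  expect_gte(length(seeded), 1)
  # the self-match pose is recovered at RMSD ~ 0 and the planted position
  rms <- vapply(seeded, function(s) s$alignment_rmsd, 1)
  expect_lt(min(rms), 1e-9)
  native_ctr <- colMeans(as.matrix(db$frases[[1]]$fragment$atoms[, c("x","y","z")]))
  best <- seeded[[which.min(rms)]]
  expect_equal(unname(best$centroid), unname(native_ctr), tolerance = 1e-6)

  # rigid motion of the whole target: same matches, co-moving poses
  set.seed(13)
  R <- random_rot3(); tr <- c(5, 1, -4)
  prot2 <- cx$protein
  xyz <- as.matrix(prot2[, c("x", "y", "z")])
  xyz2 <- sweep(xyz %*% t(R), 2, tr, "+")
  prot2$x <- xyz2[, 1]; prot2$y <- xyz2[, 2]; prot2$z <- xyz2[, 3]
  seeded2 <- screen(prot2, db)
  expect_identical(length(seeded2), length(seeded))
  rms2 <- vapply(seeded2, function(s) s$alignment_rmsd, 1)
  moved_ctr <- as.vector(native_ctr %*% t(R)) + tr
  best2 <- seeded2[[which.min(rms2)]]
  expect_equal(unname(best2$centroid), moved_ctr, tolerance = 1e-6)

  # a database with no matching fingerprints yields nothing
  faraway <- res_at(c("SER", "SER", "SER"),
                    rbind(c(0, 0, 0), c(10, 0, 0), c(5, sqrt(75), 0)))
  expect_length(screen(faraway, db), 0)
})
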