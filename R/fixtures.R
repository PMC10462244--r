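#' @title Synthetic fixtures with planted ground truth
#' @description
#' Generators for toy proteins, complexes, FRASE sets and feature clouds
#' whose ground truth (planted triplets, separable interaction patterns,
#' blob centers) is known by construction, so that every pipeline stage is
#' testable without external structure downloads. Side chains are minimal
#' proxies (a few correctly named atoms laid out along a direction vector)
#' rather than full rotamers: the algorithms consume atom types and
#' distances, not chemistry beyond typing. All generators are
#' seed-deterministic.
#' @name fixtures
NULL

# minimal side-chain atom-name chains, laid out from CA along a direction
.sidechain_atoms <- list(
  ALA = c("CB"),
  GLY = character(),
  SER = c("CB", "OG"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD1", "NE1", "CD2", "CE2", "CE3", "CZ2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  THR = c("CB", "OG1", "CG2"),
  VAL = c("CB", "CG1", "CG2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "SD", "CE"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  CYS = c("CB", "SG"),
  PRO = c("CB", "CG", "CD")
)

#' Build a minimal fixture residue
#'
#' Backbone (N, CA, C, O) around the given CA position plus a proxy side
#' chain whose atoms step 1.4 A apart from the CA along `toward` (with a
#' small lateral stagger so atoms do not stack), using correct PDB atom
#' names so template-based typing applies.
#'
#' @param resid 3-letter code.
#' @param ca Numeric length-3 CA position.
#' @param chain,resno Chain id and residue number.
#' @param toward Optional point the side chain should extend towards
#'   (default: +y from the CA).
#' @param approach Standoff distance in Angstrom: when `toward` is given,
#'   the side chain stops `approach` short of the target point instead of
#'   running through it (default 4.0, a van-der-Waals contact shell).
#' @return Protein atom data.frame rows.
#' @export
fixture_residue <- function(resid, ca, chain = "A", resno = 1L, toward = NULL,
                            approach = 4.0) {
  u <- if (is.null(toward)) c(0, 1, 0) else toward - ca
  nu <- sqrt(sum(u^2)); u <- if (nu < 1e-9) c(0, 1, 0) else u / nu
  # lateral unit vector orthogonal to u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  v <- ref - sum(ref * u) * u; v <- v / sqrt(sum(v^2))
  names_ <- c("N", "CA", "C", "O")
  coords <- rbind(ca - 1.46 * v - 0.4 * u, ca, ca + 1.52 * v - 0.4 * u,
                  ca + 1.52 * v - 0.4 * u + c(0, 0, 1.23))
  sc <- .sidechain_atoms[[resid]]
  if (is.null(sc)) sc <- c("CB")
  step <- 1.4
  if (!is.null(toward) && length(sc) > 0) {
    reach <- max(1.4, nu - approach)
    step <- min(1.4, reach / length(sc))
  }
  for (k in seq_along(sc)) {
    lateral <- if (k %% 2 == 0) 0.5 * v else -0.25 * v
    coords <- rbind(coords, ca + (step * k) * u + lateral)
    names_ <- c(names_, sc[k])
  }
  el <- toupper(substr(names_, 1, 1))
  data.frame(elety = names_, element = el, resid = resid, chain = chain,
             resno = as.integer(resno), x = coords[, 1], y = coords[, 2],
             z = coords[, 3], standard = resid %in% standard_residues(),
             stringsAsFactors = FALSE)
}

# CA triangle with prescribed edge lengths (d12, d13, d23), in the z=0 plane
triangle_coords <- function(edges) {
  d12 <- edges[1]; d13 <- edges[2]; d23 <- edges[3]
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(max(d13^2 - x3^2, 0))
  rbind(c(0, 0, 0), c(d12, 0, 0), c(x3, y3, 0))
}

#' Generate a protein with planted residue triplets
#'
#' Each planted triplet's CA atoms are placed at exactly the requested
#' edge lengths (triplets stacked 40 A apart along z); side chains point
#' at the triangle centroid. Filler ALA residues are rejection-sampled so
#' every filler CA is at least 12.5 A from all other CA atoms, which makes
#' unintended qualifying triplets impossible (every edge involving a
#' filler exceeds the 12 A window).
#'
#' @param spec List with fields `seed`, `n_residues` (filler count),
#'   `planted_triplets` (list of `list(names, edges)`), `noise` (CA jitter
#'   sd in Angstrom, default 0).
#' @return Protein atom data.frame.
#' @export
make_planted_protein <- function(spec) {
  set.seed(spec$seed %||% 1)
  noise <- spec$noise %||% 0
  rows <- list(); cas <- NULL; resno <- 0L
  for (ti in seq_along(spec$planted_triplets %||% list())) {
    pt <- spec$planted_triplets[[ti]]
    tri <- triangle_coords(pt$edges)
    tri[, 3] <- tri[, 3] + 40 * (ti - 1)
    ctr <- colMeans(tri)
    for (k in 1:3) {
      resno <- resno + 1L
      ca <- tri[k, ] + stats::rnorm(3, sd = noise)
      rows[[length(rows) + 1]] <- fixture_residue(pt$names[k], ca, "A", resno,
                                                  toward = ctr)
      cas <- rbind(cas, ca)
    }
  }
  n_fill <- spec$n_residues %||% 0
  tries <- 0
  while (n_fill > 0 && tries < 20000) {
    tries <- tries + 1
    cand <- stats::runif(3, min = -35, max = 35) + c(0, 0, -45)
    if (is.null(cas) || min(sqrt(rowSums(sweep(cas, 2, cand)^2))) >= 12.5) {
      resno <- resno + 1L
      rows[[length(rows) + 1]] <- fixture_residue("ALA", cand, "A", resno)
      cas <- rbind(cas, cand)
      n_fill <- n_fill - 1
    }
  }
  do.call(rbind, rows)
}

#' A toy para-cresol-like ligand
#'
#' Six-membered aromatic ring (Kekule alternation), a hydroxyl at C4 and a
#' methyl at C1, centered at `center`. Fragments of this ligand fall in
#' the 50-300 Da window, making it a convenient database fixture.
#'
#' @param center Length-3 position of the ring centroid.
#' @param rotation Optional 3x3 rotation applied about the centroid.
#' @return A [frase_mol()].
#' @export
fixture_ligand <- function(center = c(0, 0, 0), rotation = diag(3)) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  oh <- (1.39 + 1.36) * c(cos(ang[4]), sin(ang[4]), 0)
  me <- (1.39 + 1.50) * c(cos(ang[1]), sin(ang[1]), 0)
  atoms <- data.frame(
    element = c(rep("C", 6), "O", "C"),
    x = c(ring[, 1], oh[1], me[1]), y = c(ring[, 2], oh[2], me[2]),
    z = c(ring[, 3], oh[3], me[3]))
  bonds <- data.frame(
    a1 = c(1, 2, 3, 4, 5, 6, 4, 1), a2 = c(2, 3, 4, 5, 6, 1, 7, 8),
    order = c(2, 1, 2, 1, 2, 1, 1, 1))
  mol <- frase_mol(atoms, bonds)
  mol <- apply_transform_mol(mol, rotation, center - as.vector(center %*% t(rotation)))
  # recentre exactly
  sh <- center - colMeans(as.matrix(mol$atoms[, c("x", "y", "z")]))
  mol$atoms$x <- mol$atoms$x + sh[1]; mol$atoms$y <- mol$atoms$y + sh[2]
  mol$atoms$z <- mol$atoms$z + sh[3]
  mol
}

#' Generate a toy protein-ligand complex with a planted pocket
#'
#' The fixture ligand sits at the centroid of a planted TRP/GLY/ARG CA
#' triplet (edges `edges`), with side chains pointing inward so the
#' environment shell at 4.5 A is non-empty. The pocket instantiates the
#' native-like interaction chemistry of [make_separable_frase_set()]: a
#' LYS amine donor at ~3 A from the ligand hydroxyl, a PHE aromatic probe
#' stacked ~3.5 A off the ring plane, plus LEU packing residues for
#' buriedness.
#'
#' @param seed Integer seed.
#' @param edges Triplet edge lengths (default `c(10, 10, 10)`).
#' @param n_pack Number of packing LEU residues (default 6).
#' @return A `frase_complex`.
#' @export
make_planted_complex <- function(seed = 1, edges = c(10, 10, 10), n_pack = 6) {
  set.seed(seed)
  tri <- triangle_coords(edges)
  ctr <- colMeans(tri)
  lig <- fixture_ligand(center = ctr)
  names_ <- c("TRP", "GLY", "ARG")
  rows <- list()
  for (k in 1:3) {
    rows[[k]] <- fixture_residue(names_[k], tri[k, ], "A", k, toward = ctr)
  }
  rn <- 3L
  # amine donor facing the hydroxyl oxygen
  at <- lig$atoms
  o <- as.numeric(at[at$element == "O", c("x", "y", "z")][1, ])
  u <- o - ctr; u <- u / sqrt(sum(u^2))
  nz <- o + 3.0 * u
  rn <- rn + 1L
  df <- fixture_residue("LYS", nz + 5.6 * u, "A", rn, toward = ctr)
  df[df$elety == "NZ", c("x", "y", "z")] <- as.list(nz)
  rows[[length(rows) + 1]] <- df
  # aromatic probe stacked off the ring plane
  ring <- as.matrix(at[1:6, c("x", "y", "z")])
  nrm <- pracma_cross(ring[2, ] - ring[1, ], ring[3, ] - ring[1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  cg <- colMeans(ring) + 3.5 * nrm
  rn <- rn + 1L
  df <- fixture_residue("PHE", cg + 4.2 * nrm, "A", rn, toward = colMeans(ring))
  df[df$elety == "CG", c("x", "y", "z")] <- as.list(cg)
  rows[[length(rows) + 1]] <- df
  # packing residues below the ring plane, side chains toward the ligand
  for (p in seq_len(n_pack)) {
    ang <- 2 * pi * p / n_pack
    ca <- ctr + c(6.5 * cos(ang), 6.5 * sin(ang), ifelse(p %% 2 == 0, 4.5, -4.5))
    rn <- rn + 1L
    rows[[length(rows) + 1]] <- fixture_residue("LEU", ca, "A", rn, toward = ctr)
  }
  structure(list(protein = do.call(rbind, rows), ligand = lig,
                 provenance = sprintf("planted-complex-seed%d", seed)),
            class = "frase_complex")
}

# fragment template for the separable set: aromatic ring with two para
# hydroxyls and a methyl, randomly rotated about its centroid
separable_fragment <- function(center = c(0, 0, 0)) {
  fixture_ligand(center = center, rotation = random_rotation())
}

#' Generate a class-separable FRASE set
#'
#' True FRASEs plant complementary contacts: an amine donor (LYS NZ) at
#' 2.8-3.2 A from each fragment hydroxyl, an aromatic probe (PHE CG/CD1)
#' stacked ~3.5 A off the ring plane, plus uninformative ALA/LEU packing
#' atoms at 4-9 A. Decoys are produced from these by fragment shuffling
#' ([generate_decoys()]), so their contact geometry no longer matches the
#' planted chemistry: the two classes are separable by construction.
#'
#' @param n_true Number of true FRASEs.
#' @param multiplicity Decoys per true FRASE (default 2).
#' @param seed Integer seed.
#' @return List with elements `true` and `decoys` (lists of `frase`).
#' @export
make_separable_frase_set <- function(n_true, multiplicity = 2, seed = 1) {
  set.seed(seed)
  truths <- vector("list", n_true)
  for (i in seq_len(n_true)) {
    frag <- separable_fragment()
    at <- frag$atoms
    ctr <- colMeans(as.matrix(at[, c("x", "y", "z")]))
    rows <- list(); rn <- 0L
    # donors facing each hydroxyl oxygen
    for (oi in which(at$element == "O")) {
      o <- as.numeric(at[oi, c("x", "y", "z")])
      u <- o - ctr; u <- u / sqrt(sum(u^2))
      nz <- o + stats::runif(1, 2.8, 3.2) * u
      rn <- rn + 1L
      df <- fixture_residue("LYS", nz + 5.6 * u, "A", rn, toward = ctr)
      # pull NZ exactly onto the planted contact point
      df[df$elety == "NZ", c("x", "y", "z")] <- as.list(nz)
      rows[[length(rows) + 1]] <- df
    }
    # aromatic probe stacked off the ring plane
    ring <- as.matrix(at[1:6, c("x", "y", "z")])
    nrm <- pracma_cross(ring[2, ] - ring[1, ], ring[3, ] - ring[1, ])
    nrm <- nrm / sqrt(sum(nrm^2))
    cg <- colMeans(ring) + stats::runif(1, 3.4, 3.6) * nrm
    rn <- rn + 1L
    df <- fixture_residue("PHE", cg + 4.2 * nrm, "A", rn, toward = colMeans(ring))
    df[df$elety == "CG", c("x", "y", "z")] <- as.list(cg)
    rows[[length(rows) + 1]] <- df
    # packing noise
    for (k in seq_len(4)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rn <- rn + 1L
      rows[[length(rows) + 1]] <- fixture_residue(
        sample(c("ALA", "LEU", "VAL"), 1),
        ctr + stats::runif(1, 6, 9) * u, "A", rn, toward = ctr)
    }
    truths[[i]] <- new_frase(frag, do.call(rbind, rows), label = "true",
                             provenance = sprintf("separable-%d", i),
                             id = sprintf("T%05d", i))
  }
  decoys <- generate_decoys(truths, multiplicity = multiplicity, seed = seed + 1)
  list(true = truths, decoys = decoys)
}

# cross product (kept local; avoids pulling in a geometry dependency)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate Gaussian blobs of same-typed pharmacophore features
#'
#' Blob centers are rejection-sampled with pairwise separation at least
#' `min_sep`; features scatter around them with sd `sigma`. The planted
#' centers are attached as `attr(, "centers")`.
#'
#' @param k_blobs Number of blobs.
#' @param per_blob Features per blob.
#' @param sigma Scatter sd in Angstrom.
#' @param min_sep Minimum center separation in Angstrom.
#' @param seed Integer seed.
#' @param ftype Feature type for all blobs (default "HBA").
#' @return Feature data.frame as from [perceive_features()].
#' @export
make_feature_blobs <- function(k_blobs = 3, per_blob = 20, sigma = 0.5,
                               min_sep = 8, seed = 1, ftype = "HBA") {
  set.seed(seed)
  centers <- NULL
  while (is.null(centers) || nrow(centers) < k_blobs) {
    cand <- stats::runif(3, -15, 15)
    if (is.null(centers) ||
        min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_sep) {
      centers <- rbind(centers, cand)
    }
  }
  feats <- do.call(rbind, lapply(seq_len(k_blobs), function(b) {
    data.frame(ftype = ftype,
               x = stats::rnorm(per_blob, centers[b, 1], sigma),
               y = stats::rnorm(per_blob, centers[b, 2], sigma),
               z = stats::rnorm(per_blob, centers[b, 3], sigma),
               source = sprintf("blob%d", b), stringsAsFactors = FALSE)
  }))
  rownames(centers) <- NULL
  attr(feats, "centers") <- centers
  feats
}
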