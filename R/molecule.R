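#' Construct a small molecule
#'
#' Lightweight container for a ligand or fragment: an atom table
#' (element, 3D coordinates, alpha-marker flag) and a bond table
#' (1-based atom indices and bond order; order 4 denotes an aromatic bond).
#' Hydrogens may be present but are ignored by all distance-based
#' computations; implicit hydrogens are inferred from standard valences
#' when computing molecular weight.
#'
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `is_alpha` (attachment markers retained on cyclic
#'   fragments; they count as carbon for molecular weight but receive no
#'   atom types).
#' @param bonds data.frame with columns `a1`, `a2`, `order`; may have zero
#'   rows for a single-atom molecule.
#' @return An object of class `frase_mol`.
#' @export
frase_mol <- function(atoms, bonds = data.frame(a1 = integer(), a2 = integer(),
                                                order = numeric())) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$is_alpha)) atoms$is_alpha <- FALSE
  atoms$element <- toupper(atoms$element)
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) > 0) {
    stopifnot(all(c("a1", "a2") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1
    stopifnot(all(bonds$a1 >= 1), all(bonds$a2 <= nrow(atoms)))
  }
  structure(list(atoms = atoms, bonds = bonds), class = "frase_mol")
}

#' @export
print.frase_mol <- function(x, ...) {
  cat("frase_mol:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds,",
      sprintf("MW %.1f Da\n", mol_weight(x)))
  invisible(x)
}

# igraph view of the bond network
mol_graph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(), a2 = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(mol$atoms)))
  )
}

# heavy-atom indices (hydrogens excluded)
heavy_idx <- function(mol) which(mol$atoms$element != "H")

# implicit hydrogen count per atom: standard valence minus bonded order
# (aromatic order 4 counted as 1.5); alpha markers are treated as methyl-like
# carbons so they contribute CH3 mass at a single attachment bond.
implicit_h <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- numeric(n)
  if (nrow(mol$bonds)) {
    ord <- ifelse(mol$bonds$order == 4, 1.5, mol$bonds$order)
    for (k in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds$a1[k]] <- deg[mol$bonds$a1[k]] + ord[k]
      deg[mol$bonds$a2[k]] <- deg[mol$bonds$a2[k]] + ord[k]
    }
  }
  el <- ifelse(mol$atoms$is_alpha, "C", mol$atoms$element)
  val <- standard_valence[el]
  val[is.na(val)] <- 0
  pmax(0, round(val - deg))
}

#' Molecular weight (Da) including implicit hydrogens
#'
#' Alpha-attachment markers count as carbon with implicit hydrogens filled
#' to valence, so a retained methyl marker contributes ~15 Da.
#'
#' @param mol A [frase_mol()].
#' @return Molecular weight in Dalton.
#' @export
mol_weight <- function(mol) {
  el <- ifelse(mol$atoms$is_alpha, "C", mol$atoms$element)
  m <- atomic_masses[el]
  if (any(is.na(m))) stop("mol_weight: unknown element ", el[which(is.na(m))[1]])
  sum(m) + sum(implicit_h(mol)) * atomic_masses[["H"]]
}

# indices of bonds that are acyclic (graph bridges) and single-order
acyclic_single_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0) return(integer())
  g <- mol_graph(mol)
  br <- igraph::bridges(g)
  bridge_ids <- as.integer(br)   # edge ids in insertion order = bond rows
  intersect(bridge_ids, which(mol$bonds$order == 1))
}

# all simple rings up to max_size, as lists of atom indices.
# DFS over the bond graph from each edge; adequate for ligand-sized graphs.
mol_rings <- function(mol, max_size = 8) {
  nb <- vector("list", nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
      nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    }
  }
  found <- list(); seen <- character()
  walk <- function(path, target) {
    last <- path[length(path)]
    for (v in nb[[last]]) {
      if (v == target && length(path) >= 3) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) { seen <<- c(seen, key); found[[length(found) + 1]] <<- path }
      } else if (!v %in% path && length(path) < max_size && v > path[1]) {
        walk(c(path, v), target)
      }
    }
  }
  for (a in seq_along(nb)) if (length(nb[[a]]) >= 2) walk(a, a)
  # keep only chordless/smallest rings: drop rings that are unions of smaller ones
  if (length(found) > 1) {
    found <- found[order(vapply(found, length, 1L))]
    ring_bonds <- function(r) {
      n <- length(r)
      paste(pmin(r, c(r[-1], r[1])), pmax(r, c(r[-1], r[1])), sep = "_")
    }
    kept <- list(); covered <- character()
    for (r in found) {
      rb <- ring_bonds(r)
      if (!all(rb %in% covered)) { kept[[length(kept) + 1]] <- r; covered <- union(covered, rb) }
    }
    found <- kept
  }
  found
}

# per-atom ring membership flag
in_ring <- function(mol, rings = mol_rings(mol)) {
  flag <- rep(FALSE, nrow(mol$atoms))
  for (r in rings) flag[r] <- TRUE
  flag
}

# aromatic ring test: all bonds order 4, or a 5/6-ring of C/N/O/S whose
# in-ring double-bond count matches the usual alternation (3 for 6-rings,
# 2 for 5-rings). A pragmatic perception, documented in the vignette.
ring_is_aromatic <- function(mol, ring) {
  n <- length(ring)
  if (!n %in% c(5L, 6L)) return(FALSE)
  el <- mol$atoms$element[ring]
  if (!all(el %in% c("C", "N", "O", "S"))) return(FALSE)
  pairs <- cbind(ring, c(ring[-1], ring[1]))
  orders <- numeric(n)
  for (k in seq_len(n)) {
    hit <- which((mol$bonds$a1 == pairs[k, 1] & mol$bonds$a2 == pairs[k, 2]) |
                 (mol$bonds$a1 == pairs[k, 2] & mol$bonds$a2 == pairs[k, 1]))
    if (length(hit) == 0) return(FALSE)
    orders[k] <- mol$bonds$order[hit[1]]
  }
  if (all(orders == 4)) return(TRUE)
  ndbl <- sum(orders == 2)
  (n == 6 && ndbl == 3) || (n == 5 && ndbl == 2)
}

# aromatic rings and per-atom aromatic flag
aromatic_rings <- function(mol) {
  rings <- mol_rings(mol)
  rings[vapply(rings, function(r) ring_is_aromatic(mol, r), TRUE)]
}

aromatic_flags <- function(mol) {
  flag <- rep(FALSE, nrow(mol$atoms))
  for (r in aromatic_rings(mol)) flag[r] <- TRUE
  flag
}

# neighbours of atom i with the connecting bond order
atom_neighbours <- function(mol, i) {
  b <- mol$bonds
  if (nrow(b) == 0) return(data.frame(idx = integer(), order = numeric()))
  sel1 <- b$a1 == i; sel2 <- b$a2 == i
  data.frame(idx = c(b$a2[sel1], b$a1[sel2]), order = c(b$order[sel1], b$order[sel2]))
}

# apply a rigid transform (rotation matrix + translation) to a molecule
apply_transform_mol <- function(mol, rot, trans) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  new_xyz <- xyz %*% t(rot)
  new_xyz <- sweep(new_xyz, 2, trans, "+")
  mol$atoms$x <- new_xyz[, 1]; mol$atoms$y <- new_xyz[, 2]; mol$atoms$z <- new_xyz[, 3]
  mol
}
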