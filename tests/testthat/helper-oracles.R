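# Shared fixture builders and independent (brute-force) reference
# implementations used to cross-check the package's vectorized/hashed code
# paths. Oracles deliberately use naive loops and no shared helpers beyond
# the containers themselves.

# ---- small molecules -------------------------------------------------------

make_benzene <- function(center = c(0, 0, 0)) {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  frase_mol(
    data.frame(element = "C", x = 1.39 * cos(ang) + center[1],
               y = 1.39 * sin(ang) + center[2], z = center[3]),
    data.frame(a1 = 1:6, a2 = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
}

make_acetate <- function() {
  # CH3-COO(-): C1 methyl, C2 carboxylate carbon, O3 (double), O4 (single)
  frase_mol(
    data.frame(element = c("C", "C", "O", "O"),
               x = c(0, 1.5, 2.1, 2.1), y = c(0, 0, 1.1, -1.1), z = 0),
    data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4), order = c(1, 2, 1)))
}

make_toluene <- function() {
  b <- make_benzene()
  at <- rbind(b$atoms, data.frame(element = "C", x = 1.39 + 1.5, y = 0, z = 0,
                                  is_alpha = FALSE))
  bd <- rbind(b$bonds, data.frame(a1 = 1, a2 = 7, order = 1))
  frase_mol(at, bd)
}

# biphenyl-4-yl acetic acid: two fused-free rings joined by a single bond,
# with a CH2-COOH tail; 4 cuttable acyclic single bonds
make_biphenyl_acetic <- function() {
  b1 <- make_benzene(c(0, 0, 0))
  b2 <- make_benzene(c(4.2, 0, 0))
  at <- rbind(b1$atoms, b2$atoms,
              data.frame(element = c("C", "C", "O", "O"),
                         x = c(-2.3, -3.8, -4.4, -4.4),
                         y = c(0, 0, 1.1, -1.1), z = 0, is_alpha = FALSE))
  bd <- rbind(b1$bonds,
              data.frame(a1 = b2$bonds$a1 + 6, a2 = b2$bonds$a2 + 6,
                         order = b2$bonds$order),
              data.frame(a1 = c(1, 4, 13, 14, 14), a2 = c(7, 13, 14, 15, 16),
                         order = c(1, 1, 1, 2, 1)))
  frase_mol(at, bd)
}

# single heavy atom with no bonds (methane-like aliphatic stub)
make_stub <- function(element = "C", xyz = c(0, 0, 0)) {
  frase_mol(data.frame(element = element, x = xyz[1], y = xyz[2], z = xyz[3]))
}

# random acyclic molecule (tree) with optional benzene ring grafted on
random_mol <- function(n_atoms = 8, with_ring = FALSE, seed = 1) {
  set.seed(seed)
  els <- sample(c("C", "C", "C", "N", "O"), n_atoms, replace = TRUE)
  xyz <- matrix(stats::rnorm(3 * n_atoms, sd = 3), ncol = 3)
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = numeric())
  for (i in 2:n_atoms) {
    bonds <- rbind(bonds, data.frame(a1 = sample(i - 1, 1), a2 = i, order = 1))
  }
  mol <- frase_mol(data.frame(element = els, x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3]), bonds)
  if (with_ring) {
    b <- make_benzene(c(10, 0, 0))
    at <- rbind(mol$atoms, b$atoms)
    bd <- rbind(mol$bonds,
                data.frame(a1 = b$bonds$a1 + n_atoms, a2 = b$bonds$a2 + n_atoms,
                           order = b$bonds$order),
                data.frame(a1 = 1, a2 = n_atoms + 1, order = 1))
    mol <- frase_mol(at, bd)
  }
  mol
}

# ---- brute-force references ------------------------------------------------

# independent fragment enumeration: all subsets of cuttable bonds via
# adjacency-matrix BFS, no igraph, no shared component logic
oracle_fragments <- function(mol, min_mw, max_mw, max_cuts = Inf) {
  n <- nrow(mol$atoms)
  b <- mol$bonds
  # a bond is cuttable iff single and removing it disconnects its endpoints
  reachable <- function(adj, from) {
    seen <- rep(FALSE, n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nx <- which(adj[v, ] & !seen)
      seen[nx] <- TRUE; queue <- c(queue, nx)
    }
    seen
  }
  base_adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(b))) {
    base_adj[b$a1[k], b$a2[k]] <- TRUE; base_adj[b$a2[k], b$a1[k]] <- TRUE
  }
  cuttable <- integer()
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1) next
    adj <- base_adj
    adj[b$a1[k], b$a2[k]] <- FALSE; adj[b$a2[k], b$a1[k]] <- FALSE
    if (!reachable(adj, b$a1[k])[b$a2[k]]) cuttable <- c(cuttable, k)
  }
  ring_atom <- rep(FALSE, n)
  for (k in setdiff(seq_len(nrow(b)), cuttable)) {
    # non-bridge bonds lie on rings (orders other than bridges included)
    adj <- base_adj
    adj[b$a1[k], b$a2[k]] <- FALSE; adj[b$a2[k], b$a1[k]] <- FALSE
    if (reachable(adj, b$a1[k])[b$a2[k]]) ring_atom[c(b$a1[k], b$a2[k])] <- TRUE
  }
  subsets <- list(integer())
  for (k in seq_len(min(max_cuts, length(cuttable)))) {
    subsets <- c(subsets, utils::combn(cuttable, k, simplify = FALSE))
  }
  out <- list(); seen <- character()
  for (cut in subsets) {
    adj <- base_adj
    for (k in cut) {
      adj[b$a1[k], b$a2[k]] <- FALSE; adj[b$a2[k], b$a1[k]] <- FALSE
    }
    assigned <- rep(FALSE, n)
    for (v in seq_len(n)) {
      if (assigned[v]) next
      comp <- which(reachable(adj, v))
      assigned[comp] <- TRUE
      key <- paste(comp, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      frag <- extract_fragment_oracle(mol, comp, ring_atom, cut)
      if (frag$mw >= min_mw && frag$mw <= max_mw) {
        out[[length(out) + 1]] <- key
      }
    }
  }
  sort(unlist(out))
}

# oracle-side fragment assembly: reuses mol_weight (mass table) but builds
# the atom/bond selection independently
extract_fragment_oracle <- function(mol, idx, ring_atom, cut) {
  b <- mol$bonds
  atoms <- mol$atoms[idx, , drop = FALSE]
  inside <- b$a1 %in% idx & b$a2 %in% idx
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  bonds <- data.frame(a1 = remap[b$a1[inside]], a2 = remap[b$a2[inside]],
                      order = b$order[inside])
  if (any(ring_atom[idx])) {
    for (k in cut) {
      ends <- c(b$a1[k], b$a2[k])
      if (sum(ends %in% idx) == 1) {
        a_out <- ends[!ends %in% idx]
        marker <- mol$atoms[a_out, , drop = FALSE]
        marker$is_alpha <- TRUE
        atoms <- rbind(atoms, marker)
        bonds <- rbind(bonds, data.frame(a1 = remap[ends[ends %in% idx]],
                                         a2 = nrow(atoms), order = 1))
      }
    }
  }
  frag <- frase_mol(atoms, bonds)
  frag$mw <- mol_weight(frag)
  frag
}

# brute-force interaction fingerprint: explicit loops over atom pairs and
# their type memberships (no matrix algebra)
oracle_fingerprint <- function(frase, optimum = 3, cutoff = 10) {
  lv <- ligand_type_vocab(); pv <- protein_type_vocab()
  L <- assign_ligand_atom_types(frase$fragment)
  P <- assign_protein_atom_types(frase$environment)
  fa <- frase$fragment$atoms
  keepl <- which(fa$element != "H" & !fa$is_alpha)
  keepp <- which(frase$environment$element != "H")
  fp <- numeric(length(lv) * length(pv))
  for (i in keepl) {
    for (j in keepp) {
      d <- sqrt((fa$x[i] - frase$environment$x[j])^2 +
                (fa$y[i] - frase$environment$y[j])^2 +
                (fa$z[i] - frase$environment$z[j])^2)
      if (d > cutoff) next
      w <- exp(-(d - optimum)^2)
      for (m in which(L[i, ])) {
        for (nn in which(P[j, ])) {
          l <- (m - 1) * length(pv) + nn
          fp[l] <- fp[l] + w
        }
      }
    }
  }
  fp
}

# brute-force triplet enumeration over all residue triples
oracle_triplets <- function(residues, min_edge = 8, max_edge = 12) {
  res <- residues[residues$standard, , drop = FALSE]
  n <- nrow(res)
  keys <- character()
  if (n < 3) return(keys)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    p <- as.matrix(res[c(i, j, k), c("cx", "cy", "cz")])
    d <- c(sqrt(sum((p[1, ] - p[2, ])^2)), sqrt(sum((p[1, ] - p[3, ])^2)),
           sqrt(sum((p[2, ] - p[3, ])^2)))
    if (all(d >= min_edge & d <= max_edge)) {
      keys <- c(keys, paste(res$resno[c(i, j, k)], collapse = "-"))
    }
  }
  sort(keys)
}

# brute-force all-pairs triplet matching: fingerprint-set intersection plus
# per-permutation bit and edge checks, no hash index
oracle_matches <- function(target_triplets, db, edge_tol = 2.0) {
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  edge_of <- function(tt, a, b) {
    # edges stored (d12, d13, d23)
    key <- paste(sort(c(a, b)), collapse = "")
    tt$edges[c("12" = 1, "13" = 2, "23" = 3)[key]]
  }
  out <- character()
  for (ti in seq_along(target_triplets)) {
    tt <- target_triplets[[ti]]
    for (di in seq_along(db$index$triplets)) {
      dt <- db$index$triplets[[di]]
      for (r in seq_len(6)) {
        p <- perms[r, ]
        if (!all(dt$bits[p] == tt$bits)) next
        ok <- TRUE
        for (a in 1:2) for (b in (a + 1):3) {
          if (abs(edge_of(dt, p[a], p[b]) - edge_of(tt, a, b)) > edge_tol) {
            ok <- FALSE
          }
        }
        if (ok) out <- c(out, paste(ti, db$index$frase_of[di], r, sep = ":"))
      }
    }
  }
  sort(out)
}

# random typed frase fixture: a rotated template fragment plus residues of
# varied chemistry scattered at 2-9 A
random_typed_frase <- function(seed) {
  set.seed(seed)
  tmpl <- switch(seed %% 3 + 1, make_toluene(), make_acetate(),
                 fixture_ligand())
  R <- {
    q <- qr(matrix(stats::rnorm(9), 3)); Q <- qr.Q(q)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    Q
  }
  xyz <- as.matrix(tmpl$atoms[, c("x", "y", "z")]) %*% t(R)
  tmpl$atoms$x <- xyz[, 1]; tmpl$atoms$y <- xyz[, 2]; tmpl$atoms$z <- xyz[, 3]
  resnames <- sample(c("LYS", "ASP", "PHE", "SER", "LEU", "HIS", "ARG", "THR"),
                     sample(3:6, 1), replace = TRUE)
  ctr <- colMeans(xyz)
  rows <- lapply(seq_along(resnames), function(k) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    fixture_residue(resnames[k], ctr + stats::runif(1, 4, 10) * u, "A", k,
                    toward = ctr, approach = stats::runif(1, 2, 5))
  })
  new_frase(tmpl, do.call(rbind, rows), label = "true",
            provenance = sprintf("random-%d", seed))
}

# proper random rotation for alignment tests
random_rot3 <- function() {
  q <- qr(matrix(stats::rnorm(9), 3)); Q <- qr.Q(q)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
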