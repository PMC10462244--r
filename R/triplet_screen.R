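#' @title Residue-triplet screening
#' @description
#' The matching unit for database screening is a triplet of protein
#' residues whose CA atoms form an approximately equilateral triangle with
#' all three edges in the 8-12 A window. Each triplet is encoded as six
#' order-permuted 33-bit fingerprints (three concatenated 11-bit residue
#' strings), making the screen invariant to residue order; a matched
#' triplet defines a 3-point rigid (Kabsch) superposition that transplants
#' the database fragment into the target frame.
#' @name triplet_screen
NULL

# the 6 orderings of three residues
.perm3 <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

#' Enumerate qualifying residue triplets
#'
#' Every unordered triple of standard residues whose three pairwise CA
#' distances all lie in `[min_edge, max_edge]`.
#'
#' @param residues Residue table from [residue_table()] (or any data.frame
#'   with columns resid, chain, resno, standard, cx, cy, cz).
#' @param min_edge,max_edge Edge window in Angstrom (defaults 8 and 12).
#' @return List of `residue_triplet` objects, each carrying the member
#'   residues, CA coordinates, edge lengths, six 33-bit fingerprints and
#'   the canonical (lexicographically smallest) fingerprint.
#' @export
enumerate_triplets <- function(residues, min_edge = 8, max_edge = 12) {
  res <- residues[residues$standard, , drop = FALSE]
  n <- nrow(res)
  if (n < 3) return(list())
  xyz <- as.matrix(res[, c("cx", "cy", "cz")])
  D <- as.matrix(stats::dist(xyz))
  ok <- D >= min_edge & D <= max_edge
  out <- list()
  for (i in seq_len(n - 2)) {
    js <- which(ok[i, ] & seq_len(n) > i)
    for (j in js) {
      ks <- which(ok[i, ] & ok[j, ] & seq_len(n) > j)
      for (k in ks) {
        out[[length(out) + 1]] <- make_triplet(res[c(i, j, k), , drop = FALSE],
                                               c(D[i, j], D[i, k], D[j, k]))
      }
    }
  }
  out
}

# construct a residue_triplet from a 3-row residue table and its edges
# edges are stored as (d12, d13, d23)
make_triplet <- function(res3, edges = NULL) {
  ca <- as.matrix(res3[, c("cx", "cy", "cz")])
  if (is.null(edges)) {
    d <- as.matrix(stats::dist(ca))
    edges <- c(d[1, 2], d[1, 3], d[2, 3])
  }
  bits <- vapply(res3$resid, residue_bitstring, "")
  fps <- triplet_fingerprints_from_bits(bits)
  structure(list(residues = res3, ca = ca, edges = edges, bits = unname(bits),
                 fingerprints = fps, canonical = min(fps)),
            class = "residue_triplet")
}

triplet_fingerprints_from_bits <- function(bits) {
  apply(.perm3, 1, function(p) paste(bits[p], collapse = ""))
}

#' Six order-permuted fingerprints of a triplet
#'
#' Concatenates the three 11-bit residue strings under all 3! orderings.
#' Residues with identical bitstrings make some of the six coincide; all
#' six are still emitted.
#'
#' @param triplet A `residue_triplet`.
#' @return Character vector of six 33-character binary strings.
#' @export
triplet_fingerprints <- function(triplet) triplet$fingerprints

#' Build the triplet fingerprint index of a FRASE database
#'
#' Enumerates triplets in every FRASE environment and keys them by their
#' canonical fingerprint for O(1) lookup during screening.
#'
#' @param db A `frase_db`.
#' @param min_edge,max_edge Edge window in Angstrom.
#' @return List with `triplets` (flat list), `frase_of` (parallel integer
#'   vector of owning frase indices) and `keys` (environment mapping
#'   canonical fingerprint to entry ids).
#' @export
build_triplet_index <- function(db, min_edge = 8, max_edge = 12) {
  triplets <- list(); frase_of <- integer()
  keys <- new.env(parent = emptyenv())
  for (i in seq_along(db$frases)) {
    rt <- residue_table(db$frases[[i]]$environment)
    for (tt in enumerate_triplets(rt, min_edge, max_edge)) {
      triplets[[length(triplets) + 1]] <- tt
      frase_of <- c(frase_of, i)
      id <- length(triplets)
      keys[[tt$canonical]] <- c(keys[[tt$canonical]], id)
    }
  }
  list(triplets = triplets, frase_of = frase_of, keys = keys)
}

#' Match target triplets against a FRASE database
#'
#' A match is emitted when a target triplet's fingerprint equals any of a
#' database triplet's six fingerprints (exact binary equality). Each
#' bit-compatible residue permutation that also passes the edge gate
#' (corresponding edges within `edge_tol`) yields one match carrying the
#' implied residue correspondence.
#'
#' @param target_triplets List of `residue_triplet` from the target.
#' @param db A `frase_db` with a built index.
#' @param edge_tol Per-edge compatibility tolerance in Angstrom
#'   (default 2); set to `Inf` to disable the gate.
#' @return List of matches: `target`, `db_triplet`, `frase_id` (index into
#'   `db$frases`), `perm` (db residue ordering matched onto the target
#'   order).
#' @export
match_triplets <- function(target_triplets, db, edge_tol = 2.0) {
  idx <- db$index
  out <- list()
  # edge between triplet positions a<b, in (d12,d13,d23) storage order
  epos <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  for (tt in target_triplets) {
    ids <- idx$keys[[tt$canonical]]
    if (is.null(ids)) next
    for (id in ids) {
      dt <- idx$triplets[[id]]
      for (r in seq_len(nrow(.perm3))) {
        p <- .perm3[r, ]
        if (!all(dt$bits[p] == tt$bits)) next
        okedge <- TRUE
        for (a in 1:2) for (b in (a + 1):3) {
          de <- dt$edges[epos[min(p[a], p[b]), max(p[a], p[b])]]
          te <- tt$edges[epos[a, b]]
          if (abs(de - te) > edge_tol) { okedge <- FALSE; break }
        }
        if (!okedge) next
        out[[length(out) + 1]] <- list(target = tt, db_triplet = dt,
                                       frase_id = idx$frase_of[id], perm = p)
      }
    }
  }
  out
}

#' Proper rigid superposition of two 3-point sets (Kabsch)
#'
#' Least-squares rotation + translation (no scaling, no reflection)
#' mapping `src` onto `dst`.
#'
#' @param src,dst Numeric 3x3 matrices, one point per row.
#' @return List with `rot` (3x3 proper rotation, det = +1), `trans`
#'   (length-3 translation) and `rmsd` over the three points.
#' @export
kabsch_3pt <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (any(!is.finite(R))) stop("kabsch_3pt: numerical failure in superposition")
  trans <- cd - as.vector(cs %*% t(R))
  fitted <- sweep(src %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - dst)^2)))
  list(rot = R, trans = trans, rmsd = rmsd)
}

#' Align a FRASE into the target frame via a triplet match
#'
#' Superposes the database triplet's CA atoms (in matched permutation
#' order) onto the target triplet's CA atoms and applies the resulting
#' rigid transform to all FRASE atoms (fragment and environment).
#'
#' @param frase The database `frase`.
#' @param match One element of the [match_triplets()] result.
#' @return The transformed `frase` with an `alignment_rmsd` field.
#' @export
align_frase <- function(frase, match) {
  src <- match$db_triplet$ca[match$perm, , drop = FALSE]
  dst <- match$target$ca
  fit <- kabsch_3pt(src, dst)
  out <- frase
  out$fragment <- apply_transform_mol(frase$fragment, fit$rot, fit$trans)
  exyz <- as.matrix(frase$environment[, c("x", "y", "z")])
  exyz <- sweep(exyz %*% t(fit$rot), 2, fit$trans, "+")
  out$environment$x <- exyz[, 1]; out$environment$y <- exyz[, 2]
  out$environment$z <- exyz[, 3]
  out$alignment_rmsd <- fit$rmsd
  out
}

#' Build a target-based FRASE around a seeded fragment
#'
#' Cuts out the target residues within `radius` of the fragment and merges
#' them with the fragment; the label is left unset for scoring.
#'
#' @param target_protein Target protein atom data.frame.
#' @param fragment Seeded fragment (in the target frame).
#' @param radius Environment radius in Angstrom (default 4.5).
#' @param provenance Identifier recorded on the FRASE.
#' @return A `frase` with `label = NA`, or `NULL` when the environment is
#'   empty (such fragments are excluded from scoring).
#' @export
make_target_frase <- function(target_protein, fragment, radius = 4.5,
                              provenance = "target") {
  env <- extract_environment(target_protein, fragment, radius)
  if (nrow(env) == 0) return(NULL)
  new_frase(fragment, env, label = NA, provenance = provenance)
}

#' Screen a target protein against a FRASE database
#'
#' Composition of triplet enumeration, fingerprint matching, 3-point
#' alignment and target-FRASE construction: one seeded fragment per
#' (FRASE, match) pair, deduplicated by fragment-centroid distance within
#' `dedup_tol` for the same source FRASE.
#'
#' @param target_protein Target protein atom data.frame (apo structure).
#' @param db A `frase_db`.
#' @param min_edge,max_edge Triplet edge window in Angstrom.
#' @param edge_tol Edge compatibility gate in Angstrom.
#' @param dedup_tol Centroid distance below which two poses of the same
#'   FRASE are merged (default 0.5 A).
#' @return List of `seeded_fragment` objects: `fragment` (transformed
#'   [frase_mol()]), `frase_id`, `alignment_rmsd`, `score` (NA until
#'   scored).
#' @export
screen <- function(target_protein, db, min_edge = 8, max_edge = 12,
                   edge_tol = 2.0, dedup_tol = 0.5) {
  rt <- residue_table(target_protein)
  tts <- enumerate_triplets(rt, min_edge, max_edge)
  matches <- match_triplets(tts, db, edge_tol)
  seeded <- list()
  cent <- function(mol) colMeans(as.matrix(mol$atoms[, c("x", "y", "z")]))
  for (m in matches) {
    fr <- db$frases[[m$frase_id]]
    al <- align_frase(fr, m)
    cm <- cent(al$fragment)
    dup <- FALSE
    for (s in seeded) {
      if (s$frase_id == m$frase_id &&
          sqrt(sum((s$centroid - cm)^2)) < dedup_tol) { dup <- TRUE; break }
    }
    if (dup) next
    seeded[[length(seeded) + 1]] <- structure(
      list(fragment = al$fragment, frase_id = m$frase_id,
           source_id = fr$id, alignment_rmsd = al$alignment_rmsd,
           centroid = cm, score = NA_real_),
      class = "seeded_fragment")
  }
  seeded
}
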