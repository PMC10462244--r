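#' @title FRASE database construction and persistence
#' @description
#' A FRASE (FRAgment in Structural Environment) pairs a ligand fragment
#' with every protein residue having at least one heavy atom within 4.5 A
#' of the fragment. This file implements ligand fragmentation (acyclic
#' single-bond enumeration with a 50-300 Da window and alpha-atom
#' retention on cyclic fragments), environment extraction, database
#' assembly with a triplet fingerprint index, and SDF round-trip storage.
#' @name frase_db
NULL

#' Enumerate fragments of a ligand
#'
#' Fragments are all connected substructures obtainable by deleting any
#' subset (up to `max_cuts` bonds) of acyclic single bonds, deduplicated
#' by atom set. Ring bonds are never broken, so any ring intersecting a
#' fragment is wholly contained in it. When a cut detaches a substituent
#' from a cyclic fragment, the substituent's first atom is retained as a
#' carbon-like alpha marker: it contributes to molecular weight but never
#' to atom typing. Only fragments with molecular weight inside
#' `[min_mw, max_mw]` are returned.
#'
#' @param ligand A [frase_mol()] with perceived bond orders.
#' @param min_mw,max_mw Molecular-weight window in Da (defaults 50, 300).
#' @param max_cuts Maximum number of simultaneous bond cuts (default 3).
#' @return List of fragments; each is a [frase_mol()] with extra fields
#'   `mw`, `parent_atoms` (indices into the parent ligand) and
#'   `attachment_points`.
#' @export
fragment_ligand <- function(ligand, min_mw = 50, max_mw = 300, max_cuts = 3) {
  cuttable <- acyclic_single_bonds(ligand)
  nb <- nrow(ligand$bonds)
  rings <- mol_rings(ligand)
  ring_atoms <- in_ring(ligand, rings)

  subsets <- list(integer())
  for (k in seq_len(min(max_cuts, length(cuttable)))) {
    cmb <- utils::combn(cuttable, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }

  seen <- character()
  out <- list()
  for (cut in subsets) {
    keep_bonds <- setdiff(seq_len(nb), cut)
    g <- igraph::graph_from_data_frame(
      d = ligand$bonds[keep_bonds, c("a1", "a2"), drop = FALSE],
      directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(ligand$atoms))))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      idx <- sort(which(comp == cid))
      key <- paste(idx, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      frag <- extract_fragment(ligand, idx, ring_atoms)
      if (frag$mw >= min_mw && frag$mw <= max_mw) out[[length(out) + 1]] <- frag
    }
  }
  out
}

# build a fragment frase_mol from parent atom indices, adding alpha markers
# for bonds cut at a cyclic fragment
extract_fragment <- function(ligand, idx, ring_atoms = in_ring(ligand)) {
  atoms <- ligand$atoms[idx, , drop = FALSE]
  b <- ligand$bonds
  inside <- b$a1 %in% idx & b$a2 %in% idx
  cut <- (b$a1 %in% idx) != (b$a2 %in% idx)
  remap <- match(seq_len(nrow(ligand$atoms)), idx)
  bonds <- data.frame(a1 = remap[b$a1[inside]], a2 = remap[b$a2[inside]],
                      order = b$order[inside])
  attach_local <- integer()
  is_cyclic <- any(ring_atoms[idx])
  if (any(cut)) {
    for (k in which(cut)) {
      a_in <- if (b$a1[k] %in% idx) b$a1[k] else b$a2[k]
      a_out <- if (b$a1[k] %in% idx) b$a2[k] else b$a1[k]
      attach_local <- c(attach_local, remap[a_in])
      if (is_cyclic) {
        marker <- ligand$atoms[a_out, , drop = FALSE]
        marker$is_alpha <- TRUE
        atoms <- rbind(atoms, marker)
        bonds <- rbind(bonds, data.frame(a1 = remap[a_in], a2 = nrow(atoms),
                                         order = 1))
      }
    }
  }
  rownames(atoms) <- NULL
  frag <- frase_mol(atoms, bonds)
  frag$mw <- mol_weight(frag)
  frag$parent_atoms <- idx
  frag$attachment_points <- unique(attach_local)
  frag
}

#' Extract the structural environment of a fragment
#'
#' Returns the atoms of exactly those protein residues having at least one
#' heavy atom within `radius` of at least one fragment heavy atom (whole
#' residues are included). Alpha markers and hydrogens are ignored on the
#' fragment side.
#'
#' @param protein Protein atom data.frame.
#' @param fragment A [frase_mol()] positioned in the same frame.
#' @param radius Environment radius in Angstrom (default 4.5).
#' @return Protein atom data.frame restricted to the environment residues.
#' @export
extract_environment <- function(protein, fragment, radius = 4.5) {
  fa <- fragment$atoms
  fa <- fa[fa$element != "H" & !fa$is_alpha, , drop = FALSE]
  if (nrow(fa) == 0 || nrow(protein) == 0) return(protein[0, , drop = FALSE])
  pxyz <- as.matrix(protein[, c("x", "y", "z")])
  fxyz <- as.matrix(fa[, c("x", "y", "z")])
  d2 <- outer(rowSums(pxyz^2), rowSums(fxyz^2), "+") - 2 * pxyz %*% t(fxyz)
  near <- apply(d2, 1, min) <= radius^2 + 1e-12
  keys <- residue_key(protein)
  keep <- keys %in% unique(keys[near])
  protein[keep, , drop = FALSE]
}

#' Construct a FRASE
#'
#' @param fragment A fragment [frase_mol()].
#' @param environment Protein atom data.frame (the residue shell).
#' @param label `"true"`, `"decoy"`, or `NA` for unscored target FRASEs.
#' @param provenance Source identifier.
#' @param id Optional stable identifier.
#' @return Object of class `frase`.
#' @export
new_frase <- function(fragment, environment, label = "true",
                      provenance = "synthetic", id = NULL) {
  structure(list(fragment = fragment, environment = environment,
                 label = label, provenance = provenance, id = id),
            class = "frase")
}

#' @export
print.frase <- function(x, ...) {
  nres <- length(unique(residue_key(x$environment)))
  cat("frase", if (!is.null(x$id)) paste0("[", x$id, "]") else "",
      ": fragment", nrow(x$fragment$atoms), "atoms,", nres,
      "environment residues, label =", x$label, "\n")
  invisible(x)
}

#' Build a FRASE database from complexes
#'
#' For every complex, enumerates fragments of its ligand, extracts each
#' fragment's residue environment, and stores one FRASE per fragment with
#' a non-empty environment. Environments are indexed by their residue
#' triplet fingerprints for fast screening. Per-complex failures are
#' logged as warnings and skipped.
#'
#' @param complexes List of `frase_complex` objects.
#' @param radius Environment radius in Angstrom (default 4.5).
#' @param min_mw,max_mw Fragment molecular-weight window in Da.
#' @param max_cuts Fragmentation cut cap.
#' @param min_edge,max_edge Triplet edge window in Angstrom (defaults 8, 12).
#' @return Object of class `frase_db` with elements `frases` (list) and
#'   `index` (triplet fingerprint index, see [build_triplet_index()]).
#' @export
build_frase_db <- function(complexes, radius = 4.5, min_mw = 50, max_mw = 300,
                           max_cuts = 3, min_edge = 8, max_edge = 12) {
  frases <- list()
  for (cx in complexes) {
    res <- tryCatch({
      if (is.null(cx$ligand)) stop("complex has no ligand")
      frags <- fragment_ligand(cx$ligand, min_mw, max_mw, max_cuts)
      for (fr in frags) {
        env <- extract_environment(cx$protein, fr, radius)
        if (nrow(env) > 0) {
          frases[[length(frases) + 1]] <- new_frase(
            fr, env, label = "true", provenance = cx$provenance,
            id = sprintf("F%05d", length(frases) + 1L))
        }
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) warning("build_frase_db: skipping ", cx$provenance, ": ", res)
  }
  db <- structure(list(frases = frases, index = NULL), class = "frase_db")
  db$index <- build_triplet_index(db, min_edge, max_edge)
  db
}

#' @export
print.frase_db <- function(x, ...) {
  cat("frase_db:", length(x$frases), "frases,",
      length(x$index$keys), "indexed triplet fingerprints\n")
  invisible(x)
}

# serialize one environment atom table into an SDF datablock string
env_to_tag <- function(env) {
  paste(apply(env, 1, function(r) {
    paste(trimws(r[["elety"]]), trimws(r[["element"]]), trimws(r[["resid"]]),
          trimws(r[["chain"]]), trimws(r[["resno"]]),
          format(as.numeric(r[["x"]]), nsmall = 4),
          format(as.numeric(r[["y"]]), nsmall = 4),
          format(as.numeric(r[["z"]]), nsmall = 4))
  }), collapse = "|")
}

tag_to_env <- function(tag) {
  rows <- strsplit(strsplit(tag, "|", fixed = TRUE)[[1]], " +")
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("elety", "element", "resid", "chain", "resno", "x", "y", "z")
  df$resno <- as.integer(df$resno)
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y); df$z <- as.numeric(df$z)
  df$standard <- df$resid %in% standard_residues()
  df
}

mol_to_sdf <- function(mol, name, datablock) {
  n <- nrow(mol$atoms)
  ab <- cbind(as.matrix(mol$atoms[, c("x", "y", "z")]), matrix(0, n, 13))
  colnames(ab) <- paste0("C", seq_len(16))
  el <- ifelse(mol$atoms$is_alpha, "R", mol$atoms$element)
  el <- paste0(substr(el, 1, 1), tolower(substr(el, 2, 2)))
  rownames(ab) <- paste(el, seq_len(n), sep = "_")
  bb <- as.matrix(mol$bonds[, c("a1", "a2", "order")])
  if (nrow(bb) == 0) bb <- matrix(numeric(), 0, 3)
  colnames(bb) <- c("C1", "C2", "C3")
  if (nrow(bb)) rownames(bb) <- seq_len(nrow(bb))
  header <- c(Molecule_Name = name, Source = "frasebot", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0            999 V2000",
                                    n, nrow(bb)))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = datablock)
}

sdf_to_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  el <- toupper(gsub("_.*", "", rownames(ab)))
  is_alpha <- el == "R"
  el[is_alpha] <- "C"
  atoms <- data.frame(element = el, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                      is_alpha = is_alpha, stringsAsFactors = FALSE)
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (nrow(bb)) data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
           else data.frame(a1 = integer(), a2 = integer(), order = numeric())
  frag <- frase_mol(atoms, bonds)
  frag$mw <- mol_weight(frag)
  frag
}

#' Write a FRASE database to an SD file
#'
#' One V2000 record per FRASE: the fragment as the molecule block (alpha
#' markers stored as `R` pseudo-atoms) and the environment serialized in
#' tagged property fields (`FRASE_ENV`: atom name, element, residue,
#' chain, number and coordinates; plus `FRASE_ID`, `FRASE_LABEL`,
#' `FRASE_PROVENANCE`). The triplet index is rebuilt on load.
#'
#' @param db A `frase_db`.
#' @param path Output SDF path.
#' @export
write_db <- function(db, path) {
  sdfs <- lapply(seq_along(db$frases), function(i) {
    fr <- db$frases[[i]]
    mol_to_sdf(fr$fragment, fr$id %||% sprintf("F%05d", i),
               c(FRASE_ID = fr$id %||% sprintf("F%05d", i),
                 FRASE_LABEL = as.character(fr$label),
                 FRASE_PROVENANCE = as.character(fr$provenance),
                 FRASE_ENV = env_to_tag(fr$environment)))
  })
  ids <- vapply(sdfs, function(s) ChemmineR::header(s)[["Molecule_Name"]], "")
  set <- methods::new("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

#' Read a FRASE database from an SD file
#'
#' @param path SDF path written by [write_db()].
#' @param min_edge,max_edge Triplet edge window used to rebuild the index.
#' @return A `frase_db`.
#' @export
read_db <- function(path, min_edge = 8, max_edge = 12) {
  if (!file.exists(path)) stop("read_db: file not found: ", path)
  set <- ChemmineR::read.SDFset(path)
  frases <- list()
  for (i in seq_along(set@SDF)) {
    sdf <- set@SDF[[i]]
    d <- ChemmineR::datablock(sdf)
    if (!all(c("FRASE_ID", "FRASE_LABEL", "FRASE_ENV") %in% names(d))) {
      warning("read_db: record ", i, " missing FRASE tags; skipped")
      next
    }
    frases[[length(frases) + 1]] <- new_frase(
      sdf_to_mol(sdf), tag_to_env(d[["FRASE_ENV"]]),
      label = d[["FRASE_LABEL"]],
      provenance = d[["FRASE_PROVENANCE"]] %||% "unknown",
      id = d[["FRASE_ID"]])
  }
  db <- structure(list(frases = frases, index = NULL), class = "frase_db")
  db$index <- build_triplet_index(db, min_edge, max_edge)
  db
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}
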