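#' @title Structure input/output and atom typing
#' @description
#' Readers/writers for protein-ligand complexes and the atom-typing rules
#' that feed every downstream module. Proteins are represented as flat atom
#' tables (one row per heavy atom, bio3d-style columns), ligands as
#' [frase_mol()] objects.
#' @name complex_io
NULL

# default exclusion list for solvent / buffer heteros
default_exclusions <- function() {
  c("HOH", "WAT", "DOD", "SO4", "PO4", "GOL", "EDO", "PEG", "ACT", "DMS",
    "CL", "NA", "K", "MG", "ZN", "CA", "MN", "BR", "IOD", "NO3", "TRS")
}

#' Read a protein-ligand complex from a PDB file
#'
#' Separates protein residues (ATOM records plus flagged non-standard
#' residues) from the ligand (HETATM records matching `ligand_selector`).
#' Waters and common buffer molecules are dropped via `exclude`. Only the
#' first model and first altloc are used; hydrogens are discarded. Ligand
#' connectivity is taken from `ligand_sdf` when given, otherwise inferred
#' from interatomic distances (single bonds).
#'
#' @param path PDB file path.
#' @param ligand_selector HETATM residue name identifying the ligand, or
#'   `NULL` for an apo protein.
#' @param ligand_sdf Optional SDF/MOL file with the ligand (correct bond
#'   orders); coordinates from the SDF are used as-is.
#' @param exclude Residue names to drop entirely.
#' @return A `frase_complex`: list with `protein` (atom data.frame with
#'   columns elety, element, resid, chain, resno, x, y, z, standard),
#'   `ligand` (a [frase_mol()] or NULL) and `provenance`.
#' @export
read_complex <- function(path, ligand_selector = NULL, ligand_sdf = NULL,
                         exclude = default_exclusions()) {
  if (!file.exists(path)) stop("read_complex: file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) stop("read_complex: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  # first altloc only
  if (!is.null(at$alt)) {
    keep_alt <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep_alt, , drop = FALSE]
  }
  el <- at$elesy
  if (is.null(el) || all(is.na(el))) el <- gsub("[0-9'\\*]", "", substr(at$elety, 1, 1))
  el <- toupper(trimws(el))
  at$element <- el
  at <- at[at$element != "H" & !at$resid %in% exclude, , drop = FALSE]

  is_lig <- if (is.null(ligand_selector)) rep(FALSE, nrow(at)) else
    at$resid %in% ligand_selector
  if (!is.null(ligand_selector) && !any(is_lig) && is.null(ligand_sdf)) {
    stop("read_complex: ligand selector '", ligand_selector, "' matched nothing")
  }
  prot <- at[!is_lig & at$type == "ATOM" |
             (!is_lig & at$type == "HETATM" & at$resid %in% c("MSE", "SEC", "PYL")),
             , drop = FALSE]
  protein <- data.frame(
    elety = trimws(prot$elety), element = prot$element, resid = prot$resid,
    chain = prot$chain, resno = prot$resno,
    x = prot$x, y = prot$y, z = prot$z,
    standard = prot$resid %in% standard_residues(),
    stringsAsFactors = FALSE
  )

  ligand <- NULL
  if (!is.null(ligand_sdf)) {
    ligand <- read_fragment_sdf(ligand_sdf)[[1]]$fragment
  } else if (any(is_lig)) {
    lg <- at[is_lig, , drop = FALSE]
    atoms <- data.frame(element = lg$element, x = lg$x, y = lg$y, z = lg$z,
                        stringsAsFactors = FALSE)
    ligand <- frase_mol(atoms, infer_bonds(atoms))
  }
  structure(list(protein = protein, ligand = ligand,
                 provenance = basename(path)),
            class = "frase_complex")
}

#' @export
print.frase_complex <- function(x, ...) {
  nres <- nrow(unique(x$protein[, c("resid", "chain", "resno")]))
  cat("frase_complex:", nres, "residues,",
      if (is.null(x$ligand)) "no ligand" else
        paste0(nrow(x$ligand$atoms), "-atom ligand"),
      "(", x$provenance, ")\n")
  invisible(x)
}

# distance-based single-bond inference for ligands read from PDB
infer_bonds <- function(atoms, tol = 0.45) {
  covr <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10, F = 0.64,
            CL = 0.99, BR = 1.14, I = 1.33, H = 0.32)
  n <- nrow(atoms)
  out <- list()
  if (n >= 2) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ri <- covr[atoms$element[i]]; rj <- covr[atoms$element[j]]
      if (is.na(ri)) ri <- 0.77
      if (is.na(rj)) rj <- 0.77
      if (d[i, j] <= ri + rj + tol) out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(data.frame(a1 = integer(), a2 = integer(), order = numeric()))
  m <- do.call(rbind, out)
  data.frame(a1 = m[, 1], a2 = m[, 2], order = 1)
}

#' Write a complex to a PDB file
#'
#' Protein atoms as ATOM records, ligand atoms as HETATM records with
#' residue name `LIG`. Coordinates keep PDB precision (3 decimals).
#'
#' @param cx A `frase_complex`.
#' @param path Output file.
#' @export
write_complex <- function(cx, path) {
  p <- cx$protein
  lines <- character()
  fmt <- function(serial, type, elety, resid, chain, resno, x, y, z, element) {
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            type, serial, substr(elety, 1, 4), resid, chain, resno, x, y, z, element)
  }
  s <- 0L
  for (i in seq_len(nrow(p))) {
    s <- s + 1L
    lines <- c(lines, fmt(s, "ATOM", p$elety[i], p$resid[i], p$chain[i],
                          p$resno[i], p$x[i], p$y[i], p$z[i], p$element[i]))
  }
  if (!is.null(cx$ligand)) {
    la <- cx$ligand$atoms
    for (i in seq_len(nrow(la))) {
      s <- s + 1L
      lines <- c(lines, fmt(s, "HETATM", paste0(la$element[i], i), "LIG", "X",
                            1L, la$x[i], la$y[i], la$z[i], la$element[i]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Residue-level summary of a protein atom table
#'
#' One row per residue carrying a CA atom, with the CA coordinate used for
#' triplet enumeration and a `standard` flag (non-standard residues are
#' excluded from triplet enumeration).
#'
#' @param protein Protein atom data.frame (see [read_complex()]).
#' @return data.frame with columns resid, chain, resno, standard, cx, cy, cz.
#' @export
residue_table <- function(protein) {
  ca <- protein[protein$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca[, c("resid", "chain", "resno")]), , drop = FALSE]
  data.frame(resid = ca$resid, chain = ca$chain, resno = ca$resno,
             standard = if (!is.null(ca$standard)) ca$standard else
               ca$resid %in% standard_residues(),
             cx = ca$x, cy = ca$y, cz = ca$z,
             stringsAsFactors = FALSE)
}

# residue key helper used to slice whole residues out of atom tables
residue_key <- function(df) paste(df$resid, df$chain, df$resno, sep = "|")

#' Assign ligand atom types (29-label vocabulary)
#'
#' Documented graph rules over elements, bond orders and perceived rings.
#' Multi-typing is expected: a benzene carbon is both "Aromatic" and
#' "Aromatic Carbon". Hydrogens and alpha-attachment markers carry no
#' types.
#'
#' @param mol A [frase_mol()] with connectivity.
#' @return Logical matrix, one row per atom, 29 columns named by
#'   [ligand_type_vocab()].
#' @export
assign_ligand_atom_types <- function(mol) {
  if (!inherits(mol, "frase_mol")) stop("assign_ligand_atom_types: need a frase_mol")
  vocab <- ligand_type_vocab()
  n <- nrow(mol$atoms)
  M <- matrix(FALSE, n, length(vocab), dimnames = list(NULL, vocab))
  if (n == 0) return(M)
  el <- mol$atoms$element
  ar <- aromatic_flags(mol)
  hc <- implicit_h(mol)
  nbrs <- lapply(seq_len(n), function(i) atom_neighbours(mol, i))
  deg <- vapply(nbrs, nrow, 1L)

  dbl_to <- function(i, elem) {
    nb <- nbrs[[i]]
    any(nb$order == 2 & el[nb$idx] == elem)
  }
  n_nb_elem <- function(i, elem) sum(el[nbrs[[i]]$idx] == elem)

  carboxylate_c <- vapply(seq_len(n), function(i) {
    el[i] == "C" && !ar[i] && n_nb_elem(i, "O") >= 2 && dbl_to(i, "O")
  }, TRUE)
  nitro_n <- vapply(seq_len(n), function(i) {
    el[i] == "N" && n_nb_elem(i, "O") >= 2 &&
      all(deg[nbrs[[i]]$idx[el[nbrs[[i]]$idx] == "O"]] == 1)
  }, TRUE)
  carbonyl_c <- vapply(seq_len(n), function(i) el[i] == "C" && !ar[i] && dbl_to(i, "O"), TRUE)
  vinyl_c <- vapply(seq_len(n), function(i) el[i] == "C" && !ar[i] && dbl_to(i, "C"), TRUE)
  # guanidine / amidine carbon: C=N with >=2 N neighbours
  amidine_c <- vapply(seq_len(n), function(i) {
    el[i] == "C" && !ar[i] && dbl_to(i, "N") && n_nb_elem(i, "N") >= 2
  }, TRUE)

  for (i in seq_len(n)) {
    if (el[i] == "H" || mol$atoms$is_alpha[i]) next
    nb <- nbrs[[i]]
    set <- character()
    if (ar[i]) {
      set <- c(set, "Aromatic",
               switch(el[i], C = "Aromatic Carbon", N = "Aromatic Nitrogen",
                      O = "Aromatic Oxygen", S = "Aromatic Sulfur", NULL))
    }
    if (el[i] %in% c("N", "O", "S", "P")) set <- c(set, "Hetero")
    if (el[i] %in% c("F", "CL", "BR", "I")) {
      set <- c(set, "Halogen",
               switch(el[i], F = "F", CL = "Cl", BR = "Br", I = "I"))
    }
    if (el[i] == "C" && !ar[i]) set <- c(set, "Aliphatic Carbon")
    if (vinyl_c[i]) set <- c(set, "Vinyl")

    if (el[i] == "O") {
      is_nitro_o <- deg[i] == 1 && any(nitro_n[nb$idx])
      is_carbox_o <- any(carboxylate_c[nb$idx])
      is_phosph_o <- n_nb_elem(i, "P") >= 1
      has_h <- hc[i] >= 1
      c_nb <- nb$idx[el[nb$idx] == "C"]
      if (is_nitro_o) set <- c(set, "Nitro Oxygen")
      if (is_carbox_o) set <- c(set, "Carboxylate Oxygen", "Negative Ionizable")
      if (is_phosph_o) {
        set <- c(set, "Phosphate Oxygen")
        if (deg[i] == 1) set <- c(set, "Negative Ionizable")
      }
      if (!is_nitro_o) set <- c(set, "H-bond Acceptor")
      if (has_h) {
        set <- c(set, "H-bond Donor")
        if (length(c_nb) == 1 && !is_carbox_o && !is_phosph_o) {
          if (vinyl_c[c_nb]) set <- c(set, "Enol Oxygen")
          else if (!carbonyl_c[c_nb]) set <- c(set, "Alcohol Oxygen")
        }
      }
    }

    if (el[i] == "N" && !ar[i]) {
      is_amide <- any(carbonyl_c[nb$idx]) && !nitro_n[i]
      is_imine <- dbl_to(i, "C")
      is_enamine <- !is_amide && !is_imine &&
        any(vinyl_c[nb$idx] & !carbonyl_c[nb$idx])
      is_amine <- !is_amide && !is_imine && !nitro_n[i] && all(nb$order == 1)
      if (nitro_n[i]) set <- c(set, "Nitro Nitrogen")
      if (is_amide) set <- c(set, "Amide Nitrogen")
      if (is_imine) set <- c(set, "Imine Nitrogen")
      if (is_enamine) set <- c(set, "Enamine Nitrogen")
      if (is_amine) set <- c(set, "Amine Nitrogen", "Positive Ionizable")
      if (any(amidine_c[nb$idx])) set <- c(set, "Positive Ionizable")
      if (hc[i] >= 1 && !nitro_n[i]) set <- c(set, "H-bond Donor")
      if ((is_imine || is_amine) && !nitro_n[i]) set <- c(set, "H-bond Acceptor")
    }
    if (el[i] == "N" && ar[i]) {
      if (hc[i] >= 1) set <- c(set, "H-bond Donor") else set <- c(set, "H-bond Acceptor")
    }

    if (el[i] == "S") {
      o_dbl <- sum(nb$order == 2 & el[nb$idx] == "O")
      if (o_dbl >= 2) set <- c(set, "Sulfone Sulfur")
      if (o_dbl == 1) set <- c(set, "Sulfoxide Sulfur")
    }
    M[i, unique(set)] <- TRUE
  }
  M
}

#' Assign protein atom types (13-label vocabulary)
#'
#' Template lookup by residue name and PDB atom name against the shipped
#' rules table (`inst/extdata/protein_atom_types.tsv`): residue-specific
#' rows override the backbone wildcard rows. Atoms without a template row
#' (e.g. CYS SG, for which the vocabulary has no sulfur label) carry no
#' types and contribute nothing to the fingerprint.
#'
#' @param protein Protein atom data.frame.
#' @param table Optional alternative template table.
#' @return Logical matrix, one row per atom, 13 columns named by
#'   [protein_type_vocab()].
#' @export
assign_protein_atom_types <- function(protein, table = protein_type_table()) {
  vocab <- protein_type_vocab()
  n <- nrow(protein)
  M <- matrix(FALSE, n, length(vocab), dimnames = list(NULL, vocab))
  if (n == 0) return(M)
  key_specific <- paste(table$res, table$atom)
  for (i in seq_len(n)) {
    k <- paste(protein$resid[i], protein$elety[i])
    hit <- match(k, key_specific)
    if (is.na(hit)) hit <- match(paste("*", protein$elety[i]), key_specific)
    if (!is.na(hit)) {
      labs <- strsplit(table$types[hit], ",", fixed = TRUE)[[1]]
      M[i, labs] <- TRUE
    }
  }
  M
}
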