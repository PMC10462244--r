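#' @title Atom-type vocabularies and residue bit encoding
#' @description
#' The interaction fingerprint used by the nativeness classifier is built
#' over a fixed cross-product of a 29-label ligand atom-type vocabulary and
#' a 13-label protein atom-type vocabulary (29 x 13 = 377 features).
#' Residues are separately encoded as 11-bit many-hot strings for triplet
#' fingerprinting.
#' @name vocab
NULL

#' Ligand atom-type vocabulary (29 labels)
#'
#' Fixed, ordered vocabulary of pharmacophoric/chemical atom types assigned
#' to ligand heavy atoms. An atom may carry several labels (e.g. a benzene
#' carbon is both "Aromatic" and "Aromatic Carbon"); each label it carries
#' contributes to the corresponding row of the interaction fingerprint.
#'
#' @return Character vector of length 29.
#' @export
ligand_type_vocab <- function() {
  c("Aromatic", "Hetero", "Halogen", "Negative Ionizable",
    "Positive Ionizable", "H-bond Donor", "H-bond Acceptor",
    "Amide Nitrogen", "Amine Nitrogen", "Vinyl", "Carboxylate Oxygen",
    "Alcohol Oxygen", "Nitro Oxygen", "Nitro Nitrogen", "Phosphate Oxygen",
    "Sulfone Sulfur", "Sulfoxide Sulfur", "Enol Oxygen", "Imine Nitrogen",
    "Enamine Nitrogen", "Aromatic Nitrogen", "Aromatic Oxygen",
    "Aromatic Sulfur", "Aromatic Carbon", "Aliphatic Carbon",
    "F", "Cl", "Br", "I")
}

#' Protein atom-type vocabulary (13 labels)
#'
#' Fixed, ordered vocabulary of atom types assigned to protein heavy atoms
#' via per-residue templates (see
#' `system.file("extdata", "protein_atom_types.tsv", package = "frasebot")`).
#'
#' @return Character vector of length 13.
#' @export
protein_type_vocab <- function() {
  c("Aromatic", "NegativeIonizable", "Positive Ionizable", "H-bond Donor",
    "H-bond Acceptor", "Amide Nitrogen", "Amine Nitrogen",
    "Carboxylate Oxygen", "Alcohol Oxygen", "Imine Nitrogen",
    "Aromatic Nitrogen", "Aromatic Carbon", "Aliphatic Carbon")
}

# package-local cache for the shipped rule tables
.frasebot_cache <- new.env(parent = emptyenv())

#' Residue 11-bit encoding table
#'
#' Loads (and caches) the 20-row table mapping each standard amino acid to
#' its 11-bit many-hot descriptor. Layout: positions 1-3 size thermometer,
#' 4-6 hydrophobicity thermometer, 7 H-bond acceptor, 8 H-bond donor,
#' 9 positive ionizable, 10 negative ionizable, 11 aromatic.
#'
#' Size terciles are thermometer-coded from side-chain heavy-atom counts
#' (thresholds >= 2, >= 5, >= 8 atoms); hydrophobicity from the
#' Fauchere-Pliska side-chain pi scale (thresholds >= 0.2, >= 1.0, >= 1.8),
#' which places tryptophan at the maximum (all three bits set) and glycine
#' at zero. The table is a plain TSV so an alternative encoding can be
#' dropped in via the `path` argument of [encode_residue()].
#'
#' @param path Optional path to an alternative TSV table.
#' @return A data.frame with rownames = 3-letter codes and 11 binary columns.
#' @export
residue_bits_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.frasebot_cache$residue_bits)) return(.frasebot_cache$residue_bits)
    path <- system.file("extdata", "residue_bits.tsv", package = "frasebot")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    rownames(tab) <- tab$res
    tab$res <- NULL
    stopifnot(nrow(tab) == 20L, ncol(tab) == 11L)
    .frasebot_cache$residue_bits <- tab
    return(tab)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  rownames(tab) <- tab$res
  tab$res <- NULL
  tab
}

#' Standard amino-acid codes
#' @return Character vector of the 20 standard 3-letter codes.
#' @export
standard_residues <- function() rownames(residue_bits_table())

#' Encode a residue as an 11-bit many-hot vector
#'
#' @param residue_name 3-letter amino-acid code (e.g. `"TRP"`).
#' @param table Optional encoding table from [residue_bits_table()].
#' @return Integer vector of length 11 with entries in {0, 1}.
#' @examples
#' encode_residue("TRP")  # size and hydrophobicity bits all 1
#' encode_residue("GLY")  # all bits 0
#' @export
encode_residue <- function(residue_name, table = residue_bits_table()) {
  residue_name <- toupper(residue_name)
  if (!residue_name %in% rownames(table)) {
    stop("encode_residue: unknown residue code '", residue_name, "'")
  }
  bits <- as.integer(table[residue_name, ])
  stopifnot(length(bits) == 11L, all(bits %in% c(0L, 1L)))
  bits
}

# bitstring form used for triplet fingerprints / hash keys
residue_bitstring <- function(residue_name, table = residue_bits_table()) {
  paste(encode_residue(residue_name, table), collapse = "")
}

# protein atom-type template table: data.frame(res, atom, types)
protein_type_table <- function(path = NULL) {
  if (is.null(path) && !is.null(.frasebot_cache$protein_types)) {
    return(.frasebot_cache$protein_types)
  }
  p <- if (is.null(path)) {
    system.file("extdata", "protein_atom_types.tsv", package = "frasebot")
  } else path
  tab <- utils::read.delim(p, stringsAsFactors = FALSE)
  vocab <- protein_type_vocab()
  for (s in tab$types) {
    labs <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (!all(labs %in% vocab)) {
      stop("protein_type_table: out-of-vocabulary label in '", s, "'")
    }
  }
  if (is.null(path)) .frasebot_cache$protein_types <- tab
  tab
}

# atomic masses for molecular-weight computation (monoisotopic-free average)
atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971, B = 10.81
)

# standard valences used for implicit-hydrogen counting
standard_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1, BR = 1, I = 1, H = 1,
  B = 3, SE = 2
)
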