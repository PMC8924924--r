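#' @importFrom stats runif rnorm rmultinom setNames dist
#' @importFrom utils head
NULL

# Metals retained on receptor ingestion; everything else inorganic is dropped.
METAL_WHITELIST <- c("NA", "FE", "MG", "K", "MN", "ZN", "CA")

# Single collapsed SYBYL type used for every whitelisted metal.
METAL_TYPE <- "Met"

DEFAULT_LIGAND_TYPES <- c(
  "C.1", "C.2", "C.3", "C.ar", "C.cat",
  "N.1", "N.2", "N.3", "N.4", "N.am", "N.ar", "N.pl3",
  "O.2", "O.3", "O.co2",
  "S.2", "S.3", "S.o", "S.o2", "P.3",
  "F", "Cl", "Br", "I", METAL_TYPE, "Other"
)

DEFAULT_RECEPTOR_TYPES <- c(
  "C.1", "C.2", "C.3", "C.ar", "C.cat",
  "N.2", "N.3", "N.4", "N.am", "N.ar", "N.pl3",
  "O.2", "O.3", "O.co2",
  "S.3", "P.3", "F", "Cl", "Br", "I", METAL_TYPE, "Other"
)

#' SYBYL atom-type vocabulary with disjoint ligand and receptor blocks
#'
#' Ligand and receptor atoms are treated as distinct entities: the same
#' SYBYL type (say \code{C.3}) occupies a different one-hot index depending
#' on which entity carries it. All whitelisted metals collapse onto the
#' single type \code{"Met"} before lookup.
#'
#' @param ligand_types character vector of SYBYL types for ligand atoms.
#' @param receptor_types character vector of SYBYL types for receptor atoms.
#' @return An object of class \code{sybyl_vocabulary} with the index map.
#' @export
sybyl_vocabulary <- function(ligand_types = DEFAULT_LIGAND_TYPES,
                             receptor_types = DEFAULT_RECEPTOR_TYPES) {
  stopifnot(!anyDuplicated(ligand_types), !anyDuplicated(receptor_types))
  if (!"Other" %in% ligand_types) ligand_types <- c(ligand_types, "Other")
  if (!"Other" %in% receptor_types) receptor_types <- c(receptor_types, "Other")
  keys <- c(paste0("L:", ligand_types), paste0("R:", receptor_types))
  vocab <- list(
    ligand = ligand_types,
    receptor = receptor_types,
    index = setNames(seq_along(keys), keys),
    size = length(keys)
  )
  class(vocab) <- "sybyl_vocabulary"
  vocab
}

#' @export
print.sybyl_vocabulary <- function(x, ...) {
  cat("SYBYL vocabulary:", length(x$ligand), "ligand +",
      length(x$receptor), "receptor types (", x$size, "one-hot columns )\n")
  invisible(x)
}

#' Collapse metal atom types onto the shared metal type
#'
#' Idempotent: non-metal types and the collapsed type pass through unchanged.
#'
#' @param type SYBYL type string(s).
#' @param element element symbol(s), used to recognise metals typed by element.
#' @return character vector of collapsed types.
#' @export
collapse_metal_type <- function(type, element = type) {
  is_met <- toupper(element) %in% METAL_WHITELIST |
    toupper(type) %in% METAL_WHITELIST | type == METAL_TYPE
  type[is_met] <- METAL_TYPE
  type
}

#' One-hot encode atoms against a SYBYL vocabulary
#'
#' @param atoms data.frame with columns \code{sybyl_type}, \code{entity}
#'   (\code{"ligand"} or \code{"receptor"}) and \code{element}.
#' @param vocab a \code{\link{sybyl_vocabulary}}.
#' @param unknown \code{"error"} (default) or \code{"other"}: what to do with
#'   a type absent from the entity's block.
#' @return numeric matrix, one row per atom, exactly one 1 per row; ligand
#'   and receptor types occupy disjoint column blocks.
#' @export
encode_onehot <- function(atoms, vocab, unknown = c("error", "other")) {
  unknown <- match.arg(unknown)
  stopifnot(inherits(vocab, "sybyl_vocabulary"))
  type <- collapse_metal_type(atoms$sybyl_type, atoms$element)
  pref <- ifelse(atoms$entity == "ligand", "L:", "R:")
  keys <- paste0(pref, type)
  idx <- vocab$index[keys]
  if (anyNA(idx)) {
    if (unknown == "error") {
      stop("SYBYL type(s) not in vocabulary: ",
           paste(unique(keys[is.na(idx)]), collapse = ", "))
    }
    idx[is.na(idx)] <- vocab$index[paste0(pref[is.na(idx)], "Other")]
  }
  m <- matrix(0, nrow(atoms), vocab$size)
  m[cbind(seq_len(nrow(atoms)), idx)] <- 1
  m
}

# ---- residue-template SYBYL typing for protein atoms ----------------------

.backbone_types <- c(N = "N.am", CA = "C.3", C = "C.2", O = "O.2",
                     OXT = "O.co2")

.sidechain_types <- list(
  ALA = c(CB = "C.3"),
  ARG = c(CB = "C.3", CG = "C.3", CD = "C.3", NE = "N.pl3", CZ = "C.cat",
          NH1 = "N.pl3", NH2 = "N.pl3"),
  ASN = c(CB = "C.3", CG = "C.2", OD1 = "O.2", ND2 = "N.am"),
  ASP = c(CB = "C.3", CG = "C.2", OD1 = "O.co2", OD2 = "O.co2"),
  CYS = c(CB = "C.3", SG = "S.3"),
  GLN = c(CB = "C.3", CG = "C.3", CD = "C.2", OE1 = "O.2", NE2 = "N.am"),
  GLU = c(CB = "C.3", CG = "C.3", CD = "C.2", OE1 = "O.co2", OE2 = "O.co2"),
  GLY = c(),
  HIS = c(CB = "C.3", CG = "C.ar", ND1 = "N.ar", CD2 = "C.ar", CE1 = "C.ar",
          NE2 = "N.ar"),
  ILE = c(CB = "C.3", CG1 = "C.3", CG2 = "C.3", CD1 = "C.3"),
  LEU = c(CB = "C.3", CG = "C.3", CD1 = "C.3", CD2 = "C.3"),
  LYS = c(CB = "C.3", CG = "C.3", CD = "C.3", CE = "C.3", NZ = "N.4"),
  MET = c(CB = "C.3", CG = "C.3", SD = "S.3", CE = "C.3"),
  PHE = c(CB = "C.3", CG = "C.ar", CD1 = "C.ar", CD2 = "C.ar", CE1 = "C.ar",
          CE2 = "C.ar", CZ = "C.ar"),
  PRO = c(CB = "C.3", CG = "C.3", CD = "C.3"),
  SER = c(CB = "C.3", OG = "O.3"),
  THR = c(CB = "C.3", OG1 = "O.3", CG2 = "C.3"),
  TRP = c(CB = "C.3", CG = "C.ar", CD1 = "C.ar", CD2 = "C.ar", NE1 = "N.ar",
          CE2 = "C.ar", CE3 = "C.ar", CZ2 = "C.ar", CZ3 = "C.ar",
          CH2 = "C.ar"),
  TYR = c(CB = "C.3", CG = "C.ar", CD1 = "C.ar", CD2 = "C.ar", CE1 = "C.ar",
          CE2 = "C.ar", CZ = "C.ar", OH = "O.3"),
  VAL = c(CB = "C.3", CG1 = "C.3", CG2 = "C.3")
)

.generic_element_type <- function(elem) {
  e <- toupper(elem)
  out <- rep("Other", length(e))
  out[e == "C"] <- "C.3"
  out[e == "N"] <- "N.3"
  out[e == "O"] <- "O.3"
  out[e == "S"] <- "S.3"
  out[e == "P"] <- "P.3"
  out[e == "F"] <- "F"
  out[e == "CL"] <- "Cl"
  out[e == "BR"] <- "Br"
  out[e == "I"] <- "I"
  out[e %in% METAL_WHITELIST] <- METAL_TYPE
  out
}

#' Assign SYBYL types to protein atoms from residue templates
#'
#' Standard amino acids use a fixed residue/atom-name lookup table
#' (deterministic, converter-free); atoms of non-standard residues fall back
#' to a generic per-element type; whitelisted metals collapse to the single
#' metal type.
#'
#' @param resid residue names (3-letter codes).
#' @param atom_name PDB atom names.
#' @param element element symbols.
#' @return character vector of SYBYL types.
#' @export
assign_protein_sybyl <- function(resid, atom_name, element) {
  n <- length(resid)
  out <- character(n)
  for (i in seq_len(n)) {
    r <- toupper(resid[i]); a <- toupper(atom_name[i])
    t <- NA_character_
    if (r %in% names(.sidechain_types)) {
      if (a %in% names(.backbone_types)) {
        t <- .backbone_types[[a]]
      } else if (a %in% names(.sidechain_types[[r]])) {
        t <- .sidechain_types[[r]][[a]]
      }
    }
    if (is.na(t)) t <- .generic_element_type(element[i])
    out[i] <- t
  }
  collapse_metal_type(out, element)
}
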