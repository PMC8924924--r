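# Domain containers -----------------------------------------------------------
#
# Atoms travel as a data.frame with columns:
#   index, element, sybyl_type, x, y, z, entity ("ligand"/"receptor"),
#   is_metal, and for receptors additionally chain, resno, resid, atom_name,
#   is_ca. Coordinates are Angstrom throughout; hydrogens never appear.

.check_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "sybyl_type", "x", "y", "z", "entity") %in%
                  names(atoms)))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(toupper(atoms$element) == "H"))
    stop("hydrogens are not allowed in atom tables (heavy atoms only)")
  invisible(atoms)
}

#' Construct a receptor structure
#'
#' @param atoms atom data.frame (entity \code{"receptor"}).
#' @return object of class \code{receptor_structure}.
#' @export
receptor_structure <- function(atoms) {
  atoms$entity <- "receptor"
  if (is.null(atoms$is_metal))
    atoms$is_metal <- toupper(atoms$element) %in% METAL_WHITELIST
  atoms$sybyl_type <- collapse_metal_type(atoms$sybyl_type, atoms$element)
  atoms$index <- seq_len(nrow(atoms))
  .check_atoms(atoms)
  structure(list(atoms = atoms), class = "receptor_structure")
}

#' Construct a ligand topology
#'
#' Bonds are used only for RMSD symmetry matching; the scoring network never
#' sees the covalent graph.
#'
#' @param atoms atom data.frame (entity \code{"ligand"}).
#' @param bonds data.frame with columns \code{i}, \code{j}, \code{order}
#'   (\code{order} is \code{"1"}, \code{"2"}, \code{"3"} or \code{"ar"}).
#' @return object of class \code{ligand_topology}.
#' @export
ligand_topology <- function(atoms, bonds) {
  atoms$entity <- "ligand"
  if (is.null(atoms$is_metal))
    atoms$is_metal <- toupper(atoms$element) %in% METAL_WHITELIST
  atoms$index <- seq_len(nrow(atoms))
  .check_atoms(atoms)
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "order") %in% names(bonds)))
  n <- nrow(atoms)
  if (nrow(bonds) > 0 &&
      (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n)))
    stop("bond indices reference non-existent atoms")
  g <- igraph::graph_from_edgelist(
    as.matrix(bonds[, c("i", "j")]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  if (n > 1 && !igraph::is_connected(g))
    stop("ligand bond graph is not connected")
  structure(list(atoms = atoms, bonds = bonds), class = "ligand_topology")
}

#' Construct a pose record
#'
#' @param coords n x 3 matrix of ligand heavy-atom coordinates (Angstrom),
#'   in topology atom order.
#' @param score docking score (lower is better for vina-like scores).
#' @param rank docking rank within the attempt (1 = best).
#' @param conf_id receptor conformation identifier.
#' @return object of class \code{pose_record}.
#' @export
pose_record <- function(coords, score = NA_real_, rank = 1L,
                        conf_id = "conf1") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, all(is.finite(coords)), rank >= 1)
  structure(list(coords = coords, score = score, rank = as.integer(rank),
                 conf_id = conf_id), class = "pose_record")
}

#' Construct a complex example
#'
#' The atomic unit of training and evaluation: one receptor conformation,
#' one ligand topology, one pose, a label, and provenance metadata.
#'
#' @param receptor \code{receptor_structure}.
#' @param ligand \code{ligand_topology}.
#' @param pose \code{pose_record}; coordinate count must match the ligand.
#' @param label one of \code{"hit"}, \code{"gap"}, \code{"miss"},
#'   \code{"unlabeled"}.
#' @param meta list of provenance fields (\code{pdb_id}, \code{target_id},
#'   \code{site_cluster}, \code{attempt_id}).
#' @return object of class \code{complex_example}.
#' @export
complex_example <- function(receptor, ligand, pose, label = "unlabeled",
                            meta = list()) {
  stopifnot(inherits(receptor, "receptor_structure"),
            inherits(ligand, "ligand_topology"),
            inherits(pose, "pose_record"))
  if (nrow(pose$coords) != nrow(ligand$atoms))
    stop("pose coordinate count does not match ligand heavy-atom count")
  label <- match.arg(label, c("hit", "gap", "miss", "unlabeled"))
  structure(list(receptor = receptor, ligand = ligand, pose = pose,
                 label = label, meta = meta), class = "complex_example")
}

#' @export
print.complex_example <- function(x, ...) {
  cat(sprintf("complex_example: %d receptor / %d ligand atoms, label=%s\n",
              nrow(x$receptor$atoms), nrow(x$ligand$atoms), x$label))
  invisible(x)
}

# Readers ----------------------------------------------------------------------

.water_resids <- c("HOH", "WAT", "DOD", "H2O")
.buffer_resids <- c("SO4", "PO4", "GOL", "EDO", "PEG", "ACT", "DMS", "TRS",
                    "MPD", "FMT", "CIT", "NO3", "IOD", "BME", "CL", "BR")

#' Read a receptor from a PDB file
#'
#' Drops waters, common crystallographic buffers and hydrogens; keeps
#' whitelisted metal ions (Na, Fe, Mg, K, Mn, Zn, Ca); keeps the
#' highest-occupancy alternate location; assigns SYBYL types to every
#' retained atom from residue templates.
#'
#' @param path PDB file.
#' @return \code{receptor_structure}.
#' @export
read_receptor <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  if (nrow(at) == 0) stop("empty PDB file: ", path)
  # highest-occupancy altloc per (chain, resno, atom name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- !logical(nrow(at))
    for (k in unique(key[duplicated(key)])) {
      rows <- which(key == k)
      keep[rows] <- FALSE
      keep[rows[which.max(occ[rows])]] <- TRUE
    }
    at <- at[keep, , drop = FALSE]
  }
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  resid <- toupper(trimws(at$resid))
  is_water <- resid %in% .water_resids
  is_h <- elem %in% c("H", "D")
  is_metal <- elem %in% METAL_WHITELIST & at$type == "HETATM"
  is_protein <- at$type == "ATOM" & !is_water
  is_buffer <- at$type == "HETATM" & !is_metal &
    (resid %in% .buffer_resids | is_water)
  keep <- !is_h & !is_water & !is_buffer & (is_protein | is_metal)
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  if (!any(at$type == "ATOM"))
    stop("no protein atoms in '", path, "' after filtering")
  atoms <- data.frame(
    element = elem,
    sybyl_type = assign_protein_sybyl(at$resid, at$elety, elem),
    x = at$x, y = at$y, z = at$z,
    entity = "receptor",
    is_metal = elem %in% METAL_WHITELIST & at$type == "HETATM",
    chain = at$chain, resno = at$resno, resid = trimws(at$resid),
    atom_name = trimws(at$elety),
    is_ca = trimws(at$elety) == "CA" & at$type == "ATOM",
    stringsAsFactors = FALSE
  )
  receptor_structure(atoms)
}

#' Write a receptor structure to a PDB file
#'
#' @param receptor \code{receptor_structure}.
#' @param path output PDB file.
#' @return \code{path}, invisibly.
#' @export
write_receptor <- function(receptor, path) {
  at <- receptor$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(at$is_metal, "HETATM", "ATOM"),
    resno = if (!is.null(at$resno)) at$resno else seq_len(nrow(at)),
    resid = if (!is.null(at$resid)) at$resid else "UNK",
    chain = if (!is.null(at$chain)) at$chain else "A",
    elety = if (!is.null(at$atom_name)) at$atom_name else at$element,
    elesy = at$element
  )
  invisible(path)
}

#' Read a ligand (and its conformers) from Mol2 or SDF
#'
#' Mol2 keeps the SYBYL types it declares; SDF records get types derived
#' from elements and bond orders. Hydrogens are dropped everywhere. A
#' multi-record file yields one topology (from the first record) plus one
#' \code{pose_record} per record.
#'
#' @param path Mol2 (SYBYL dialect) or SDF file; format from the extension.
#' @return list with elements \code{topology} (\code{ligand_topology}) and
#'   \code{poses} (list of \code{pose_record}).
#' @export
read_ligand <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mol2") .read_ligand_mol2(path)
  else if (ext %in% c("sdf", "sd", "mol")) .read_ligand_sdf(path)
  else stop("unsupported ligand format: .", ext)
}

.strip_h_topology <- function(atoms, bonds) {
  heavy <- which(toupper(atoms$element) != "H")
  remap <- match(seq_len(nrow(atoms)), heavy)
  bonds <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, , drop = FALSE]
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  list(atoms = atoms[heavy, , drop = FALSE], bonds = bonds)
}

.read_ligand_mol2 <- function(path) {
  # split multi-molecule mol2 on @<TRIPOS>MOLECULE, parse each with bio3d
  lines <- readLines(path)
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) stop("no molecule records in mol2 file: ", path)
  ends <- c(starts[-1] - 1, length(lines))
  topo <- NULL
  poses <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    tmp <- tempfile(fileext = ".mol2")
    writeLines(lines[starts[k]:ends[k]], tmp)
    m <- tryCatch(bio3d::read.mol2(tmp), error = function(e)
      stop("cannot parse mol2 record ", k, " in '", path, "': ",
           conditionMessage(e)))
    unlink(tmp)
    elem <- sub("\\..*$", "", m$atom$elety)
    atoms <- data.frame(
      element = elem, sybyl_type = m$atom$elety,
      x = m$atom$x, y = m$atom$y, z = m$atom$z,
      entity = "ligand", stringsAsFactors = FALSE
    )
    border <- tolower(as.character(m$bond$type))
    bonds <- data.frame(i = m$bond$origin, j = m$bond$target,
                        order = ifelse(border %in% c("ar", "am"), "ar",
                                       border),
                        stringsAsFactors = FALSE)
    st <- .strip_h_topology(atoms, bonds)
    if (k == 1) {
      st$atoms$sybyl_type <- collapse_metal_type(st$atoms$sybyl_type,
                                                 st$atoms$element)
      topo <- ligand_topology(st$atoms, st$bonds)
    }
    if (nrow(st$atoms) != nrow(topo$atoms))
      stop("conformer ", k, " has a different heavy-atom count")
    poses[[k]] <- pose_record(as.matrix(st$atoms[, c("x", "y", "z")]),
                              rank = k)
  }
  list(topology = topo, poses = poses)
}

.read_ligand_sdf <- function(path) {
  sdf <- tryCatch(ChemmineR::read.SDFset(path), error = function(e)
    stop("cannot parse SDF file '", path, "': ", conditionMessage(e)))
  n_rec <- length(sdf)
  if (n_rec == 0) stop("no records in SDF file: ", path)
  topo <- NULL
  poses <- vector("list", n_rec)
  for (k in seq_len(n_rec)) {
    ab <- ChemmineR::atomblock(sdf[[k]])
    bb <- ChemmineR::bondblock(sdf[[k]])
    elem <- gsub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = elem,
                        sybyl_type = NA_character_,
                        x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        entity = "ligand", stringsAsFactors = FALSE)
    ord <- as.character(bb[, 3])
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = ifelse(ord == "4", "ar", ord),
                        stringsAsFactors = FALSE)
    st <- .strip_h_topology(atoms, bonds)
    if (k == 1) {
      st$atoms$sybyl_type <- derive_sybyl_types(st$atoms, st$bonds)
      topo <- ligand_topology(st$atoms, st$bonds)
    }
    if (nrow(st$atoms) != nrow(topo$atoms))
      stop("SDF record ", k, " has a different heavy-atom count")
    poses[[k]] <- pose_record(as.matrix(st$atoms[, c("x", "y", "z")]),
                              rank = k)
  }
  list(topology = topo, poses = poses)
}

#' Derive approximate SYBYL types from elements and bond orders
#'
#' Used for SDF input, which carries no SYBYL typing. Carbon/nitrogen/
#' oxygen/sulfur hybridisation is inferred from the highest incident bond
#' order and aromatic flags; amides and carboxylates are recognised from
#' their local bond pattern.
#'
#' @param atoms atom data.frame.
#' @param bonds bond data.frame (\code{i}, \code{j}, \code{order}).
#' @return character vector of SYBYL types.
#' @export
derive_sybyl_types <- function(atoms, bonds) {
  n <- nrow(atoms)
  elem <- toupper(atoms$element)
  inc <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      inc[[bonds$i[b]]] <- c(inc[[bonds$i[b]]], b)
      inc[[bonds$j[b]]] <- c(inc[[bonds$j[b]]], b)
    }
  }
  other_end <- function(b, i) ifelse(bonds$i[b] == i, bonds$j[b], bonds$i[b])
  out <- character(n)
  for (i in seq_len(n)) {
    ords <- bonds$order[inc[[i]]]
    arom <- any(ords == "ar")
    hi <- suppressWarnings(max(c(0, as.numeric(ords[ords != "ar"]))))
    out[i] <- switch(elem[i],
      C = if (arom) "C.ar" else if (hi >= 3) "C.1"
          else if (hi >= 2) "C.2" else "C.3",
      N = {
        # amide N: single-bonded to a carbonyl carbon
        nb <- vapply(inc[[i]], other_end, integer(1), i = i)
        amide <- any(vapply(nb, function(j) {
          elem[j] == "C" && any(bonds$order[inc[[j]]] == "2" &
            elem[vapply(inc[[j]], other_end, integer(1), i = j)] == "O")
        }, logical(1)))
        if (arom) "N.ar" else if (amide) "N.am"
        else if (hi >= 3) "N.1" else if (hi >= 2) "N.2" else "N.3"
      },
      O = if (hi >= 2) "O.2" else "O.3",
      S = if (hi >= 2) "S.2" else "S.3",
      P = "P.3",
      F = "F", CL = "Cl", BR = "Br", I = "I",
      .generic_element_type(elem[i])
    )
  }
  collapse_metal_type(out, elem)
}

# Writers ----------------------------------------------------------------------

#' Write a ligand topology with one or more poses to a Mol2 file
#'
#' Emits one \code{@<TRIPOS>MOLECULE} record per pose, SYBYL dialect.
#'
#' @param ligand \code{ligand_topology}.
#' @param poses list of \code{pose_record} (default: topology coordinates).
#' @param path output file.
#' @param name molecule name.
#' @return \code{path}, invisibly.
#' @export
write_ligand_mol2 <- function(ligand, path, poses = NULL, name = "LIG") {
  at <- ligand$atoms; bd <- ligand$bonds
  if (is.null(poses))
    poses <- list(pose_record(as.matrix(at[, c("x", "y", "z")])))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    xyz <- p$coords
    writeLines(c("@<TRIPOS>MOLECULE", name,
                 sprintf("%5d %5d     1     0     0", nrow(at), nrow(bd)),
                 "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM"), con)
    writeLines(sprintf("%7d %-8s %9.4f %9.4f %9.4f %-8s %3d %-8s %9.4f",
                       seq_len(nrow(at)),
                       paste0(at$element, seq_len(nrow(at))),
                       xyz[, 1], xyz[, 2], xyz[, 3],
                       at$sybyl_type, 1L, "LIG1", 0), con)
    writeLines("@<TRIPOS>BOND", con)
    if (nrow(bd) > 0)
      writeLines(sprintf("%6d %5d %5d %-4s", seq_len(nrow(bd)),
                         bd$i, bd$j, bd$order), con)
  }
  invisible(path)
}

#' Write ligand poses to a multi-record V2000 SDF file
#'
#' @param ligand \code{ligand_topology}.
#' @param poses list of \code{pose_record}.
#' @param path output file.
#' @param name molecule name.
#' @return \code{path}, invisibly.
#' @export
write_ligand_sdf <- function(ligand, path, poses = NULL, name = "LIG") {
  at <- ligand$atoms; bd <- ligand$bonds
  if (is.null(poses))
    poses <- list(pose_record(as.matrix(at[, c("x", "y", "z")])))
  ord_num <- ifelse(bd$order == "ar", 4L, as.integer(bd$order))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in poses) {
    xyz <- p$coords
    writeLines(c(name, "  poserank", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(at), nrow(bd))), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       xyz[, 1], xyz[, 2], xyz[, 3], at$element), con)
    if (nrow(bd) > 0)
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", bd$i, bd$j, ord_num), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

# Pocket selection -------------------------------------------------------------

#' Select receptor atoms inside a (buffered) axis-aligned box
#'
#' The boundary is closed: an atom exactly on the buffered face is kept.
#'
#' @param receptor \code{receptor_structure}.
#' @param box numeric \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} in
#'   Angstrom, typically the ligand bounding box.
#' @param buffer margin added to every face (Angstrom).
#' @return \code{receptor_structure} restricted to the region.
#' @export
select_pocket <- function(receptor, box, buffer = 2.0) {
  stopifnot(length(box) == 6, box[1] <= box[2], box[3] <= box[4],
            box[5] <= box[6])
  at <- receptor$atoms
  keep <- at$x >= box[1] - buffer & at$x <= box[2] + buffer &
          at$y >= box[3] - buffer & at$y <= box[4] + buffer &
          at$z >= box[5] - buffer & at$z <= box[6] + buffer
  if (!any(keep)) stop("no receptor atoms in the selected region")
  receptor_structure(at[keep, , drop = FALSE])
}

#' Bounding box of a coordinate set
#'
#' @param coords n x 3 matrix.
#' @return numeric \code{c(xmin, xmax, ymin, ymax, zmin, zmax)}.
#' @export
coord_box <- function(coords) {
  coords <- as.matrix(coords)
  c(range(coords[, 1]), range(coords[, 2]), range(coords[, 3]))
}

#' Truncate a receptor to the ligand pocket for network input
#'
#' Default margin 8 Angstrom around the pose bounding box keeps every atom
#' that can appear in a neighborhood at the default cutoffs.
#'
#' @param example \code{complex_example}.
#' @param margin Angstrom.
#' @return \code{complex_example} with the truncated receptor.
#' @export
truncate_to_pocket <- function(example, margin = 8.0) {
  example$receptor <- select_pocket(example$receptor,
                                    coord_box(example$pose$coords),
                                    buffer = margin)
  example
}
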