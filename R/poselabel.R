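# Symmetry-corrected RMSD and hit/gap/miss labeling ---------------------------

.topology_graph <- function(topology) {
  at <- topology$atoms; bd <- topology$bonds
  g <- igraph::make_empty_graph(n = nrow(at), directed = FALSE)
  # vertex colors: elements; edge colors: bond class (aromatic distinct)
  elem_code <- as.integer(factor(toupper(at$element)))
  g <- igraph::set_vertex_attr(g, "color", value = elem_code)
  if (nrow(bd) > 0) {
    g <- igraph::add_edges(g, as.vector(t(as.matrix(bd[, c("i", "j")]))))
    ord_code <- as.integer(factor(as.character(bd$order),
                                  levels = c("1", "2", "3", "ar", "am")))
    ord_code[is.na(ord_code)] <- 1L
    g <- igraph::set_edge_attr(g, "color", value = ord_code)
  }
  g
}

#' Enumerate element- and bond-preserving automorphisms of a ligand graph
#'
#' @param topology \code{ligand_topology}.
#' @param cap maximum number of mappings returned (with a warning beyond).
#' @return list of integer permutations of the atom indices.
#' @export
ligand_automorphisms <- function(topology, cap = 10000L) {
  g <- .topology_graph(topology)
  maps <- igraph::isomorphisms(g, g, method = "vf2")
  maps <- lapply(maps, as.integer)
  if (length(maps) > cap) {
    warning("automorphism count ", length(maps), " exceeds cap ", cap,
            "; RMSD is a minimum over the first ", cap, " mappings")
    maps <- maps[seq_len(cap)]
  }
  maps
}

#' Symmetry-corrected RMSD between a docked pose and the native pose
#'
#' Minimum over all element- and bond-preserving atom mappings (graph
#' automorphisms) of the heavy-atom RMSD. No re-superposition of the ligand
#' is performed: the docked frame is meaningful.
#'
#' @param pose_coords n x 3 matrix, topology atom order.
#' @param native_coords n x 3 matrix, topology atom order.
#' @param topology \code{ligand_topology} shared by both coordinate sets.
#' @param maps optional precomputed automorphism list (from
#'   \code{\link{ligand_automorphisms}}); avoids re-enumeration in tight
#'   loops.
#' @return list with \code{rmsd} (Angstrom) and \code{mapping} (the
#'   minimising permutation). Use \code{\link{symmetry_rmsd}} for the bare
#'   number.
#' @export
symmetry_rmsd_full <- function(pose_coords, native_coords, topology,
                               maps = NULL) {
  pose_coords <- as.matrix(pose_coords)
  native_coords <- as.matrix(native_coords)
  n <- nrow(topology$atoms)
  if (nrow(pose_coords) != n || nrow(native_coords) != n)
    stop("coordinate sets must match the topology atom count")
  if (is.null(maps)) maps <- ligand_automorphisms(topology)
  best <- Inf; best_map <- seq_len(n)
  for (m in maps) {
    # pose atom m[i] corresponds to native atom i
    dev <- pose_coords[m, , drop = FALSE] - native_coords
    r <- sqrt(mean(rowSums(dev^2)))
    if (r < best) { best <- r; best_map <- m }
  }
  list(rmsd = best, mapping = best_map)
}

#' @rdname symmetry_rmsd_full
#' @inheritParams symmetry_rmsd_full
#' @return \code{symmetry_rmsd}: the minimum RMSD in Angstrom.
#' @export
symmetry_rmsd <- function(pose_coords, native_coords, topology,
                          maps = NULL) {
  symmetry_rmsd_full(pose_coords, native_coords, topology, maps)$rmsd
}

#' RMSD of a cross-docked pose after receptor superposition
#'
#' The native pose lives in the frame of receptor A; the docked pose in the
#' frame of receptor B. The supplied rigid transform (from
#' \code{\link{superpose_group}}) maps frame A onto frame B; it is applied
#' to the native coordinates before the symmetry-corrected RMSD.
#'
#' @param pose_coords pose in the B frame (n x 3).
#' @param native_coords native pose in the A frame (n x 3).
#' @param topology \code{ligand_topology}.
#' @param transform list with \code{R} (3 x 3 rotation) and \code{t}
#'   (length-3 translation): x -> R x + t.
#' @return RMSD in Angstrom.
#' @export
crossdock_rmsd <- function(pose_coords, native_coords, topology, transform) {
  if (is.null(transform) || is.null(transform$R) || is.null(transform$t))
    stop("a receptor superposition transform {R, t} is required")
  native_b <- apply_rigid(as.matrix(native_coords), transform)
  symmetry_rmsd(pose_coords, native_b, topology)
}

#' Apply a rigid transform x -> R x + t to coordinate rows
#'
#' @param coords n x 3 matrix.
#' @param transform list with \code{R} and \code{t}.
#' @return transformed n x 3 matrix.
#' @export
apply_rigid <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$R), 2, transform$t, "+")
}

#' Label a pose from its RMSD to the native pose
#'
#' Poses within 2.5 Angstrom (inclusive) are hits, poses strictly above
#' 4 Angstrom are misses, everything between is a gap.
#'
#' @param rmsd RMSD(s) in Angstrom, nonnegative.
#' @return character vector of \code{"hit"}/\code{"gap"}/\code{"miss"}.
#' @export
label_pose <- function(rmsd) {
  if (any(rmsd < 0)) stop("negative RMSD")
  ifelse(rmsd <= 2.5, "hit", ifelse(rmsd > 4, "miss", "gap"))
}

#' Label every pose of an attempt against its native pose
#'
#' @param poses list of \code{pose_record}.
#' @param native_coords native pose coordinates (n x 3).
#' @param topology \code{ligand_topology}.
#' @param transform optional receptor superposition (see
#'   \code{\link{crossdock_rmsd}}).
#' @return data.frame \code{(pose, rmsd, label)}.
#' @export
label_attempt <- function(poses, native_coords, topology, transform = NULL) {
  rmsd <- vapply(poses, function(p) {
    if (is.null(transform)) symmetry_rmsd(p$coords, native_coords, topology)
    else crossdock_rmsd(p$coords, native_coords, topology, transform)
  }, numeric(1))
  data.frame(pose = seq_along(poses), rmsd = rmsd, label = label_pose(rmsd))
}
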