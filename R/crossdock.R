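# Cross-docking group construction and train/test splits ----------------------

#' Optimal rigid superposition (Kabsch) of one point set onto another
#'
#' Closed-form least-squares fit via SVD of the covariance matrix, with the
#' usual determinant correction so the result is a proper rotation.
#'
#' @param mobile n x 3 matrix to move.
#' @param target n x 3 matrix to fit onto (row correspondence assumed).
#' @return list with \code{R} (3 x 3), \code{t} (length 3) such that
#'   \code{mobile \%*\% t(R) + t} best fits \code{target}, and \code{rmsd}
#'   after fitting.
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(nrow(mobile) == nrow(target), ncol(mobile) == 3)
  if (nrow(mobile) < 1) stop("no atoms to superpose")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(ct - R %*% cm)
  fitted <- sweep(A %*% t(R), 2, ct, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(R = R, t = t_vec, rmsd = rmsd)
}

.ca_coords <- function(receptor) {
  at <- receptor$atoms
  if (!is.null(at$is_ca) && any(at$is_ca))
    as.matrix(at[at$is_ca, c("x", "y", "z")])
  else
    as.matrix(at[, c("x", "y", "z")])  # pseudo-atom receptors: all atoms
}

#' Superpose all structures of a target onto the first member
#'
#' Least-squares rigid superposition on matched CA atoms (or all atoms for
#' pseudo-atom receptors); members whose post-fit RMSD exceeds
#' \code{max_rmsd} are dropped and reported.
#'
#' @param structures named list of \code{receptor_structure}, all of one
#'   target (Uniprot-like) id. CA atoms are matched positionally; members
#'   with a different CA count are dropped.
#' @param target_id the shared target id.
#' @param max_rmsd exclusion threshold in Angstrom (default 5).
#' @return object of class \code{target_group}: list with \code{target_id},
#'   \code{members} (names), \code{transforms} (per member, mapping that
#'   member's frame onto the reference frame), \code{rmsd} (per member),
#'   \code{dropped}.
#' @export
superpose_group <- function(structures, target_id = "target",
                            max_rmsd = 5.0) {
  stopifnot(length(structures) >= 1)
  if (is.null(names(structures)))
    names(structures) <- paste0("struct", seq_along(structures))
  ref <- .ca_coords(structures[[1]])
  if (nrow(ref) == 0) stop("no CA atoms to superpose on")
  members <- character(0); transforms <- list(); rmsds <- numeric(0)
  dropped <- character(0)
  for (nm in names(structures)) {
    xyz <- .ca_coords(structures[[nm]])
    if (nrow(xyz) != nrow(ref)) { dropped <- c(dropped, nm); next }
    fit <- kabsch(xyz, ref)
    if (fit$rmsd > max_rmsd) { dropped <- c(dropped, nm); next }
    members <- c(members, nm)
    transforms[[nm]] <- list(R = fit$R, t = fit$t)
    rmsds <- c(rmsds, fit$rmsd)
  }
  structure(list(target_id = target_id, members = members,
                 transforms = transforms,
                 rmsd = setNames(rmsds, members), dropped = dropped),
            class = "target_group")
}

#' Cluster binding sites by ligand center of mass
#'
#' Density clustering of the superposed ligand centers of mass with
#' \code{eps = 5}, \code{min_samples = 1}. At \code{min_samples = 1} the
#' DBSCAN definition reduces exactly to connected components of the
#' eps-neighborhood graph (single linkage at eps); every point is assigned
#' and no noise points are possible. The center of mass is the unweighted
#' mean of the ligand heavy-atom coordinates.
#'
#' @param coms n x 3 matrix of ligand centers of mass (already in the
#'   common superposed frame), or a list of ligand coordinate matrices.
#' @param eps neighborhood radius in Angstrom.
#' @return integer cluster ids, one per ligand, numbered by first
#'   occurrence.
#' @export
cluster_binding_sites <- function(coms, eps = 5.0) {
  if (is.list(coms))
    coms <- do.call(rbind, lapply(coms, function(m) colMeans(as.matrix(m))))
  coms <- as.matrix(coms)
  n <- nrow(coms)
  if (n == 0) return(integer(0))
  d <- as.matrix(dist(coms))
  adj <- d <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  as.integer(factor(comp, levels = unique(comp)))
}

#' Cap a binding-site cluster at a fixed number of representatives
#'
#' Uniform sampling without replacement, reproducible by seed. Clusters at
#' or under the cap are returned unchanged.
#'
#' @param members vector (or list) of cluster members.
#' @param max_n cap (default 5).
#' @param seed RNG seed.
#' @return subset of \code{members}, in original order.
#' @export
cap_representatives <- function(members, max_n = 5L, seed = 1L) {
  n <- if (is.data.frame(members)) nrow(members) else length(members)
  if (n <= max_n) return(members)
  keep <- sort(withr_seed_sample(n, max_n, seed))
  if (is.data.frame(members)) members[keep, , drop = FALSE]
  else members[keep]
}

# seeded sample that does not disturb the caller's RNG stream
withr_seed_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(n, k)
}

#' Keep only docking attempts that sampled at least one hit pose
#'
#' Attempts whose label table contains no pose with RMSD within the hit
#' threshold are dropped; labels themselves are never altered.
#'
#' @param attempts named list; each element has a \code{labels} data.frame
#'   with a \code{label} column (as from \code{\link{label_attempt}}).
#' @return the retained sublist.
#' @export
positive_pose_filter <- function(attempts) {
  keep <- vapply(attempts, function(a) any(a$labels$label == "hit"),
                 logical(1))
  attempts[keep]
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open 10,
#' extension 0.5 -- fixed convention, recorded in split metadata); identity
#' is the number of aligned matches divided by the shorter sequence length.
#'
#' @param a,b amino-acid sequence strings.
#' @return identity in [0, 1].
#' @export
sequence_identity <- function(a, b) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  sm <- matrix(-1, length(aa), length(aa), dimnames = list(aa, aa))
  diag(sm) <- 1
  al <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5)
  matches <- Biostrings::nmatch(al)
  matches / min(nchar(a), nchar(b))
}

#' Assign targets to train/test sides under a similarity constraint
#'
#' \code{kind = "uniprot"}: every unique target id is one unit, units are
#' assigned at random targeting \code{train_fraction}.
#' \code{kind = "seqsim70"} / \code{"seqsim50"}: targets whose pairwise
#' global sequence identity reaches the threshold (0.70 / 0.50) are linked;
#' connected components are assigned wholesale to one side by seeded greedy
#' bin-packing toward the train fraction, so no pair straddling the split
#' reaches the threshold.
#'
#' @param target_ids character vector of target ids (one per target).
#' @param sequences named character vector of sequences (names =
#'   target ids); required for the seqsim kinds.
#' @param kind \code{"uniprot"}, \code{"seqsim70"} or \code{"seqsim50"}.
#' @param train_fraction requested fraction of targets on the train side.
#' @param seed RNG seed.
#' @return object of class \code{split_assignment}: data.frame
#'   \code{(target_id, side)} plus attributes \code{kind}, \code{seed},
#'   \code{identity_convention}.
#' @export
make_split <- function(target_ids, sequences = NULL,
                       kind = c("uniprot", "seqsim70", "seqsim50"),
                       train_fraction = 0.7, seed = 1L) {
  kind <- match.arg(kind)
  ids <- unique(target_ids)
  if (kind == "uniprot") {
    comp <- seq_along(ids)
  } else {
    if (is.null(sequences)) stop("sequences required for seqsim splits")
    if (!all(ids %in% names(sequences)))
      stop("missing sequences for: ",
           paste(setdiff(ids, names(sequences)), collapse = ", "))
    thr <- if (kind == "seqsim70") 0.70 else 0.50
    n <- length(ids)
    adj <- matrix(FALSE, n, n)
    if (n > 1) {
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        adj[i, j] <- adj[j, i] <-
          sequence_identity(sequences[[ids[i]]], sequences[[ids[j]]]) >= thr
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
  }
  # greedy seeded bin-packing of components toward the train fraction:
  # a component joins the train side only when that improves the fit
  comp_ids <- unique(comp)
  sizes <- vapply(comp_ids, function(cid) sum(comp == cid), numeric(1))
  ord <- withr_seed_sample(length(comp_ids), length(comp_ids), seed)
  want <- train_fraction * length(ids)
  got <- 0
  side_of_comp <- setNames(rep("test", length(comp_ids)), comp_ids)
  last_added <- NA
  for (k in ord) {
    if (abs(got + sizes[k] - want) <= abs(got - want)) {
      side_of_comp[as.character(comp_ids[k])] <- "train"
      got <- got + sizes[k]
      last_added <- k
    }
  }
  if (length(comp_ids) > 1) {
    # both sides must be populated
    if (all(side_of_comp == "train"))
      side_of_comp[as.character(comp_ids[last_added])] <- "test"
    if (all(side_of_comp == "test")) {
      k <- ord[1]
      side_of_comp[as.character(comp_ids[k])] <- "train"
    }
  }
  if (all(side_of_comp == "train") || all(side_of_comp == "test"))
    warning("similarity graph leaves a single component on one side; ",
            "requested train fraction is unattainable")
  out <- data.frame(target_id = ids,
                    side = unname(side_of_comp[as.character(comp)]))
  attr(out, "kind") <- kind
  attr(out, "seed") <- seed
  attr(out, "identity_convention") <-
    "global NW alignment; identity = matches / shorter length"
  class(out) <- c("split_assignment", class(out))
  out
}
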