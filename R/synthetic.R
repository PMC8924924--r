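# Synthetic complexes with a planted interfacial signal -----------------------
#
# The generator emulates the statistical structure the method assumes:
# typed heavy-atom receptors lining a spherical pocket, small connected
# ligand graphs, per-attempt pose sets with the 5.0/15.5/79.5% hit/gap/miss
# mixture, multi-conformation receptor ensembles with ~1.6 A spread, and
# Uniprot-like target grouping with controllable sequence identity. The
# planted signal is a set of k type-complementary contacts (receptor amide
# N within 3.5 A of a ligand hydroxyl O in the native pose) that only
# interfacial message passing can resolve. Every decoy pose is a rigid
# motion of the single ligand conformer, so ligand-internal geometry
# carries no pose information by construction.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  force(expr)
}

.rand_unit <- function(n = 1) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

.rand_rotation <- function(max_angle = pi) {
  .rotation_matrix(as.numeric(.rand_unit()), runif(1, 0, max_angle))
}

# pseudo-atom SYBYL types mapped onto real residue/atom names so that a
# PDB round trip through the residue-template typer preserves them
.PSEUDO_ATOM_MAP <- list(
  "C.3"  = c(resid = "ALA", atom = "CB",  elem = "C"),
  "C.ar" = c(resid = "PHE", atom = "CG",  elem = "C"),
  "N.am" = c(resid = "ASN", atom = "ND2", elem = "N"),
  "O.2"  = c(resid = "ASN", atom = "OD1", elem = "O"),
  "O.3"  = c(resid = "SER", atom = "OG",  elem = "O"),
  "S.3"  = c(resid = "CYS", atom = "SG",  elem = "S"),
  "Met"  = c(resid = "ZN",  atom = "ZN",  elem = "ZN")
)

#' Specification of a synthetic study
#'
#' Defaults are the study conditions: the 5.0/15.5/79.5\% hit/gap/miss pose
#' mixture, up to 64 poses per attempt with a 1 Angstrom minimum pairwise
#' difference, and a ~1.6 Angstrom ensemble backbone spread.
#'
#' @param seed master seed; all generation is a pure function of
#'   (spec, seed).
#' @param n_targets number of targets.
#' @param structures_per_target receptor conformations (and docking
#'   attempts) per target.
#' @param pocket_radius pocket shell radius in Angstrom.
#' @param ligand_size heavy-atom count range.
#' @param mixture hit/gap/miss fractions (must sum to 1).
#' @param contacts planted type-complementary contact pairs k.
#' @param poses_per_attempt pose count per docking attempt.
#' @param min_pose_sep minimum pairwise pose RMSD in Angstrom.
#' @param ensemble_size conformations per generated ensemble.
#' @param backbone_scale target mean pairwise ensemble RMSD in Angstrom.
#' @param seq_length length of the Uniprot-like sequences.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1L, n_targets = 20L,
                           structures_per_target = 4L,
                           pocket_radius = 8.0,
                           ligand_size = c(8L, 30L),
                           mixture = c(hit = 0.05, gap = 0.155,
                                       miss = 0.795),
                           contacts = 3L,
                           poses_per_attempt = 64L,
                           min_pose_sep = 1.0,
                           ensemble_size = 6L,
                           backbone_scale = 1.6,
                           seq_length = 120L) {
  stopifnot(abs(sum(mixture) - 1) < 1e-9, length(mixture) == 3,
            contacts >= 1, pocket_radius > 4)
  structure(list(seed = as.integer(seed), n_targets = as.integer(n_targets),
                 structures_per_target = as.integer(structures_per_target),
                 pocket_radius = pocket_radius,
                 ligand_size = as.integer(ligand_size),
                 mixture = mixture, contacts = as.integer(contacts),
                 poses_per_attempt = as.integer(poses_per_attempt),
                 min_pose_sep = min_pose_sep,
                 ensemble_size = as.integer(ensemble_size),
                 backbone_scale = backbone_scale,
                 seq_length = as.integer(seq_length)),
            class = "synthetic_spec")
}

.pseudo_receptor_atoms <- function(xyz, types) {
  info <- do.call(rbind, .PSEUDO_ATOM_MAP[types])
  data.frame(element = unname(info[, "elem"]),
             sybyl_type = types,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             entity = "receptor",
             is_metal = types == "Met",
             chain = "A", resno = seq_len(nrow(xyz)),
             resid = unname(info[, "resid"]),
             atom_name = unname(info[, "atom"]),
             is_ca = FALSE, stringsAsFactors = FALSE)
}

#' Generate one synthetic target (receptor + ligand + native pose)
#'
#' The receptor is a shell of typed pseudo-atoms lining a spherical pocket
#' with k designated anchor atoms (amide N); the ligand is a connected
#' random tree of heavy atoms grown inside the pocket with k complementary
#' hydroxyl O atoms; the native pose satisfies every contact rule
#' (anchor-complement distance within 3.5 Angstrom) with no steric overlap
#' below 2.2 Angstrom.
#'
#' @param spec \code{synthetic_spec}.
#' @param index target index (1-based); determinism is per (spec, index).
#' @return list with \code{receptor}, \code{ligand} (native coordinates),
#'   \code{native} (\code{pose_record}), \code{anchors} (receptor atom
#'   indices), \code{contacts} (ligand atom indices), \code{target_id}.
#' @export
gen_target <- function(spec, index = 1L) {
  .with_seed(spec$seed * 1000L + 7919L * as.integer(index), {
    k <- spec$contacts
    rp <- spec$pocket_radius
    n_lig <- sample(spec$ligand_size[1]:spec$ligand_size[2], 1)
    # ligand: random connected tree grown inside the pocket
    for (attempt in 1:50) {
      pos <- matrix(0, n_lig, 3)
      parent <- integer(n_lig)
      ok <- TRUE
      for (a in seq_len(n_lig)[-1]) {
        placed <- FALSE
        for (try in 1:60) {
          p_idx <- sample.int(a - 1, 1)
          cand <- pos[p_idx, ] + 1.5 * as.numeric(.rand_unit())
          if (sqrt(sum(cand^2)) > rp - 2.5) next
          d <- sqrt(rowSums((pos[seq_len(a - 1), , drop = FALSE] -
                               matrix(cand, a - 1, 3, byrow = TRUE))^2))
          d[p_idx] <- Inf
          if (all(d >= 1.2)) {
            pos[a, ] <- cand; parent[a] <- p_idx; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("ligand generation failed for target ", index)
    pos <- sweep(pos, 2, colMeans(pos))   # center in the pocket
    lig_types <- sample(c("C.3", "C.ar", "N.3", "O.2"), n_lig,
                        replace = TRUE, prob = c(0.55, 0.25, 0.1, 0.1))
    # N.3 is ligand-only here; keep it out of the pseudo-receptor map
    contact_idx <- sample.int(n_lig, k)
    lig_types[contact_idx] <- "O.3"
    bonds <- data.frame(i = parent[-1], j = seq_len(n_lig)[-1],
                        order = "1", stringsAsFactors = FALSE)
    lig_atoms <- data.frame(
      element = sub("\\..*$", "", lig_types), sybyl_type = lig_types,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      entity = "ligand", stringsAsFactors = FALSE)
    ligand <- ligand_topology(lig_atoms, bonds)
    # anchors: one amide N outward of each contact atom, ~3.0 A away
    anchor_xyz <- matrix(0, k, 3)
    for (ci in seq_len(k)) {
      placed <- FALSE
      for (try in 1:200) {
        base <- pos[contact_idx[ci], ]
        dir <- if (sqrt(sum(base^2)) > 0.5 && try <= 100)
          base / sqrt(sum(base^2)) else as.numeric(.rand_unit())
        cand <- base + runif(1, 2.6, 3.4) * dir
        d_lig <- sqrt(rowSums((pos - matrix(cand, n_lig, 3,
                                            byrow = TRUE))^2))
        d_lig[contact_idx[ci]] <- Inf
        d_anc <- if (ci > 1)
          sqrt(rowSums((anchor_xyz[seq_len(ci - 1), , drop = FALSE] -
                          matrix(cand, ci - 1, 3, byrow = TRUE))^2))
        else Inf
        if (all(d_lig >= 2.2) && all(d_anc >= 2.2) &&
            sqrt(sum(cand^2)) <= rp + 1.5) {
          anchor_xyz[ci, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("anchor placement failed for target ", index)
    }
    # pocket shell
    n_shell <- 70L
    shell <- matrix(NA_real_, n_shell, 3)
    got <- 0L
    for (try in 1:4000) {
      if (got >= n_shell) break
      cand <- as.numeric(.rand_unit()) * (rp + runif(1, 0, 2.5))
      d_all <- sqrt(rowSums((rbind(anchor_xyz,
                                   shell[seq_len(got), , drop = FALSE]) -
                               matrix(cand, got + k, 3, byrow = TRUE))^2))
      d_lig <- sqrt(rowSums((pos - matrix(cand, n_lig, 3, byrow = TRUE))^2))
      if (all(d_all >= 2.2) && all(d_lig >= 3.0)) {
        got <- got + 1L
        shell[got, ] <- cand
      }
    }
    shell <- shell[seq_len(got), , drop = FALSE]
    shell_types <- sample(c("C.3", "C.ar", "O.2", "S.3"), got,
                          replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05))
    rec_xyz <- rbind(anchor_xyz, shell)
    rec_types <- c(rep("N.am", k), shell_types)
    if (index %% 3 == 0) {   # occasional structural metal on the shell
      mpos <- as.numeric(.rand_unit()) * (rp + 1)
      rec_xyz <- rbind(rec_xyz, mpos)
      rec_types <- c(rec_types, "Met")
    }
    receptor <- receptor_structure(.pseudo_receptor_atoms(rec_xyz,
                                                          rec_types))
    native <- pose_record(pos, score = 0, rank = 1L, conf_id = "conf1")
    list(receptor = receptor, ligand = ligand, native = native,
         anchors = seq_len(k), contacts = contact_idx,
         target_id = sprintf("UP%05d", as.integer(index)))
  })
}

.identity_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# rigid re-placement of the native conformer: rotate about the pose
# centroid, then translate
.rigid_pose <- function(native, R, t_vec) {
  ctr <- colMeans(native)
  sweep(sweep(native, 2, ctr) %*% t(R), 2, ctr + t_vec, "+")
}

#' Generate a labeled pose set for one docking attempt
#'
#' Class counts are one multinomial draw at the spec mixture (recorded in
#' the result). Hits are bounded rigid jitters of the native pose, gaps are
#' rigid offsets rejection-sampled into the (2.5, 4] window, misses are
#' random rigid placements inside the pocket. Every pose keeps at least
#' \code{min_pose_sep} RMSD from every other, avoids receptor clashes, and
#' every emitted label is recomputed from the symmetry-corrected RMSD,
#' never trusted from construction.
#'
#' @param target result of \code{\link{gen_target}}.
#' @param spec \code{synthetic_spec}.
#' @param receptor receptor conformation to dock against (default the
#'   target's own).
#' @param n_poses poses to generate (default \code{spec$poses_per_attempt}).
#' @param attempt_id attempt identifier string.
#' @param conf_id receptor conformation id.
#' @param seed RNG seed for this attempt.
#' @return list with \code{examples} (list of \code{complex_example}),
#'   \code{labels} (data.frame pose/rmsd/label), \code{counts} (the
#'   multinomial draw).
#' @export
gen_poses <- function(target, spec, receptor = target$receptor,
                      n_poses = spec$poses_per_attempt,
                      attempt_id = "a1", conf_id = "conf1", seed = 1L) {
  .with_seed(seed, {
    native <- target$native$coords
    n_lig <- nrow(native)
    rec_xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
    auto_maps <- ligand_automorphisms(target$ligand)
    counts <- as.integer(rmultinom(1, n_poses, spec$mixture))
    names(counts) <- names(spec$mixture)
    want <- rep(c("hit", "gap", "miss"), counts)
    poses <- list()
    accept_ok <- function(cand) {
      if (length(poses) > 0) {
        for (p in poses)
          if (.identity_rmsd(cand, p) < spec$min_pose_sep) return(FALSE)
      }
      d2 <- outer(rowSums(cand^2), rowSums(rec_xyz^2), "+") -
        2 * cand %*% t(rec_xyz)
      min(d2) >= 1.9^2   # no receptor contact below 1.9 A
    }
    rmsds <- numeric(0)
    for (cls in want) {
      placed <- FALSE
      for (try in 1:400) {
        cand <- switch(cls,
          hit = .rigid_pose(native, .rand_rotation(runif(1, 0, 0.45)),
                            runif(1, 0, 1.6) * as.numeric(.rand_unit())),
          gap = .rigid_pose(native, .rand_rotation(runif(1, 0, 0.7)),
                            runif(1, 2.2, 4.6) * as.numeric(.rand_unit())),
          miss = .rigid_pose(native, .rand_rotation(),
                             runif(1, 0, spec$pocket_radius - 2.5) *
                               as.numeric(.rand_unit()))
        )
        if (max(sqrt(rowSums(cand^2))) > spec$pocket_radius + 1.0) next
        r <- symmetry_rmsd(cand, native, target$ligand, maps = auto_maps)
        lab <- label_pose(r)
        if (lab != cls) next
        if (!accept_ok(cand)) next
        poses[[length(poses) + 1]] <- cand
        rmsds <- c(rmsds, r)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not satisfy the pose mixture (class ", cls,
             ") within the retry budget for attempt ", attempt_id)
    }
    # emulated docking score: weakly informative, rank by it
    dock_score <- rmsds + rnorm(length(rmsds), 0, 3)
    dock_rank <- rank(dock_score, ties.method = "first")
    order_out <- order(dock_rank)
    labels <- label_pose(rmsds)
    examples <- lapply(order_out, function(i) {
      complex_example(
        receptor, target$ligand,
        pose_record(poses[[i]], score = dock_score[i],
                    rank = dock_rank[i], conf_id = conf_id),
        label = labels[i],
        meta = list(target_id = target$target_id, attempt_id = attempt_id,
                    conf_id = conf_id, rmsd = rmsds[i],
                    pdb_id = attempt_id, site_cluster = 1L))
    })
    list(examples = examples,
         labels = data.frame(pose = seq_along(order_out),
                             rmsd = rmsds[order_out],
                             label = labels[order_out]),
         counts = counts)
  })
}

#' Generate a receptor conformational ensemble
#'
#' Each member displaces every atom by a smooth correlated field (a sum of
#' three random long-wavelength sinusoidal modes), rescaled so the mean
#' pairwise all-atom RMSD across members matches the requested scale.
#'
#' @param receptor \code{receptor_structure}.
#' @param n ensemble size.
#' @param scale target mean pairwise RMSD in Angstrom; 0 gives identical
#'   copies.
#' @param seed RNG seed.
#' @return list of \code{receptor_structure} of length \code{n}.
#' @export
gen_ensemble <- function(receptor, n = 6L, scale = 1.6, seed = 1L) {
  .with_seed(seed, {
    xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
    lapply(seq_len(n), function(m) {
      disp <- matrix(0, nrow(xyz), 3)
      if (scale > 0) {
        for (mode in 1:3) {
          kvec <- as.numeric(.rand_unit()) * runif(1, 2 * pi / 25,
                                                   2 * pi / 12)
          amp <- as.numeric(.rand_unit())
          phase <- runif(1, 0, 2 * pi)
          disp <- disp + outer(sin(xyz %*% kvec + phase)[, 1], amp)
        }
        rms <- sqrt(mean(rowSums(disp^2)))
        disp <- disp * (scale / sqrt(2)) / rms
      }
      at <- receptor$atoms
      at[, c("x", "y", "z")] <- xyz + disp
      receptor_structure(at)
    })
  })
}

#' Generate a full synthetic study
#'
#' Targets with shared Uniprot-like ids, receptor conformations, sequences
#' with controllable pairwise identity (consecutive target pairs are ~85\%
#' identical so similarity splits are exercisable), labeled pose sets per
#' attempt, and everything the cross-docking and training pipelines
#' consume.
#'
#' @param spec \code{synthetic_spec}.
#' @param docking \code{"self"} (all attempts against the crystal
#'   conformation) or \code{"ensemble"} (attempts cycle through the
#'   conformations).
#' @param verbose print progress.
#' @return object of class \code{synthetic_study}: list with \code{spec},
#'   \code{targets}, \code{structures} (per target), \code{sequences},
#'   \code{examples} (flat list of \code{complex_example}),
#'   \code{attempts} (per-attempt label tables).
#' @export
gen_study <- function(spec, docking = c("self", "ensemble"),
                      verbose = FALSE) {
  docking <- match.arg(docking)
  targets <- lapply(seq_len(spec$n_targets), function(i)
    gen_target(spec, i))
  sequences <- .gen_sequences(spec, vapply(targets, `[[`, "",
                                           "target_id"))
  structures <- lapply(seq_len(spec$n_targets), function(i) {
    ens <- gen_ensemble(targets[[i]]$receptor,
                        n = spec$structures_per_target,
                        scale = spec$backbone_scale,
                        seed = spec$seed * 100L + i)
    # the crystal conformation is member 1
    ens[[1]] <- targets[[i]]$receptor
    names(ens) <- sprintf("%s_conf%d", targets[[i]]$target_id,
                          seq_along(ens))
    ens
  })
  examples <- list()
  attempts <- list()
  for (i in seq_len(spec$n_targets)) {
    if (verbose) message("target ", i, "/", spec$n_targets)
    for (j in seq_len(spec$structures_per_target)) {
      conf <- if (docking == "self") 1L else j
      rec <- structures[[i]][[conf]]
      aid <- sprintf("%s_a%d", targets[[i]]$target_id, j)
      gp <- gen_poses(targets[[i]], spec, receptor = rec,
                      attempt_id = aid,
                      conf_id = names(structures[[i]])[conf],
                      seed = spec$seed * 10000L + i * 100L + j)
      examples <- c(examples, gp$examples)
      attempts[[aid]] <- list(target_id = targets[[i]]$target_id,
                              labels = gp$labels, counts = gp$counts)
    }
  }
  structure(list(spec = spec, targets = targets, structures = structures,
                 sequences = sequences, examples = examples,
                 attempts = attempts, docking = docking),
            class = "synthetic_study")
}

.gen_sequences <- function(spec, target_ids) {
  .with_seed(spec$seed + 333L, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    n <- length(target_ids)
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (i %% 2 == 0) {
        # mutate the previous target's sequence at ~15% of positions
        prev <- strsplit(seqs[i - 1], "")[[1]]
        mut <- runif(length(prev)) < 0.15
        prev[mut] <- sample(aa, sum(mut), replace = TRUE)
        seqs[i] <- paste(prev, collapse = "")
      } else {
        seqs[i] <- paste(sample(aa, spec$seq_length, replace = TRUE),
                         collapse = "")
      }
    }
    setNames(seqs, target_ids)
  })
}
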