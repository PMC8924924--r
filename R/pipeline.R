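# End-to-end plumbing: cross-docking build over a study, manifests ------------

#' Build cross-docking groups for a synthetic (or loaded) study
#'
#' For every target: superpose its receptor conformations onto the first
#' member, cluster the superposed native-ligand centers of mass into
#' binding sites (eps = 5, min_samples = 1), cap each site at five
#' representatives, and drop docking attempts that sampled no hit pose.
#'
#' @param study \code{synthetic_study}.
#' @param max_rmsd superposition exclusion threshold (Angstrom).
#' @param cap representatives kept per binding-site cluster.
#' @param seed seed for representative sampling.
#' @return list with \code{groups} (per target: \code{target_group},
#'   cluster ids, kept members) and \code{attempts} (the retained,
#'   positive-filtered attempt list).
#' @export
crossdock_build <- function(study, max_rmsd = 5.0, cap = 5L, seed = 1L) {
  groups <- list()
  for (i in seq_along(study$targets)) {
    tid <- study$targets[[i]]$target_id
    grp <- superpose_group(study$structures[[i]], target_id = tid,
                           max_rmsd = max_rmsd)
    # native ligand COM per retained member, in the reference frame
    coms <- lapply(grp$members, function(nm) {
      apply_rigid(study$targets[[i]]$native$coords, grp$transforms[[nm]])
    })
    sites <- cluster_binding_sites(coms)
    kept <- unlist(lapply(split(grp$members, sites),
                          cap_representatives, max_n = cap,
                          seed = seed + i))
    groups[[tid]] <- list(group = grp, sites = sites, kept = kept)
  }
  attempts <- positive_pose_filter(study$attempts)
  list(groups = groups, attempts = attempts)
}

#' Split a study's targets into train and test sets
#'
#' @param study \code{synthetic_study}.
#' @param kind \code{"uniprot"}, \code{"seqsim70"} or \code{"seqsim50"}.
#' @param train_fraction requested train fraction.
#' @param seed RNG seed.
#' @return \code{split_assignment}.
#' @export
study_split <- function(study, kind = "uniprot", train_fraction = 0.7,
                        seed = 1L) {
  ids <- vapply(study$targets, `[[`, "", "target_id")
  make_split(ids, study$sequences, kind = kind,
             train_fraction = train_fraction, seed = seed)
}

#' Partition study examples by a split assignment
#'
#' @param study \code{synthetic_study}.
#' @param split \code{split_assignment}.
#' @param attempts optional retained attempt list (e.g. after
#'   \code{\link{crossdock_build}}); examples of dropped attempts are
#'   excluded.
#' @return list with \code{train} and \code{test} example lists.
#' @export
study_examples <- function(study, split, attempts = NULL) {
  side <- setNames(split$side, split$target_id)
  keep_attempt <- if (is.null(attempts)) NULL else names(attempts)
  pick <- function(want) {
    Filter(function(e) {
      ok <- identical(unname(side[e$meta$target_id]), want)
      if (!is.null(keep_attempt))
        ok <- ok && e$meta$attempt_id %in% keep_attempt
      ok
    }, study$examples)
  }
  list(train = pick("train"), test = pick("test"))
}

# Manifest ---------------------------------------------------------------------

#' Write a study to disk (structures, poses, manifest)
#'
#' Receptor conformations go to PDB, ligand topologies to Mol2 (SYBYL
#' dialect), pose sets to multi-record SDF, sequences to FASTA, and a
#' JSON-lines manifest ties one complex example per line to its files.
#'
#' @param study \code{synthetic_study}.
#' @param dir output directory (created).
#' @return the manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seq_path <- file.path(dir, "targets.fasta")
  writeLines(paste0(">", names(study$sequences), "\n", study$sequences),
             seq_path)
  manifest <- file.path(dir, "manifest.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (i in seq_along(study$targets)) {
    tgt <- study$targets[[i]]
    tid <- tgt$target_id
    for (nm in names(study$structures[[i]]))
      write_receptor(study$structures[[i]][[nm]],
                     file.path(dir, paste0(nm, ".pdb")))
    write_ligand_mol2(tgt$ligand, file.path(dir, paste0(tid, "_ligand.mol2")),
                      name = tid)
  }
  by_attempt <- split(
    study$examples,
    vapply(study$examples, function(e) e$meta$attempt_id, character(1)))
  for (aid in names(by_attempt)) {
    exs <- by_attempt[[aid]]
    ord <- order(vapply(exs, function(e) e$pose$rank, integer(1)))
    exs <- exs[ord]
    lig <- exs[[1]]$ligand
    write_ligand_sdf(lig, file.path(dir, paste0(aid, "_poses.sdf")),
                     poses = lapply(exs, `[[`, "pose"), name = aid)
    for (e in exs) {
      rec <- jsonlite::toJSON(list(
        attempt_id = aid, target_id = e$meta$target_id,
        pdb_id = e$meta$pdb_id, site_cluster = e$meta$site_cluster,
        receptor_file = paste0(e$meta$conf_id, ".pdb"),
        ligand_file = paste0(e$meta$target_id, "_ligand.mol2"),
        pose_file = paste0(aid, "_poses.sdf"),
        pose_index = e$pose$rank, docking_score = e$pose$score,
        docking_rank = e$pose$rank, rmsd = e$meta$rmsd,
        label = e$label), auto_unbox = TRUE, digits = NA)
      writeLines(rec, con)
    }
  }
  invisible(manifest)
}

#' Read a study manifest back into complex examples
#'
#' @param manifest path to a JSON-lines manifest written by
#'   \code{\link{write_study}} (or following the same contract).
#' @return list with \code{examples} (list of \code{complex_example}) and
#'   \code{sequences} (if a \code{targets.fasta} sits next to the
#'   manifest).
#' @export
read_manifest <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest)
  recs <- lapply(lines, jsonlite::fromJSON)
  rec_cache <- new.env(); lig_cache <- new.env(); pose_cache <- new.env()
  get_cached <- function(cache, key, loader) {
    if (!exists(key, cache)) assign(key, loader(file.path(dir, key)), cache)
    get(key, cache)
  }
  examples <- lapply(recs, function(r) {
    receptor <- get_cached(rec_cache, r$receptor_file, read_receptor)
    lig <- get_cached(lig_cache, r$ligand_file,
                      function(p) read_ligand(p)$topology)
    poses <- get_cached(pose_cache, r$pose_file,
                        function(p) read_ligand(p)$poses)
    p <- poses[[r$pose_index]]
    p$score <- r$docking_score
    p$rank <- as.integer(r$docking_rank)
    complex_example(receptor, lig, p, label = r$label,
                    meta = list(target_id = r$target_id,
                                attempt_id = r$attempt_id,
                                pdb_id = r$pdb_id,
                                site_cluster = r$site_cluster,
                                conf_id = sub("\\.pdb$", "",
                                              r$receptor_file),
                                rmsd = r$rmsd))
  })
  seqs <- NULL
  fasta <- file.path(dir, "targets.fasta")
  if (file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    seqs <- setNames(as.character(ss), names(ss))
  }
  list(examples = examples, sequences = seqs)
}
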