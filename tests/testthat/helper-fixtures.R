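# Shared fixtures and independent oracles for the test suite.
# Everything is built in code at test time; nothing is read from disk.

# regular benzene ring, C-C 1.39 A, aromatic bonds
benzene_topology <- function() {
  ang <- (0:5) * pi / 3
  r <- 1.39
  atoms <- data.frame(
    element = "C", sybyl_type = "C.ar",
    x = r * cos(ang), y = r * sin(ang), z = 0,
    entity = "ligand", stringsAsFactors = FALSE)
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = "ar",
                      stringsAsFactors = FALSE)
  ligand_topology(atoms, bonds)
}

# random connected molecule (tree + optional ring closure) with mixed
# elements and bond orders; n <= 12 keeps brute-force enumeration feasible
random_molecule <- function(n, seed) {
  set.seed(seed)
  pos <- matrix(0, n, 3)
  parent <- integer(n)
  for (a in seq_len(n)[-1]) {
    repeat {
      parent[a] <- sample.int(a - 1, 1)
      d <- rnorm(3); d <- 1.5 * d / sqrt(sum(d^2))
      cand <- pos[parent[a], ] + d
      if (a == 2 || min(sqrt(rowSums(sweep(pos[1:(a - 1), , drop = FALSE],
                                           2, cand)^2))) > 1.0) {
        pos[a, ] <- cand
        break
      }
    }
  }
  elems <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- data.frame(i = parent[-1], j = seq_len(n)[-1],
                      order = sample(c("1", "1", "2"), n - 1,
                                     replace = TRUE),
                      stringsAsFactors = FALSE)
  atoms <- data.frame(element = elems,
                      sybyl_type = paste0(elems, ".3"),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      entity = "ligand", stringsAsFactors = FALSE)
  ligand_topology(atoms, bonds)
}

# brute-force automorphism enumeration by recursive backtracking over
# element- and bond-preserving assignments (independent of igraph)
bf_automorphisms <- function(topology) {
  n <- nrow(topology$atoms)
  elem <- toupper(topology$atoms$element)
  bd <- topology$bonds
  bkey <- matrix("", n, n)
  if (nrow(bd) > 0) {
    for (b in seq_len(nrow(bd))) {
      bkey[bd$i[b], bd$j[b]] <- bkey[bd$j[b], bd$i[b]] <-
        as.character(bd$order[b])
    }
  }
  out <- list()
  assign_next <- function(mapping) {
    a <- length(mapping) + 1
    if (a > n) {
      out[[length(out) + 1]] <<- as.integer(mapping)
      return(invisible())
    }
    for (cand in setdiff(seq_len(n), mapping)) {
      if (elem[cand] != elem[a]) next
      ok <- TRUE
      for (prev in seq_along(mapping)) {
        if (bkey[a, prev] != bkey[cand, mapping[prev]]) { ok <- FALSE; break }
      }
      if (ok) assign_next(c(mapping, cand))
    }
  }
  assign_next(integer(0))
  out
}

bf_min_rmsd <- function(pose, native, topology) {
  maps <- bf_automorphisms(topology)
  min(vapply(maps, function(m)
    sqrt(mean(rowSums((pose[m, , drop = FALSE] - native)^2))), numeric(1)))
}

# quadratic-time pairwise ROC AUC estimator (ties count one half)
bf_roc_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# random rigid transform and its application to a whole complex
rand_rigid_transform <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  list(R = R, t = rnorm(3, 0, 5))
}

transform_example <- function(example, tr) {
  at <- example$receptor$atoms
  xyz <- apply_rigid(as.matrix(at[, c("x", "y", "z")]), tr)
  at[, c("x", "y", "z")] <- xyz
  example$receptor <- receptor_structure(at)
  example$pose$coords <- apply_rigid(example$pose$coords, tr)
  example
}

# permute ligand atoms (topology + pose rows) and receptor atoms
permute_example <- function(example, seed) {
  set.seed(seed)
  nl <- nrow(example$ligand$atoms)
  pl <- sample.int(nl)       # new order: position k holds old atom pl[k]
  inv <- order(pl)
  at <- example$ligand$atoms[pl, , drop = FALSE]
  bd <- example$ligand$bonds
  bd$i <- inv[bd$i]; bd$j <- inv[bd$j]
  example$ligand <- ligand_topology(at, bd)
  example$pose$coords <- example$pose$coords[pl, , drop = FALSE]
  ra <- example$receptor$atoms
  example$receptor <- receptor_structure(
    ra[sample.int(nrow(ra)), , drop = FALSE])
  example
}

# small standard study shared by fast tests (memoized per session)
.fix_env <- new.env(parent = emptyenv())

small_study <- function() {
  if (!exists("small_study", .fix_env)) {
    spec <- synthetic_spec(seed = 7, n_targets = 6,
                           structures_per_target = 2,
                           poses_per_attempt = 24)
    assign("small_study", gen_study(spec), .fix_env)
  }
  get("small_study", .fix_env)
}

# full-scale fixture + trained models for the acceptance properties;
# built once and reused by every block that needs it
ablation_fixture <- function() {
  if (!exists("ablation", .fix_env)) {
    spec <- synthetic_spec(seed = 2024)
    study <- gen_study(spec)
    split <- study_split(study, kind = "uniprot", train_fraction = 0.75,
                         seed = 5)
    se <- study_examples(study, split)
    cfg_int <- parse_layer_config("l->l->r->l->r->l")
    cfg_lig <- parse_layer_config("l->l->l->l->l->l")
    tc <- training_config(epochs = 30, seed = 17)
    fit_int <- train_graphite(se$train, cfg_int, train_cfg = tc)
    fit_lig <- train_graphite(se$train, cfg_lig,
                              train_cfg = training_config(epochs = 5,
                                                          seed = 17))
    y <- vapply(se$test, function(e) e$label, "") == "hit"
    s_int <- score_examples(se$test, fit_int)
    s_lig <- score_examples(se$test, fit_lig)
    assign("ablation", list(study = study, split = split, se = se,
                            fit_int = fit_int, fit_lig = fit_lig,
                            y = y, s_int = s_int, s_lig = s_lig),
           .fix_env)
  }
  get("ablation", .fix_env)
}
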