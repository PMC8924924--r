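test_that("superposition recovers a known rigid transform exactly", {
  st <- small_study()
  rec <- st$structures[[1]][[1]]
  tr <- rand_rigid_transform(77)
  at2 <- rec$atoms
  at2[, c("x", "y", "z")] <-
    apply_rigid(as.matrix(rec$atoms[, c("x", "y", "z")]), tr)
  moved <- receptor_structure(at2)
  grp <- superpose_group(list(ref = rec, moved = moved), "T1")
  expect_equal(unname(grp$rmsd["moved"]), 0, tolerance = 1e-6)
  # recovered transform inverts the applied one
  got <- grp$transforms[["moved"]]
  expect_equal(got$R %*% tr$R, diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # group of one: identity transform, zero RMSD
  solo <- superpose_group(list(only = rec), "T1")
  expect_equal(solo$transforms[["only"]]$R, diag(3), tolerance = 1e-12)
  expect_equal(unname(solo$rmsd), 0)
})

test_that("kabsch equals the optimal rigid fit from an independent tool", {
  for (seed in 1:5) {
    set.seed(seed)
    P <- matrix(rnorm(30), 10, 3)
    Q <- matrix(rnorm(30), 10, 3)
    fit <- kabsch(P, Q)
    moved <- matrix(bio3d::fit.xyz(as.vector(t(Q)), as.vector(t(P)),
                                   fixed.inds = 1:30, mobile.inds = 1:30),
                    ncol = 3, byrow = TRUE)
    oracle <- sqrt(mean(rowSums((moved - Q)^2)))
    expect_equal(fit$rmsd, oracle, tolerance = 1e-6)
    # the returned transform achieves the reported RMSD
    moved <- apply_rigid(P, fit)
    expect_equal(sqrt(mean(rowSums((moved - Q)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("members beyond 5 A optimal RMSD are excluded from the group", {
  st <- small_study()
  rec <- st$structures[[2]][[1]]
  xyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  set.seed(12)
  at_far <- rec$atoms
  # perturb until the *optimal* fit RMSD exceeds 5 A
  repeat {
    pert <- xyz + matrix(rnorm(length(xyz), 0, 6), nrow(xyz), 3)
    if (kabsch(pert, xyz)$rmsd > 5) break
  }
  at_far[, c("x", "y", "z")] <- pert
  grp <- superpose_group(list(ref = rec, far = receptor_structure(at_far)),
                         "T2")
  expect_equal(grp$members, "ref")
  expect_equal(grp$dropped, "far")
})

test_that("site clustering merges 4 A centers and separates 6 A centers", {
  coms <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(length(unique(cluster_binding_sites(coms))), 1)
  coms2 <- rbind(c(0, 0, 0), c(6, 0, 0))
  expect_equal(length(unique(cluster_binding_sites(coms2))), 2)
  # single ligand: one cluster (min_samples = 1, no noise points)
  expect_equal(cluster_binding_sites(matrix(c(1, 2, 3), 1)), 1L)
  # chaining: 0 -- 4 -- 8 is one density-connected cluster
  expect_equal(length(unique(cluster_binding_sites(
    rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))))), 1)
})

test_that("site clustering is invariant to input order", {
  set.seed(3)
  coms <- rbind(matrix(rnorm(15, 0, 2), 5, 3),
                matrix(rnorm(15, 20, 2), 5, 3))
  c1 <- cluster_binding_sites(coms)
  perm <- sample.int(10)
  c2 <- cluster_binding_sites(coms[perm, ])
  # same partition, possibly different cluster numbers
  expect_equal(outer(c1[perm], c1[perm], "=="), outer(c2, c2, "=="))
})

test_that("representative capping is uniform, seeded and conservative", {
  expect_equal(cap_representatives(letters[1:3], 5, seed = 1),
               letters[1:3])
  s1 <- cap_representatives(1:100, 5, seed = 9)
  s2 <- cap_representatives(1:100, 5, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  # empirical selection frequency approximates 5/100 per member
  counts <- integer(100)
  for (seed in 1:400) {
    sel <- cap_representatives(1:100, 5, seed = seed)
    counts[sel] <- counts[sel] + 1
  }
  freq <- counts / 400
  expect_equal(mean(freq), 0.05, tolerance = 1e-9)
  expect_true(all(freq > 0.005 & freq < 0.15))
})

test_that("the positive-pose filter drops hitless attempts, keeps labels", {
  mk <- function(labs) list(labels = data.frame(
    pose = seq_along(labs), rmsd = NA, label = labs))
  attempts <- list(
    a = mk(c(rep("miss", 63), "hit")),
    b = mk(c("gap", rep("miss", 10))),
    c = mk(c("hit", "hit", "gap")),
    d = mk(rep("miss", 5)))
  kept <- positive_pose_filter(attempts)
  expect_setequal(names(kept), c("a", "c"))
  expect_identical(kept$a, attempts$a)
})

test_that("sequence identity convention behaves at the anchors", {
  expect_equal(sequence_identity("ACDEFGHIKL", "ACDEFGHIKL"), 1)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  m <- "ACDEFGHIKLMNPQRSTAAA"   # 17/20 identical
  expect_equal(sequence_identity(s, m), 0.85, tolerance = 1e-9)
})

test_that("uniprot splits co-locate identical ids; seqsim respects bounds", {
  ids <- c("A", "A", "B", "C")
  sp <- make_split(ids, kind = "uniprot", train_fraction = 0.5, seed = 2)
  expect_equal(nrow(sp), 3)   # unique targets
  expect_length(unique(sp$side[sp$target_id == "A"]), 1)

  st <- small_study()
  for (kind in c("seqsim70", "seqsim50")) {
    sp <- study_split(st, kind = kind, seed = 4)
    thr <- if (kind == "seqsim70") 0.70 else 0.50
    expect_true(all(c("train", "test") %in% sp$side))
    tr <- sp$target_id[sp$side == "train"]
    te <- sp$target_id[sp$side == "test"]
    for (a in tr) for (b in te) {
      expect_lt(sequence_identity(st$sequences[[a]], st$sequences[[b]]),
                thr)
    }
  }
})

test_that("highly similar sequence pairs land on the same side", {
  st <- small_study()
  sp <- study_split(st, kind = "seqsim70", seed = 4)
  side <- setNames(sp$side, sp$target_id)
  ids <- names(st$sequences)
  # generator makes consecutive pairs ~85% identical
  for (i in seq(2, length(ids), by = 2)) {
    idd <- sequence_identity(st$sequences[[ids[i - 1]]],
                             st$sequences[[ids[i]]])
    if (idd >= 0.70)
      expect_equal(unname(side[ids[i - 1]]), unname(side[ids[i]]))
  }
})
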