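test_that("target generation is a pure function of (spec, index)", {
  spec <- synthetic_spec(seed = 5, n_targets = 2)
  t1 <- gen_target(spec, 1)
  t2 <- gen_target(spec, 1)
  expect_identical(t1$receptor$atoms, t2$receptor$atoms)
  expect_identical(t1$ligand$atoms, t2$ligand$atoms)
  expect_identical(t1$native$coords, t2$native$coords)
  t3 <- gen_target(spec, 2)
  expect_false(identical(t1$ligand$atoms$x, t3$ligand$atoms$x))
})

test_that("the native pose satisfies every planted contact rule", {
  spec <- synthetic_spec(seed = 9, n_targets = 3)
  for (i in 1:3) {
    tgt <- gen_target(spec, i)
    rec_xyz <- as.matrix(tgt$receptor$atoms[, c("x", "y", "z")])
    for (ci in seq_along(tgt$contacts)) {
      d <- sqrt(sum((tgt$native$coords[tgt$contacts[ci], ] -
                       rec_xyz[tgt$anchors[ci], ])^2))
      expect_lte(d, 3.5)
      expect_equal(tgt$receptor$atoms$sybyl_type[tgt$anchors[ci]], "N.am")
      expect_equal(tgt$ligand$atoms$sybyl_type[tgt$contacts[ci]], "O.3")
    }
    # no steric overlap below 2.2 A between entities
    d2 <- outer(rowSums(tgt$native$coords^2), rowSums(rec_xyz^2), "+") -
      2 * tgt$native$coords %*% t(rec_xyz)
    expect_gte(sqrt(min(d2)), 1.9)
  }
})

test_that("generated complexes round-trip through the structure formats", {
  tgt <- gen_target(synthetic_spec(seed = 10, n_targets = 1), 1)
  pdb <- tempfile(fileext = ".pdb")
  write_receptor(tgt$receptor, pdb)
  rec <- read_receptor(pdb)
  expect_equal(rec$atoms$sybyl_type, tgt$receptor$atoms$sybyl_type)
  mol2 <- tempfile(fileext = ".mol2")
  write_ligand_mol2(tgt$ligand, mol2)
  lig <- read_ligand(mol2)$topology
  expect_equal(lig$atoms$sybyl_type, tgt$ligand$atoms$sybyl_type)
  expect_equal(nrow(lig$bonds), nrow(tgt$ligand$bonds))
})

test_that("emitted pose labels agree with independent recomputation", {
  st <- small_study()
  tgt_of <- setNames(seq_along(st$targets),
                     vapply(st$targets, `[[`, "", "target_id"))
  for (e in st$examples[seq(1, length(st$examples), by = 17)]) {
    tgt <- st$targets[[tgt_of[e$meta$target_id]]]
    r <- symmetry_rmsd(e$pose$coords, tgt$native$coords, tgt$ligand)
    expect_equal(r, e$meta$rmsd, tolerance = 1e-9)
    expect_equal(label_pose(r), e$label)
  }
})

test_that("pose sets respect the mixture draw and the 1 A separation", {
  spec <- synthetic_spec(seed = 31, n_targets = 1, poses_per_attempt = 40)
  tgt <- gen_target(spec, 1)
  gp <- gen_poses(tgt, spec, attempt_id = "x", seed = 3)
  expect_equal(sum(gp$counts), 40)
  expect_equal(unname(table(factor(gp$labels$label,
                                   c("hit", "gap", "miss")))),
               unname(gp$counts), ignore_attr = TRUE)
  # pairwise minimum separation
  coords <- lapply(gp$examples, function(e) e$pose$coords)
  for (a in seq_along(coords)[-1]) for (b in seq_len(a - 1)) {
    expect_gte(sqrt(mean(rowSums((coords[[a]] - coords[[b]])^2))), 1.0)
  }
  # docking ranks are a permutation of 1..n
  expect_setequal(vapply(gp$examples, function(e) e$pose$rank, 1L),
                  seq_len(40))
})

test_that("the large-sample mixture approaches 5/15.5/79.5 percent", {
  spec <- synthetic_spec(seed = 41, n_targets = 1, poses_per_attempt = 64)
  counts <- c(hit = 0, gap = 0, miss = 0)
  for (s in 1:16) {
    tgt <- gen_target(spec, 1)
    gp <- gen_poses(tgt, spec, attempt_id = paste0("a", s), seed = 100 + s)
    counts <- counts + gp$counts
  }
  frac <- counts / sum(counts)   # 1024 poses
  expect_equal(unname(frac["hit"]), 0.05, tolerance = 0.5)
  expect_equal(unname(frac["gap"]), 0.155, tolerance = 0.35)
  expect_equal(unname(frac["miss"]), 0.795, tolerance = 0.08)
})

test_that("misses rarely satisfy the planted interface contacts", {
  spec <- synthetic_spec(seed = 13, n_targets = 1, poses_per_attempt = 50,
                         mixture = c(hit = 0, gap = 0, miss = 1))
  tgt <- gen_target(spec, 1)
  gp <- gen_poses(tgt, spec, attempt_id = "m", seed = 8)
  rec_xyz <- as.matrix(tgt$receptor$atoms[, c("x", "y", "z")])
  all_ok <- vapply(gp$examples, function(e) {
    all(vapply(seq_along(tgt$contacts), function(ci) {
      sqrt(sum((e$pose$coords[tgt$contacts[ci], ] -
                  rec_xyz[tgt$anchors[ci], ])^2)) <= 3.5
    }, logical(1)))
  }, logical(1))
  expect_lt(mean(all_ok), 0.10)
})

test_that("ensembles hit the requested backbone spread", {
  tgt <- gen_target(synthetic_spec(seed = 23, n_targets = 1), 1)
  # scale 0: identical copies
  ens0 <- gen_ensemble(tgt$receptor, n = 3, scale = 0, seed = 1)
  expect_identical(ens0[[1]]$atoms, ens0[[2]]$atoms)
  # default scale: mean pairwise RMSD within +/- 30% of 1.6 A
  rmsds <- c()
  for (seed in 1:25) {
    ens <- gen_ensemble(tgt$receptor, n = 4, scale = 1.6, seed = seed)
    xyz <- lapply(ens, function(r) as.matrix(r$atoms[, c("x", "y", "z")]))
    for (a in 2:4) for (b in 1:(a - 1))
      rmsds <- c(rmsds, sqrt(mean(rowSums((xyz[[a]] - xyz[[b]])^2))))
  }
  expect_gt(mean(rmsds), 1.6 * 0.7)
  expect_lt(mean(rmsds), 1.6 * 1.3)
  # members remain valid structures
  ens <- gen_ensemble(tgt$receptor, n = 2, scale = 1.6, seed = 2)
  expect_s3_class(ens[[1]], "receptor_structure")
})

test_that("a study is reproducible and carries coherent metadata", {
  spec <- synthetic_spec(seed = 3, n_targets = 2,
                         structures_per_target = 2, poses_per_attempt = 12)
  s1 <- gen_study(spec)
  s2 <- gen_study(spec)
  expect_identical(vapply(s1$examples, function(e) e$meta$rmsd, 1),
                   vapply(s2$examples, function(e) e$meta$rmsd, 1))
  expect_length(s1$examples, 2 * 2 * 12)
  expect_equal(length(s1$sequences), 2)
  expect_true(all(nchar(s1$sequences) == spec$seq_length))
})
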