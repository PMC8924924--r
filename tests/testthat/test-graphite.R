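make_small_model <- function(spec_str = "l->l->r->l->r->l", seed = 5) {
  v <- sybyl_vocabulary()
  cfg <- parse_layer_config(spec_str)
  par <- graphite_params(cfg, v, channels = 8L, n_basis = 6L, hidden = 12L,
                         seed = seed)
  list(v = v, cfg = cfg, par = par)
}

test_that("analytic gradients match finite differences at a generic point", {
  m <- make_small_model()
  ex <- small_study()$examples[[1]]
  fx <- featurize_example(ex, m$cfg, m$v, n_basis = 6L)
  par <- m$par
  # move off the zero-bias initialisation (LeakyReLU kink, flat LayerNorm)
  set.seed(8)
  for (li in seq_along(par$layers))
    for (nm in names(par$layers[[li]]))
      par$layers[[li]][[nm]] <- par$layers[[li]][[nm]] +
        rnorm(length(par$layers[[li]][[nm]]), 0, 0.05)
  for (nm in names(par$final))
    par$final[[nm]] <- par$final[[nm]] +
      rnorm(length(par$final[[nm]]), 0, 0.05)
  fwd <- graphite_forward(fx, m$cfg, par, keep_cache = TRUE)
  g <- graphite_backward(fx, m$cfg, par, fwd, dlogit = 1)
  probe <- function(get, set, gval) {
    p0 <- get(par)
    ks <- unique(round(seq(1, length(p0), length.out = 3)))
    for (k in ks) {
      pa <- set(par, k, 1e-5); pb <- set(par, k, -1e-5)
      num <- (graphite_forward(fx, m$cfg, pa)$logit -
                graphite_forward(fx, m$cfg, pb)$logit) / 2e-5
      expect_equal(gval[k], num, tolerance = 1e-4)
    }
  }
  for (li in seq_along(par$layers)) for (nm in names(par$layers[[li]])) {
    probe(function(p) p$layers[[li]][[nm]],
          function(p, k, d) { p$layers[[li]][[nm]][k] <-
            p$layers[[li]][[nm]][k] + d; p },
          as.numeric(g$layers[[li]][[nm]]))
  }
  for (nm in names(par$final)) {
    probe(function(p) p$final[[nm]],
          function(p, k, d) { p$final[[nm]][k] <- p$final[[nm]][k] + d; p },
          as.numeric(g$final[[nm]]))
  }
})

test_that("the logit is invariant under atom permutation and rigid motion", {
  m <- make_small_model()
  for (i in c(1, 4, 9)) {
    ex <- small_study()$examples[[i]]
    base <- graphite_logit(ex, m$cfg, m$par, m$v)
    perm <- graphite_logit(permute_example(ex, 11 + i), m$cfg, m$par, m$v)
    expect_equal(perm, base, tolerance = 1e-5)
    rig <- graphite_logit(transform_example(ex, rand_rigid_transform(31 + i)),
                          m$cfg, m$par, m$v)
    expect_equal(rig, base, tolerance = 1e-4)
  }
})

test_that("with no edges the interaction block reduces to the skip path", {
  m <- make_small_model("l->l")
  # one-atom ligand, distant receptor atom: the l->l layer has no edges
  lig <- ligand_topology(
    data.frame(element = "C", sybyl_type = "C.3", x = 0, y = 0, z = 0,
               entity = "ligand", stringsAsFactors = FALSE),
    data.frame(i = integer(0), j = integer(0), order = character(0)))
  rec <- receptor_structure(
    data.frame(element = "C", sybyl_type = "C.3", x = 50, y = 0, z = 0,
               entity = "receptor", stringsAsFactors = FALSE))
  ex <- complex_example(rec, lig, pose_record(matrix(0, 1, 3)))
  fx <- featurize_example(ex, m$cfg, m$v, n_basis = 6L)
  expect_length(fx$layers[[1]]$dist, 0)
  base <- graphite_forward(fx, m$cfg, m$par)$logit
  # zeroing the kernel weights must not change anything (empty sum)
  par0 <- m$par
  par0$layers[[1]]$Wk[] <- 0
  expect_equal(graphite_forward(fx, m$cfg, par0)$logit, base)
})

test_that("zero kernel weights equal the zero-edge case on a real complex", {
  m <- make_small_model("l->l")
  ex <- small_study()$examples[[2]]
  fx <- featurize_example(ex, m$cfg, m$v, n_basis = 6L)
  expect_gt(length(fx$layers[[1]]$src_local), 0)
  par0 <- m$par
  par0$layers[[1]]$Wk[] <- 0
  # manually remove all edges from the featurization
  fx_no <- fx
  fx_no$layers[[1]]$src_local <- integer(0)
  fx_no$layers[[1]]$tgt_local <- integer(0)
  fx_no$layers[[1]]$dist <- numeric(0)
  expect_equal(graphite_forward(fx, m$cfg, par0)$logit,
               graphite_forward(fx_no, m$cfg, par0)$logit)
})

test_that("the convolution sum is linear in coincident sources", {
  # 1 target ligand atom; receptor sources duplicated at the same position
  m <- make_small_model("r->l")
  mk <- function(n_src) {
    rec <- receptor_structure(
      data.frame(element = "N", sybyl_type = "N.am",
                 x = rep(3, n_src), y = 0, z = 0,
                 entity = "receptor", stringsAsFactors = FALSE))
    lig <- ligand_topology(
      data.frame(element = "C", sybyl_type = "C.3", x = 0, y = 0, z = 0,
                 entity = "ligand", stringsAsFactors = FALSE),
      data.frame(i = integer(0), j = integer(0), order = character(0)))
    complex_example(rec, lig, pose_record(matrix(0, 1, 3)))
  }
  conv_term <- function(n_src) {
    fx <- featurize_example(mk(n_src), m$cfg, m$v, n_basis = 6L)
    fwd <- graphite_forward(fx, m$cfg, m$par, keep_cache = TRUE)
    fwd$cache$layer[[1]]$pre   # pre-MLP: convolution sum (no target skip)
  }
  one <- conv_term(1)
  two <- conv_term(2)
  expect_equal(two, 2 * one, tolerance = 1e-10)
})

test_that("readout pooling doubles when every ligand atom is duplicated", {
  m <- make_small_model("l")    # embedding-only: z_L is the pooled one-hot
  lig1 <- random_molecule(5, 2)
  rec <- receptor_structure(
    data.frame(element = "C", sybyl_type = "C.3", x = 20, y = 0, z = 0,
               entity = "receptor", stringsAsFactors = FALSE))
  ex1 <- complex_example(rec, lig1,
                         pose_record(as.matrix(lig1$atoms[, c("x", "y", "z")])))
  # coincident duplicate of every ligand atom, chained into the bond graph
  at2 <- rbind(lig1$atoms, lig1$atoms)
  bd2 <- rbind(lig1$bonds,
               data.frame(i = seq_len(5), j = seq_len(5) + 5, order = "1"))
  lig2 <- ligand_topology(at2, bd2)
  ex2 <- complex_example(rec, lig2,
                         pose_record(as.matrix(at2[, c("x", "y", "z")])))
  fx1 <- featurize_example(ex1, m$cfg, m$v, n_basis = 6L)
  fx2 <- featurize_example(ex2, m$cfg, m$v, n_basis = 6L)
  f1 <- graphite_forward(fx1, m$cfg, m$par, keep_cache = TRUE)
  f2 <- graphite_forward(fx2, m$cfg, m$par, keep_cache = TRUE)
  expect_equal(f2$cache$z, 2 * f1$cache$z, tolerance = 1e-12)
})

test_that("a ligand-only configuration scores rigid re-placements equally", {
  m <- make_small_model("l->l->l")
  st <- small_study()
  aid <- names(st$attempts)[1]
  exs <- Filter(function(e) e$meta$attempt_id == aid, st$examples)
  logits <- vapply(exs, graphite_logit, numeric(1),
                   config = m$cfg, params = m$par, vocab = m$v)
  # every pose is a rigid motion of one conformer: identical ligand features
  expect_lt(diff(range(logits)), 1e-8)
})

test_that("forward is reproducible and params depend only on the seed", {
  m1 <- make_small_model(seed = 33)
  m2 <- make_small_model(seed = 33)
  expect_identical(m1$par$layers, m2$par$layers)
  ex <- small_study()$examples[[1]]
  expect_identical(graphite_logit(ex, m1$cfg, m1$par, m1$v),
                   graphite_logit(ex, m2$cfg, m2$par, m2$v))
})

test_that("rescore_attempt sorts by logit with stable docking-rank ties", {
  m <- make_small_model()
  st <- small_study()
  aid <- names(st$attempts)[2]
  exs <- Filter(function(e) e$meta$attempt_id == aid, st$examples)
  rs <- rescore_attempt(exs, m$cfg, m$par, m$v)
  expect_setequal(rs$pose, seq_along(exs))
  expect_equal(rs$anpr_rank, seq_along(exs))
  expect_true(all(diff(rs$logit) <= 1e-12))
  # exactly tied logits preserve the docking order (zeroed readout head)
  tied <- m$par
  tied$final$Wf2[] <- 0
  rs2 <- rescore_attempt(exs, m$cfg, tied, m$v)
  expect_true(all(rs2$logit == rs2$logit[1]))
  expect_equal(rs2$docking_rank, sort(rs2$docking_rank))
  # single pose
  rs3 <- rescore_attempt(exs[1], m$cfg, m$par, m$v)
  expect_equal(rs3$anpr_rank, 1L)
})

test_that("checkpoints round-trip bit-exactly", {
  m <- make_small_model()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(path, m$cfg, m$par, m$v, extra = list(note = "test"))
  ck <- load_checkpoint(path)
  expect_identical(ck$params$layers, m$par$layers)
  expect_identical(ck$params$final, m$par$final)
  ex <- small_study()$examples[[1]]
  expect_identical(graphite_logit(ex, ck$config, ck$params, ck$vocab),
                   graphite_logit(ex, m$cfg, m$par, m$v))
})
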