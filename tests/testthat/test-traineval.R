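test_that("ROC AUC equals the pairwise brute-force estimator", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:120, 1)
    scores <- round(rnorm(n), 1)   # rounding forces ties
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), bf_roc_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "one class")
})

test_that("ROC AUC agrees with an independent library implementation", {
  set.seed(11)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, 0.2)
  ours <- roc_auc(scores, labels)
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("perfect separation gives ROC and PR AUC of 1", {
  scores <- c(5, 4, 3, 1, 0.5)
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(roc_auc(scores, labels), 1)
  expect_equal(pr_auc(scores, labels), 1)
})

test_that("random scores at 5% positives give AUC 0.5 and PR AUC 0.05", {
  set.seed(19)
  n <- 100000
  labels <- rbinom(n, 1, 0.05)
  scores <- runif(n)
  expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.01)
  expect_lt(abs(pr_auc(scores, labels) - 0.05), 0.005)
})

test_that("top-n pose enrichment reproduces hand counts", {
  # three attempts whose first hit appears at ranks 1, 2 and 16
  mk <- function(first_hit, n = 16) {
    rmsd <- rep(10, n); rmsd[first_hit] <- 1.0
    data.frame(rank = 1:n, rmsd = rmsd)
  }
  curve <- topn_pose_enrichment(list(mk(1), mk(2), mk(16)))
  expect_equal(curve$fraction[1], 1 / 3)
  expect_equal(curve$fraction[2], 2 / 3)
  expect_equal(curve$fraction[16], 1)
  # monotone non-decreasing, bounded in [0, 1]
  expect_true(all(diff(curve$fraction) >= 0))
  expect_true(all(curve$fraction >= 0 & curve$fraction <= 1))
  # an attempt whose rank-1 pose is always a hit gives a constant 1 curve
  allhit <- topn_pose_enrichment(list(mk(1), mk(1)))
  expect_true(all(allhit$fraction == 1))
  # a permutation cannot change the curve endpoint (same pose set)
  perm <- lapply(list(mk(1), mk(2), mk(16)), function(a) {
    a$rank <- sample(a$rank); a })
  expect_equal(topn_pose_enrichment(perm)$fraction[16], curve$fraction[16])
  expect_error(topn_pose_enrichment(list()), "no attempts")
})

test_that("enrichment factors follow the closed form", {
  # 10 compounds, 2 actives both in the top half: ef(0.5) = (0.2)^-1 * 2/5
  active <- c(TRUE, FALSE, TRUE, FALSE, FALSE,
              FALSE, FALSE, FALSE, FALSE, FALSE)
  ef <- enrichment_factor(NULL, active, nu = c(0.5, 1))
  expect_equal(ef$ef[ef$nu == 0.5], 2.0)
  # ef(1) = 1 for any input
  expect_equal(ef$ef[ef$nu == 1], 1.0)
  for (seed in 1:5) {
    set.seed(seed)
    act <- rbinom(50, 1, 0.2) == 1
    if (!any(act)) next
    e1 <- enrichment_factor(rnorm(50), act, nu = 1)
    expect_equal(e1$ef, 1.0, tolerance = 1e-12)
    # bounded by 1/ap
    eall <- enrichment_factor(rnorm(50), act, nu = c(0.02, 0.1, 0.25))
    expect_true(all(eall$ef <= 1 / mean(act) + 1e-12))
    expect_true(all(eall$ef >= 0))
  }
  # all actives ranked first at nu = ap achieves the bound 1/ap
  act <- c(rep(TRUE, 2), rep(FALSE, 8))
  eb <- enrichment_factor(10:1, act, nu = 0.2)
  expect_equal(eb$ef, 5)
  expect_error(enrichment_factor(NULL, rep(FALSE, 3)), "no actives")
  expect_error(enrichment_factor(NULL, act, nu = 0), "nu")
})

test_that("training is deterministic and learns the planted signal", {
  st <- small_study()
  split <- study_split(st, kind = "uniprot", train_fraction = 0.7,
                       seed = 3)
  se <- study_examples(st, split)
  cfg <- parse_layer_config("l->l->r->l->r->l")
  tc <- training_config(epochs = 2, seed = 21)
  fit1 <- train_graphite(se$train, cfg, train_cfg = tc, channels = 16L,
                         n_basis = 8L, hidden = 32L)
  fit2 <- train_graphite(se$train, cfg, train_cfg = tc, channels = 16L,
                         n_basis = 8L, hidden = 32L)
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$params$layers, fit2$params$layers)
  # a few more epochs separate hits from misses on held-out targets
  fit <- train_graphite(se$train, cfg,
                        train_cfg = training_config(epochs = 10, seed = 21),
                        channels = 16L, n_basis = 8L, hidden = 32L)
  y <- vapply(se$test, function(e) e$label, "") == "hit"
  auc <- roc_auc(score_examples(se$test, fit), y)
  expect_gt(auc, 0.7)
})

test_that("single-class training sets are rejected", {
  st <- small_study()
  hits <- Filter(function(e) e$label == "hit", st$examples)
  expect_error(train_graphite(hits, parse_layer_config("l->r")),
               "at least one hit and one miss")
})

test_that("evaluate_model reports finite metrics and both rankings", {
  st <- small_study()
  split <- study_split(st, kind = "uniprot", train_fraction = 0.7, seed = 3)
  se <- study_examples(st, split)
  cfg <- parse_layer_config("l->l->r->l->r->l")
  fit <- train_graphite(se$train, cfg,
                        train_cfg = training_config(epochs = 3, seed = 2),
                        channels = 16L, n_basis = 8L, hidden = 32L)
  rep <- evaluate_model(se$test, fit)
  expect_true(is.finite(rep$roc_auc))
  expect_true(is.finite(rep$pr_auc))
  expect_equal(nrow(rep$topn_model), 16)
  expect_true(all(is.finite(rep$topn_model$fraction)))
  expect_true(all(diff(rep$topn_model$fraction) >= 0))
  # both curves describe the same pose sets at the endpoint
  expect_equal(rep$topn_model$fraction[16], rep$topn_docking$fraction[16])
})
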