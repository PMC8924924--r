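# Metrics ----------------------------------------------------------------------

#' ROC AUC (Mann-Whitney form, ties count one half)
#'
#' Probability that a uniformly random positive outranks a uniformly random
#' negative, computed exactly from midranks.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) stop("ROC AUC undefined: one class is empty")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' PR AUC as average precision
#'
#' Step integration of precision over recall (average precision): the mean,
#' over positives in score order, of the precision at each positive. Ties in
#' score are broken by stable input order, recorded so reports are
#' reproducible.
#'
#' @inheritParams roc_auc
#' @return average precision in [0, 1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  np <- sum(labels == 1)
  if (np == 0 || all(labels == 1)) stop("PR AUC undefined: one class is empty")
  o <- order(-scores)
  y <- labels[o]
  cum_pos <- cumsum(y)
  prec <- cum_pos / seq_along(y)
  sum(prec[y == 1]) / np
}

#' Top-n pose enrichment curve
#'
#' For each n up to \code{n_max}, the fraction of docking attempts whose
#' best pose among the n highest-ranked lies within the hit threshold.
#'
#' @param attempts list; each element is a data.frame with columns
#'   \code{rank} (the ranking under evaluation, 1 = best) and \code{rmsd}.
#' @param n_max largest n (default 16).
#' @param hit_threshold Angstrom (default 2.5).
#' @return object of class \code{enrichment_curve}: data.frame
#'   \code{(n, fraction)}.
#' @export
topn_pose_enrichment <- function(attempts, n_max = 16L, hit_threshold = 2.5) {
  if (length(attempts) == 0) stop("no attempts")
  first_hit <- vapply(attempts, function(a) {
    o <- order(a$rank)
    hits <- which(a$rmsd[o] <= hit_threshold)
    if (length(hits) == 0) Inf else min(hits)
  }, numeric(1))
  frac <- vapply(seq_len(n_max), function(n) mean(first_hit <= n),
                 numeric(1))
  out <- data.frame(n = seq_len(n_max), fraction = frac)
  class(out) <- c("enrichment_curve", class(out))
  out
}

#' Compound enrichment factor ef(nu)
#'
#' \deqn{ef(\nu) = (ap)^{-1} \, a(\nu) / n(\nu)} where \eqn{ap} is the
#' overall active fraction, \eqn{n(\nu) = \lceil \nu N \rceil} the size of
#' the top \eqn{\nu}-percentile and \eqn{a(\nu)} the number of actives in
#' it. Ties in score are broken by stable input order.
#'
#' @param scores compound scores, higher = better; or \code{NULL} if
#'   \code{active} is already in ranked order.
#' @param active logical actives flags.
#' @param nu percentile(s) in (0, 1].
#' @return data.frame \code{(nu, n, a, ef)}.
#' @export
enrichment_factor <- function(scores, active, nu = c(0.01, 0.05, 0.1, 0.5, 1)) {
  active <- as.logical(active)
  if (!any(active)) stop("no actives")
  if (any(nu <= 0 | nu > 1)) stop("nu must lie in (0, 1]")
  N <- length(active)
  ranked <- if (is.null(scores)) active else active[order(-scores)]
  ap <- mean(active)
  n_v <- pmin(N, ceiling(nu * N))
  a_v <- vapply(n_v, function(k) sum(ranked[seq_len(k)]), numeric(1))
  data.frame(nu = nu, n = n_v, a = a_v, ef = (a_v / n_v) / ap)
}

# Training ---------------------------------------------------------------------

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size examples per gradient step.
#' @param lr Adam learning rate.
#' @param imbalance \code{"balanced"} (per-epoch balanced sampling of hits
#'   and misses, default) or \code{"weighted"} (all examples, inverse-class
#'   weights).
#' @param val_fraction fraction of training targets held out, by target id.
#' @param seed RNG seed for sampling and initialisation.
#' @return list of class \code{training_config}.
#' @export
training_config <- function(epochs = 40L, batch_size = 32L, lr = 1e-3,
                            imbalance = c("balanced", "weighted"),
                            val_fraction = 0.1, seed = 1L) {
  imbalance <- match.arg(imbalance)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 imbalance = imbalance, val_fraction = val_fraction,
                 seed = as.integer(seed),
                 gap_policy = "drop_in_train_keep_in_test"),
            class = "training_config")
}

.adam_init <- function(params) {
  zero <- graphite_grad_zero(params)
  list(m = zero, v = rapply(zero, function(x) x * 0, how = "replace"),
       t = 0)
}

.adam_update <- function(params, grad, state, lr, b1 = 0.9, b2 = 0.999,
                         eps = 1e-8) {
  state$t <- state$t + 1
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd_block <- function(p, g, m, v) {
    for (nm in names(g)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      p[[nm]] <- p[[nm]] - lr * (m[[nm]] / corr1) /
        (sqrt(v[[nm]] / corr2) + eps)
    }
    list(p = p, m = m, v = v)
  }
  for (li in seq_along(grad$layers)) {
    r <- upd_block(params$layers[[li]], grad$layers[[li]],
                   state$m$layers[[li]], state$v$layers[[li]])
    params$layers[[li]] <- r$p
    state$m$layers[[li]] <- r$m
    state$v$layers[[li]] <- r$v
  }
  r <- upd_block(params$final, grad$final, state$m$final, state$v$final)
  params$final <- r$p; state$m$final <- r$m; state$v$final <- r$v
  list(params = params, state = state)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
.bce_loss <- function(logit, y) {
  # numerically stable softplus(logit) - y*logit
  pmax(logit, 0) - y * logit + log1p(exp(-abs(logit)))
}

#' Train the pose-scoring network on labeled complexes
#'
#' Binary cross-entropy on the ranking logit, hit = 1 vs miss = 0. Gap
#' poses are discarded from training (they stay in any test set the caller
#' holds). A fraction of training targets is held out by target id for
#' validation. The class imbalance is handled by per-epoch balanced
#' sampling of hits and misses (or inverse-class weighting). Deterministic
#' given the seed.
#'
#' @param examples list of \code{complex_example} with labels and
#'   \code{meta$target_id}.
#' @param config \code{layer_config}.
#' @param vocab \code{sybyl_vocabulary}.
#' @param train_cfg \code{training_config}.
#' @param params optional pre-initialised \code{graphite_params}.
#' @param channels,n_basis,hidden passed to \code{\link{graphite_params}}
#'   when \code{params} is NULL.
#' @param verbose print per-epoch progress.
#' @return list with \code{params}, \code{config}, \code{vocab},
#'   \code{history} (per-epoch loss and validation AUC), \code{val_auc}.
#' @export
train_graphite <- function(examples, config, vocab = sybyl_vocabulary(),
                           train_cfg = training_config(), params = NULL,
                           channels = 64L, n_basis = 16L, hidden = 128L,
                           verbose = FALSE) {
  labels <- vapply(examples, function(e) e$label, character(1))
  keep <- labels %in% c("hit", "miss")   # gap policy: drop from training
  ex <- examples[keep]
  y <- as.integer(labels[keep] == "hit")
  if (length(unique(y)) < 2)
    stop("training set needs at least one hit and one miss")
  tgt <- vapply(ex, function(e) {
    t <- e$meta$target_id
    if (is.null(t)) "target" else t
  }, character(1))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(train_cfg$seed)
  # held-out validation targets
  utgt <- unique(tgt)
  n_val <- max(0L, round(train_cfg$val_fraction * length(utgt)))
  val_tgt <- if (n_val > 0 && length(utgt) > 1)
    sample(utgt, min(n_val, length(utgt) - 1)) else character(0)
  is_val <- tgt %in% val_tgt
  if (all(is_val)) is_val[] <- FALSE
  if (length(unique(y[!is_val])) < 2)
    stop("training split lost a class; lower val_fraction")
  if (is.null(params))
    params <- graphite_params(config, vocab, channels = channels,
                              n_basis = n_basis, hidden = hidden,
                              seed = train_cfg$seed)
  if (verbose) message("featurizing ", length(ex), " examples ...")
  fxs <- lapply(ex, featurize_example, config = config, vocab = vocab,
                n_basis = params$n_basis)
  tr_idx <- which(!is_val)
  pos <- tr_idx[y[tr_idx] == 1]
  neg <- tr_idx[y[tr_idx] == 0]
  state <- .adam_init(params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_auc = numeric(0))
  w_pos <- if (train_cfg$imbalance == "weighted")
    length(tr_idx) / (2 * length(pos)) else 1
  w_neg <- if (train_cfg$imbalance == "weighted")
    length(tr_idx) / (2 * length(neg)) else 1
  for (ep in seq_len(train_cfg$epochs)) {
    if (train_cfg$imbalance == "balanced") {
      m <- min(length(pos), length(neg))
      epoch_idx <- c(pos[sample.int(length(pos), m)],
                     neg[sample.int(length(neg), m)])
    } else {
      epoch_idx <- tr_idx
    }
    epoch_idx <- epoch_idx[sample.int(length(epoch_idx))]
    batches <- split(epoch_idx,
                     ceiling(seq_along(epoch_idx) / train_cfg$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (b in batches) {
      grad <- graphite_grad_zero(params)
      bl <- 0
      for (i in b) {
        fwd <- graphite_forward(fxs[[i]], config, params,
                                keep_cache = TRUE)
        w <- if (y[i] == 1) w_pos else w_neg
        dlogit <- w * (.sigmoid(fwd$logit) - y[i]) / length(b)
        grad <- graphite_backward(fxs[[i]], config, params, fwd, dlogit,
                                  grad)
        bl <- bl + w * .bce_loss(fwd$logit, y[i])
      }
      upd <- .adam_update(params, grad, state, train_cfg$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + bl; ep_n <- ep_n + length(b)
    }
    val_auc <- NA_real_
    if (any(is_val) && length(unique(y[is_val])) == 2) {
      vs <- vapply(which(is_val), function(i)
        graphite_forward(fxs[[i]], config, params)$logit, numeric(1))
      val_auc <- roc_auc(vs, y[is_val])
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / ep_n,
                                   val_auc = val_auc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUC %s", ep,
                      ep_loss / ep_n,
                      ifelse(is.na(val_auc), "-", sprintf("%.3f", val_auc))))
  }
  list(params = params, config = config, vocab = vocab, history = hist,
       val_auc = hist$val_auc[nrow(hist)])
}

#' Score a list of complexes with a trained model
#'
#' @param examples list of \code{complex_example}.
#' @param model list with \code{params}, \code{config}, \code{vocab} (as
#'   returned by \code{\link{train_graphite}} or a loaded checkpoint).
#' @return numeric logits.
#' @export
score_examples <- function(examples, model) {
  vapply(examples, function(e) {
    fx <- featurize_example(e, model$config, model$vocab,
                            model$params$n_basis)
    graphite_forward(fx, model$config, model$params)$logit
  }, numeric(1))
}

#' Evaluate a trained model on labeled test complexes
#'
#' Computes hit-vs-rest ROC and PR AUC (gap poses are retained in the test
#' set as negatives, per the labeling policy), plus the top-n pose
#' enrichment curve for the model ranking and the docking ranking.
#'
#' @param examples list of labeled \code{complex_example} with
#'   \code{meta$attempt_id} and precomputed RMSD in \code{meta$rmsd}.
#' @param model model list (see \code{\link{score_examples}}).
#' @param n_max top-n curve length.
#' @return list with \code{roc_auc}, \code{pr_auc}, \code{topn_model},
#'   \code{topn_docking}, \code{scores} data.frame.
#' @export
evaluate_model <- function(examples, model, n_max = 16L) {
  logits <- score_examples(examples, model)
  lab <- vapply(examples, function(e) e$label, character(1))
  rmsd <- vapply(examples, function(e) {
    r <- e$meta$rmsd
    if (is.null(r)) NA_real_ else r
  }, numeric(1))
  att <- vapply(examples, function(e) {
    a <- e$meta$attempt_id
    if (is.null(a)) "attempt" else a
  }, character(1))
  drank <- vapply(examples, function(e) e$pose$rank, integer(1))
  df <- data.frame(attempt = att, docking_rank = drank, logit = logits,
                   label = lab, rmsd = rmsd)
  y <- as.integer(lab == "hit")
  res <- list(roc_auc = roc_auc(logits, y), pr_auc = pr_auc(logits, y))
  by_att <- split(df, df$attempt)
  mk_attempt <- function(a, use_logit) {
    r <- if (use_logit) rank(-a$logit, ties.method = "first") else
      rank(a$docking_rank, ties.method = "first")
    data.frame(rank = r, rmsd = a$rmsd)
  }
  res$topn_model <- topn_pose_enrichment(
    lapply(by_att, mk_attempt, use_logit = TRUE), n_max = n_max)
  res$topn_docking <- topn_pose_enrichment(
    lapply(by_att, mk_attempt, use_logit = FALSE), n_max = n_max)
  res$scores <- df
  res
}
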