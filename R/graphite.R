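# Directional message-passing network with Bessel continuous-filter kernels ---
#
# Feature streams: the embedding (one-hot SYBYL types) opens a stream for the
# initial atom set; every interaction layer appends a stream for its target
# set. A layer's source bottleneck projects the concatenation of all earlier
# streams of the *same* atom-set token; the skip path does the same for the
# target token. Readout pools ligand and receptor rows of every stream
# separately and a final MLP maps the concatenated embedding to the ranking
# logit.

.lrelu <- function(x, slope = 0.01) ifelse(x > 0, x, slope * x)
.lrelu_grad <- function(x, slope = 0.01) ifelse(x > 0, 1, slope)
.LN_EPS <- 1e-5

# Stream schedule: which streams exist, their tokens and widths, and the
# per-layer source/target stream indices. Depends only on config + vocab.
.graphite_schedule <- function(config, vocab_size, channels) {
  tok <- config$initial
  streams <- data.frame(token = tok, width = vocab_size,
                        stringsAsFactors = FALSE)
  layers <- list()
  for (li in seq_along(config$layers)) {
    lay <- config$layers[[li]]
    src_streams <- which(streams$token == lay$source)
    if (length(src_streams) == 0)
      stop("layer ", li, " has no feature stream for source set '",
           lay$source, "' (configuration cannot be wired)")
    tgt_streams <- which(streams$token == lay$target)
    layers[[li]] <- list(
      src_streams = src_streams, tgt_streams = tgt_streams,
      d_src = sum(streams$width[src_streams]),
      d_tgt = sum(streams$width[tgt_streams])
    )
    streams <- rbind(streams, data.frame(token = lay$target,
                                         width = channels))
  }
  # readout slots: every stream contributes its ligand and/or receptor pool
  lig_streams <- which(streams$token %in% c("l", "lr"))
  rec_streams <- which(streams$token %in% c("r", "lr"))
  z_dim <- sum(streams$width[lig_streams]) + sum(streams$width[rec_streams])
  if (z_dim == 0) stop("readout is empty: no stream touches any atom set")
  list(streams = streams, layers = layers,
       lig_streams = lig_streams, rec_streams = rec_streams, z_dim = z_dim)
}

.kaiming <- function(nr, nc, fan_in = nr) {
  s <- sqrt(6 / max(1, fan_in))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

#' Initialise network parameters for a layer configuration
#'
#' All learnable quantities of the network: per-layer Bessel kernel weights,
#' source/target bottleneck projections, post-convolution MLPs with layer
#' normalisation, and the final readout MLP. Initialisation is uniform
#' Kaiming-style fan-in scaling under the recorded seed, so parameter sets
#' are reproducible.
#'
#' @param config \code{layer_config}.
#' @param vocab \code{sybyl_vocabulary}.
#' @param channels feature width of every interaction layer (default 64).
#' @param n_basis Bessel basis functions per layer (default 16).
#' @param hidden hidden width of the final MLP (default 128).
#' @param pool \code{"sum"} (default; preserves pooling linearity) or
#'   \code{"mean"}.
#' @param seed RNG seed for the initialisation.
#' @return object of class \code{graphite_params}.
#' @export
graphite_params <- function(config, vocab, channels = 64L, n_basis = 16L,
                            hidden = 128L, pool = c("sum", "mean"),
                            seed = 1L) {
  pool <- match.arg(pool)
  sched <- .graphite_schedule(config, vocab$size, channels)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  layers <- lapply(seq_along(config$layers), function(li) {
    sl <- sched$layers[[li]]
    p <- list(
      Wk = .kaiming(n_basis, channels),
      Wsb = .kaiming(sl$d_src, channels), bsb = numeric(channels),
      W1 = .kaiming(channels, channels), b1 = numeric(channels),
      W2 = .kaiming(channels, channels), b2 = numeric(channels),
      gamma = rep(1, channels), beta = numeric(channels)
    )
    if (sl$d_tgt > 0) {
      p$Wtb <- .kaiming(sl$d_tgt, channels)
      p$btb <- numeric(channels)
    }
    p
  })
  final <- list(Wf1 = .kaiming(sched$z_dim, hidden), bf1 = numeric(hidden),
                Wf2 = .kaiming(hidden, 1), bf2 = 0)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(layers = layers, final = final,
                 channels = as.integer(channels),
                 n_basis = as.integer(n_basis),
                 hidden = as.integer(hidden), pool = pool, seed = seed,
                 schedule = sched, vocab_size = vocab$size),
            class = "graphite_params")
}

#' Featurize a complex for the network
#'
#' Precomputes everything the forward pass needs that does not depend on the
#' parameters: one-hot features, per-layer directed edges, Bessel basis
#' values and local index maps. Caching this makes repeated forward/backward
#' sweeps (training epochs) cheap.
#'
#' @param example \code{complex_example}.
#' @param config \code{layer_config}.
#' @param vocab \code{sybyl_vocabulary}.
#' @param n_basis Bessel basis size (must match the parameters used later).
#' @return object of class \code{graphite_input}.
#' @export
featurize_example <- function(example, config, vocab, n_basis = 16L) {
  cc <- complex_coords(example)
  nb <- build_neighborhoods(example, config)
  sets <- list(l = which(cc$entity == "ligand"),
               r = which(cc$entity == "receptor"),
               lr = seq_along(cc$entity))
  atoms <- data.frame(sybyl_type = cc$sybyl_type, entity = cc$entity,
                      element = cc$element, stringsAsFactors = FALSE)
  X <- encode_onehot(atoms, vocab, unknown = "other")
  layers <- lapply(seq_along(config$layers), function(li) {
    lay <- config$layers[[li]]
    e <- nb$edges[[li]]
    list(
      n_src = length(sets[[lay$source]]),
      n_tgt = length(sets[[lay$target]]),
      src_local = match(e$source, sets[[lay$source]]),
      tgt_local = match(e$target, sets[[lay$target]]),
      dist = e$dist,
      basis = bessel_basis(lay$cutoff, n_basis)
    )
  })
  # per-token ligand/receptor row masks for pooling
  n_l <- length(sets$l)
  rows <- list(l = list(lig = seq_len(n_l), rec = integer(0)),
               r = list(lig = integer(0),
                        rec = seq_along(sets$r)),
               lr = list(lig = seq_len(n_l),
                         rec = n_l + seq_along(sets$r)))
  structure(list(X = X, sets = sets, layers = layers, rows = rows,
                 n_atoms = length(cc$entity)),
            class = "graphite_input")
}

.concat_streams <- function(streams, idx) {
  if (length(idx) == 1) streams[[idx]] else do.call(cbind, streams[idx])
}

.add_bias <- function(m, b) sweep(m, 2, b, "+")

#' Forward pass: ranking logit for one featurized complex
#'
#' @param fx \code{graphite_input} from \code{\link{featurize_example}}.
#' @param config \code{layer_config} (the one used to featurize).
#' @param params \code{graphite_params}.
#' @param keep_cache keep intermediate activations for
#'   \code{\link{graphite_backward}}.
#' @return list with \code{logit} (scalar) and, if requested, \code{cache}.
#' @export
graphite_forward <- function(fx, config, params, keep_cache = FALSE) {
  sched <- params$schedule
  tok <- sched$streams$token
  C <- params$channels
  streams <- vector("list", nrow(sched$streams))
  streams[[1]] <- fx$X[fx$sets[[config$initial]], , drop = FALSE]
  cache <- if (keep_cache) vector("list", length(config$layers)) else NULL
  for (li in seq_along(config$layers)) {
    sl <- sched$layers[[li]]
    lp <- params$layers[[li]]
    lf <- fx$layers[[li]]
    H_src <- .concat_streams(streams, sl$src_streams)
    h <- .add_bias(H_src %*% lp$Wsb, lp$bsb)
    nE <- length(lf$src_local)
    agg <- matrix(0, lf$n_tgt, C)
    Fk <- NULL; M <- NULL; B <- NULL
    if (nE > 0) {
      B <- bessel_basis_values(lf$dist, lf$basis)
      Fk <- B %*% lp$Wk
      M <- Fk * h[lf$src_local, , drop = FALSE]
      rs <- rowsum(M, lf$tgt_local)
      agg[as.integer(rownames(rs)), ] <- rs
    }
    if (sl$d_tgt > 0) {
      H_tgt <- .concat_streams(streams, sl$tgt_streams)
      pre <- agg + .add_bias(H_tgt %*% lp$Wtb, lp$btb)
    } else {
      H_tgt <- NULL
      pre <- agg
    }
    a1 <- .add_bias(pre %*% lp$W1, lp$b1)
    r1 <- .lrelu(a1)
    a2 <- .add_bias(r1 %*% lp$W2, lp$b2)
    mu <- rowMeans(a2)
    v <- rowMeans((a2 - mu)^2)
    inv_sd <- 1 / sqrt(v + .LN_EPS)
    xhat <- (a2 - mu) * inv_sd
    out <- .add_bias(sweep(xhat, 2, lp$gamma, "*"), lp$beta)
    streams[[li + 1]] <- out
    if (keep_cache)
      cache[[li]] <- list(H_src = H_src, h = h, Fk = Fk, B = B,
                          H_tgt = H_tgt, pre = pre, a1 = a1, r1 = r1,
                          xhat = xhat, inv_sd = inv_sd)
  }
  # readout
  pool_fun <- function(mat, rows) {
    if (length(rows) == 0) return(numeric(ncol(mat)))
    p <- colSums(mat[rows, , drop = FALSE])
    if (params$pool == "mean") p <- p / length(rows)
    p
  }
  zL <- unlist(lapply(sched$lig_streams, function(si)
    pool_fun(streams[[si]], fx$rows[[tok[si]]]$lig)))
  zR <- unlist(lapply(sched$rec_streams, function(si)
    pool_fun(streams[[si]], fx$rows[[tok[si]]]$rec)))
  z <- c(zL, zR)
  zf1 <- as.numeric(z %*% params$final$Wf1) + params$final$bf1
  rf <- .lrelu(zf1)
  logit <- sum(rf * params$final$Wf2) + params$final$bf2
  res <- list(logit = logit)
  if (keep_cache)
    res$cache <- list(streams = streams, layer = cache, z = z, zf1 = zf1,
                      rf = rf)
  res
}

# Zero-filled gradient container with the same shapes as params.
graphite_grad_zero <- function(params) {
  zl <- lapply(params$layers, function(lp) lapply(lp, function(w) w * 0))
  zf <- lapply(params$final, function(w) w * 0)
  list(layers = zl, final = zf)
}

#' Backward pass: parameter gradients for one example
#'
#' Analytic reverse-mode differentiation of \code{\link{graphite_forward}}
#' with respect to every learnable parameter, for an upstream gradient
#' \code{dlogit} (e.g. from a binary cross-entropy loss on the logit).
#' Gradients are accumulated into \code{grad} in place-like fashion
#' (the updated container is returned).
#'
#' @param fx \code{graphite_input}.
#' @param config \code{layer_config}.
#' @param params \code{graphite_params}.
#' @param fwd result of \code{graphite_forward(..., keep_cache = TRUE)}.
#' @param dlogit upstream scalar gradient.
#' @param grad gradient container from \code{graphite_grad_zero} (or a
#'   previous call) to accumulate into.
#' @return the updated gradient container.
#' @export
graphite_backward <- function(fx, config, params, fwd, dlogit = 1,
                              grad = graphite_grad_zero(params)) {
  sched <- params$schedule
  tok <- sched$streams$token
  C <- params$channels
  cache <- fwd$cache
  streams <- cache$streams
  # final MLP
  g <- dlogit
  grad$final$Wf2 <- grad$final$Wf2 + matrix(cache$rf * g, ncol = 1)
  grad$final$bf2 <- grad$final$bf2 + g
  drf <- as.numeric(params$final$Wf2) * g
  dzf1 <- drf * .lrelu_grad(cache$zf1)
  grad$final$Wf1 <- grad$final$Wf1 + outer(cache$z, dzf1)
  grad$final$bf1 <- grad$final$bf1 + dzf1
  dz <- as.numeric(params$final$Wf1 %*% dzf1)
  # scatter readout gradient into stream gradients
  dstreams <- lapply(streams, function(s) s * 0)
  off <- 0
  scatter_pool <- function(si, rows) {
    w <- ncol(streams[[si]])
    seg <- dz[off + seq_len(w)]
    off <<- off + w
    if (length(rows) > 0) {
      add <- matrix(seg, length(rows), w, byrow = TRUE)
      if (params$pool == "mean") add <- add / length(rows)
      dstreams[[si]][rows, ] <<- dstreams[[si]][rows, , drop = FALSE] + add
    }
  }
  for (si in sched$lig_streams) scatter_pool(si, fx$rows[[tok[si]]]$lig)
  for (si in sched$rec_streams) scatter_pool(si, fx$rows[[tok[si]]]$rec)
  # layers in reverse
  for (li in rev(seq_along(config$layers))) {
    sl <- sched$layers[[li]]
    lp <- params$layers[[li]]
    lf <- fx$layers[[li]]
    lc <- cache$layer[[li]]
    dout <- dstreams[[li + 1]]
    # LayerNorm
    grad$layers[[li]]$gamma <- grad$layers[[li]]$gamma +
      colSums(dout * lc$xhat)
    grad$layers[[li]]$beta <- grad$layers[[li]]$beta + colSums(dout)
    dxhat <- sweep(dout, 2, lp$gamma, "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * lc$xhat)
    da2 <- lc$inv_sd * (dxhat - m1 - lc$xhat * m2)
    # second linear
    grad$layers[[li]]$W2 <- grad$layers[[li]]$W2 + t(lc$r1) %*% da2
    grad$layers[[li]]$b2 <- grad$layers[[li]]$b2 + colSums(da2)
    dr1 <- da2 %*% t(lp$W2)
    da1 <- dr1 * .lrelu_grad(lc$a1)
    grad$layers[[li]]$W1 <- grad$layers[[li]]$W1 + t(lc$pre) %*% da1
    grad$layers[[li]]$b1 <- grad$layers[[li]]$b1 + colSums(da1)
    dpre <- da1 %*% t(lp$W1)
    # skip path
    if (sl$d_tgt > 0) {
      grad$layers[[li]]$Wtb <- grad$layers[[li]]$Wtb + t(lc$H_tgt) %*% dpre
      grad$layers[[li]]$btb <- grad$layers[[li]]$btb + colSums(dpre)
      dH_tgt <- dpre %*% t(lp$Wtb)
      coff <- 0
      for (si in sl$tgt_streams) {
        w <- ncol(streams[[si]])
        dstreams[[si]] <- dstreams[[si]] +
          dH_tgt[, coff + seq_len(w), drop = FALSE]
        coff <- coff + w
      }
    }
    # convolution path
    nE <- length(lf$src_local)
    dh <- matrix(0, lf$n_src, C)
    if (nE > 0) {
      dM <- dpre[lf$tgt_local, , drop = FALSE]
      dF <- dM * lc$h[lf$src_local, , drop = FALSE]
      grad$layers[[li]]$Wk <- grad$layers[[li]]$Wk + t(lc$B) %*% dF
      dh_e <- dM * lc$Fk
      rs <- rowsum(dh_e, lf$src_local)
      dh[as.integer(rownames(rs)), ] <- dh[as.integer(rownames(rs)), ,
                                           drop = FALSE] + rs
    }
    grad$layers[[li]]$Wsb <- grad$layers[[li]]$Wsb + t(lc$H_src) %*% dh
    grad$layers[[li]]$bsb <- grad$layers[[li]]$bsb + colSums(dh)
    dH_src <- dh %*% t(lp$Wsb)
    coff <- 0
    for (si in sl$src_streams) {
      w <- ncol(streams[[si]])
      dstreams[[si]] <- dstreams[[si]] +
        dH_src[, coff + seq_len(w), drop = FALSE]
      coff <- coff + w
    }
  }
  grad
}

#' Score one complex example
#'
#' @param example \code{complex_example}.
#' @param config \code{layer_config}.
#' @param params \code{graphite_params}.
#' @param vocab \code{sybyl_vocabulary}.
#' @return scalar ranking logit (higher = better pose).
#' @export
graphite_logit <- function(example, config, params,
                           vocab = sybyl_vocabulary()) {
  fx <- featurize_example(example, config, vocab, params$n_basis)
  graphite_forward(fx, config, params)$logit
}

#' Rescore the poses of one docking attempt
#'
#' Poses are re-ranked by descending logit; ties fall back on the original
#' docking rank (stable).
#'
#' @param examples list of \code{complex_example}, all poses of one attempt.
#' @param config \code{layer_config}.
#' @param params \code{graphite_params}.
#' @param vocab \code{sybyl_vocabulary}.
#' @return data.frame \code{(pose, docking_rank, logit, anpr_rank)} sorted
#'   by the new rank.
#' @export
rescore_attempt <- function(examples, config, params,
                            vocab = sybyl_vocabulary()) {
  if (length(examples) == 0) stop("empty pose list")
  logit <- vapply(examples, function(ex) {
    fx <- featurize_example(ex, config, vocab, params$n_basis)
    graphite_forward(fx, config, params)$logit
  }, numeric(1))
  drank <- vapply(examples, function(ex) ex$pose$rank, integer(1))
  o <- order(-logit, drank)
  data.frame(pose = o, docking_rank = drank[o], logit = logit[o],
             anpr_rank = seq_along(o))
}

# Checkpoints ------------------------------------------------------------------

#' Save a model checkpoint
#'
#' Serialises \code{{config, vocabulary, params, seed, version}} so that a
#' reload reproduces scores bit-exactly.
#'
#' @param path file path.
#' @param config \code{layer_config}.
#' @param params \code{graphite_params}.
#' @param vocab \code{sybyl_vocabulary}.
#' @param extra optional list stored alongside (e.g. training history).
#' @return \code{path}, invisibly.
#' @export
save_checkpoint <- function(path, config, params, vocab, extra = list()) {
  obj <- list(config = config, vocab = vocab, params = params,
              seed = params$seed,
              version = as.character(utils::packageVersion("poserank")),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by \code{\link{save_checkpoint}}.
#' @return list with \code{config}, \code{vocab}, \code{params},
#'   \code{seed}, \code{version}, \code{extra}.
#' @export
load_checkpoint <- function(path) readRDS(path)
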