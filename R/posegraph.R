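# Layer routing and directed neighborhoods ------------------------------------

#' Parse a layer-routing string into a layer configuration
#'
#' A routing string such as \code{"l->l->r->l->r->l"} (UTF-8 arrows also
#' accepted) lists the atom set visited at each step: \code{l} ligand atoms,
#' \code{r} receptor atoms, \code{lr} their union. A string of k+1 tokens
#' yields k message-passing layers; layer \eqn{\ell} passes messages from
#' set token \eqn{\ell} (sources) to set token \eqn{\ell+1} (targets), so
#' the sources of each layer are by construction the targets of the
#' previous one.
#'
#' @param spec routing string.
#' @param cutoffs radial cutoff(s) in Angstrom: one value per layer, a
#'   single value recycled, or \code{NULL} for the defaults (4.0 within an
#'   entity, 5.0 across entities).
#' @return object of class \code{layer_config} with fields \code{initial}
#'   (token of the embedding set) and \code{layers} (list of
#'   \code{list(source, target, cutoff)}).
#' @export
parse_layer_config <- function(spec, cutoffs = NULL) {
  if (!is.character(spec) || length(spec) != 1 || !nzchar(trimws(spec)))
    stop("empty layer spec")
  s <- gsub("→", "->", spec)
  tokens <- trimws(strsplit(s, "->", fixed = TRUE)[[1]])
  if (!all(tokens %in% c("l", "r", "lr")))
    stop("unknown token(s) in layer spec: ",
         paste(setdiff(tokens, c("l", "r", "lr")), collapse = ", "))
  k <- length(tokens) - 1
  if (is.null(cutoffs)) {
    cutoffs <- vapply(seq_len(k), function(i) {
      cross <- tokens[i] != tokens[i + 1] || tokens[i] == "lr"
      if (cross) 5.0 else 4.0
    }, numeric(1))
  } else {
    if (length(cutoffs) == 1) cutoffs <- rep(cutoffs, k)
    if (length(cutoffs) != k)
      stop("need ", k, " cutoffs, got ", length(cutoffs))
  }
  if (k > 0 && any(cutoffs <= 0)) stop("cutoffs must be positive")
  layers <- lapply(seq_len(k), function(i)
    list(source = tokens[i], target = tokens[i + 1], cutoff = cutoffs[i]))
  structure(list(initial = tokens[1], layers = layers, spec = s),
            class = "layer_config")
}

#' @export
print.layer_config <- function(x, ...) {
  cat("layer_config:", x$spec, "\n")
  for (i in seq_along(x$layers))
    cat(sprintf("  layer %d: %s -> %s, Rc = %.2f A\n", i,
                x$layers[[i]]$source, x$layers[[i]]$target,
                x$layers[[i]]$cutoff))
  invisible(x)
}

.set_indices <- function(entity, token) {
  switch(token,
         l = which(entity == "ligand"),
         r = which(entity == "receptor"),
         lr = seq_along(entity))
}

#' Build per-layer directed edge sets for a complex
#'
#' For each layer, every ordered pair (source atom j, target atom i) with
#' \eqn{d_{ij} < R_c} and the required set memberships receives a directed
#' edge. Self-edges are excluded. Edges are sorted by target then source
#' index, so the result is deterministic.
#'
#' @param example \code{complex_example} (or any list with an
#'   \code{atoms()}-style coordinate layout; see \code{\link{complex_coords}}).
#' @param config \code{layer_config}.
#' @return object of class \code{directed_neighborhood}: a list with one
#'   element per layer, each a data.frame \code{(source, target, dist)} in
#'   global atom indices (ligand atoms first, then receptor atoms).
#' @export
build_neighborhoods <- function(example, config) {
  cc <- complex_coords(example)
  xyz <- cc$xyz
  edges <- vector("list", length(config$layers))
  for (li in seq_along(config$layers)) {
    lay <- config$layers[[li]]
    src <- .set_indices(cc$entity, lay$source)
    tgt <- .set_indices(cc$entity, lay$target)
    if (length(src) == 0 || length(tgt) == 0) {
      edges[[li]] <- data.frame(source = integer(0), target = integer(0),
                                dist = numeric(0))
      next
    }
    # pairwise distances source x target
    d2 <- outer(rowSums(xyz[src, , drop = FALSE]^2),
                rowSums(xyz[tgt, , drop = FALSE]^2), "+") -
      2 * xyz[src, , drop = FALSE] %*% t(xyz[tgt, , drop = FALSE])
    d2[d2 < 0] <- 0
    hit <- which(sqrt(d2) < lay$cutoff, arr.ind = TRUE)
    s <- src[hit[, 1]]; t <- tgt[hit[, 2]]
    keep <- s != t
    s <- s[keep]; t <- t[keep]
    d <- sqrt(d2[hit][keep])
    o <- order(t, s)
    edges[[li]] <- data.frame(source = s[o], target = t[o], dist = d[o])
  }
  structure(list(edges = edges, n_atoms = nrow(xyz), entity = cc$entity),
            class = "directed_neighborhood")
}

#' Stack ligand and receptor atoms of a complex into one coordinate table
#'
#' Ligand atoms come first (in topology order, at the pose coordinates),
#' then receptor atoms.
#'
#' @param example \code{complex_example}.
#' @return list with \code{xyz} (n x 3), \code{entity}, \code{sybyl_type},
#'   \code{element}.
#' @export
complex_coords <- function(example) {
  lig <- example$ligand$atoms
  rec <- example$receptor$atoms
  xyz <- rbind(example$pose$coords,
               as.matrix(rec[, c("x", "y", "z")]))
  dimnames(xyz) <- NULL
  list(xyz = xyz,
       entity = c(rep("ligand", nrow(lig)), rep("receptor", nrow(rec))),
       sybyl_type = c(lig$sybyl_type, rec$sybyl_type),
       element = c(lig$element, rec$element))
}
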