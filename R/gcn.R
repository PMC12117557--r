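#' Encoder configuration
#'
#' Hyperparameters of a graph encoder. \code{encoder} must name an entry of
#' the encoder registry ("gcn" and "schnet" are built in; see
#' \code{\link{register_encoder}}).
#'
#' @param encoder encoder name.
#' @param hidden hidden width (the embedding length).
#' @param layers number of propagation layers (GCN) or interaction blocks
#'   (SchNet).
#' @param readout graph readout, "mean" or "sum" (defaults: mean for gcn,
#'   sum for schnet).
#' @param activation GCN nonlinearity, "relu" or "identity" (the latter is
#'   useful for analytic checks).
#' @param cutoff radius-neighbor cutoff in Angstrom (SchNet).
#' @param n_rbf number of Gaussian radial basis functions on [0, cutoff]
#'   (SchNet); centers are uniformly spaced and the Gaussian width equals the
#'   spacing.
#' @param dropout dropout rate inside the encoder (in [0, 1); default 0 — the
#'   classification head has its own dropout).
#' @return object of class \code{vs_encoder_config}.
#' @export
encoder_config <- function(encoder = "gcn", hidden = 128L, layers = 3L,
                           readout = c("mean", "sum"),
                           activation = c("relu", "identity"),
                           cutoff = 10, n_rbf = 50L, dropout = 0) {
  if (missing(readout)) readout <- if (encoder == "schnet") "sum" else "mean"
  readout <- match.arg(readout)
  activation <- match.arg(activation)
  stopifnot(hidden >= 1, layers >= 1, cutoff > 0, n_rbf >= 2,
            dropout >= 0, dropout < 1)
  get_encoder(encoder)  # fails early on unknown names
  structure(list(encoder = encoder, hidden = as.integer(hidden),
                 layers = as.integer(layers), readout = readout,
                 activation = activation, cutoff = cutoff,
                 n_rbf = as.integer(n_rbf), dropout = dropout),
            class = "vs_encoder_config")
}

## ---- encoder registry -----------------------------------------------------

.encoder_registry <- new.env(parent = emptyenv())

#' Register a graph encoder
#'
#' The registry maps an encoder name to its implementation so additional
#' architectures (e.g. spherical message passing models) can be added without
#' changes to the training core. An implementation is a list of functions:
#' \code{prep(graphs, cfg)} building a stacked representation of a graph
#' list, \code{assemble(stack, idx)} slicing a mini-batch out of it,
#' \code{init(cfg, d_node, n_elements)} returning a named parameter list,
#' \code{forward(batch, params, cfg, training)} returning
#' \code{list(h, cache)} with \code{h} a graphs x hidden matrix, and
#' \code{backward(dh, cache, params, cfg)} returning a gradient list. Set
#' \code{needs_coords = TRUE} for geometric encoders.
#'
#' @param name encoder name.
#' @param impl implementation list (see Details).
#' @export
register_encoder <- function(name, impl) {
  stopifnot(is.character(name), length(name) == 1L,
            all(c("init", "prep", "assemble", "forward", "backward") %in%
                  names(impl)))
  assign(name, impl, envir = .encoder_registry)
  invisible(name)
}

get_encoder <- function(name) {
  if (!exists(name, envir = .encoder_registry, inherits = FALSE)) {
    stop("unknown encoder '", name, "'; registered: ",
         paste(ls(.encoder_registry), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .encoder_registry, inherits = FALSE)
}

## ---- stacked batching -----------------------------------------------------

# Stack node features and (global-indexed) edge arrays of a graph list once;
# mini-batches are then sliced with vectorized index arithmetic. Edge arrays
# here are the GCN normalized-adjacency triplets (self-loops included).
gcn_prep <- function(graphs, cfg) {
  n_each <- vapply(graphs, function(g) g$n_atoms, integer(1))
  off <- c(0L, cumsum(n_each))
  e_counts <- vapply(graphs, function(g) length(g$adj_i), integer(1))
  eoff <- c(0L, cumsum(e_counts))
  list(
    X = do.call(rbind, lapply(graphs, function(g) g$x)),
    n_each = n_each, off = off, e_counts = e_counts, eoff = eoff,
    src = unlist(lapply(seq_along(graphs),
                        function(k) graphs[[k]]$adj_i + off[k])),
    tgt = unlist(lapply(seq_along(graphs),
                        function(k) graphs[[k]]$adj_j + off[k])),
    w = unlist(lapply(graphs, function(g) g$adj_w)),
    y = vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  )
}

# slice batch idx (graph positions) out of a stack; local node numbering
slice_stack <- function(stack, idx) {
  n_b <- stack$n_each[idx]
  loc_off <- c(0L, cumsum(n_b))
  nidx <- sequence(n_b, from = stack$off[idx] + 1L)
  e_b <- stack$e_counts[idx]
  eidx <- sequence(e_b, from = stack$eoff[idx] + 1L)
  shift <- (loc_off[-length(loc_off)] - stack$off[idx])  # per graph in batch
  eshift <- rep(shift, e_b)
  list(nidx = nidx, eidx = eidx,
       src = stack$src[eidx] + eshift, tgt = stack$tgt[eidx] + eshift,
       gid = rep(seq_along(idx), n_b), n_each = n_b,
       N = sum(n_b), y = stack$y[idx])
}

gcn_assemble <- function(stack, idx) {
  sl <- slice_stack(stack, idx)
  list(X = stack$X[sl$nidx, , drop = FALSE], src = sl$src, tgt = sl$tgt,
       w = stack$w[sl$eidx], gid = sl$gid, n_each = sl$n_each, N = sl$N,
       y = sl$y)
}

## ---- GCN ------------------------------------------------------------------

gcn_init <- function(cfg, d_node, n_elements) {
  params <- list()
  d_prev <- d_node
  for (l in seq_len(cfg$layers)) {
    params[[paste0("gcn.W", l)]] <- init_mat(d_prev, cfg$hidden)
    params[[paste0("gcn.b", l)]] <- numeric(cfg$hidden)
    d_prev <- cfg$hidden
  }
  params
}

# Per layer: add self-loops, aggregate neighbor features with
# 1/sqrt(deg_i deg_j) weights (degrees counted with self-loops), linear
# transform, nonlinearity. Aggregation is a gather/scatter-add, equivalent to
# multiplying by the symmetric-normalized adjacency.
gcn_forward <- function(batch, params, cfg, training = FALSE) {
  H <- batch$X
  cache <- list(S = list(), H = list())
  use_relu <- cfg$activation == "relu"
  for (l in seq_len(cfg$layers)) {
    S <- .gcn_scatter(H, batch$src, batch$tgt, batch$w, batch$N)
    H <- if (use_relu) {
      .bias_relu(S %*% params[[paste0("gcn.W", l)]],
                 params[[paste0("gcn.b", l)]])
    } else {
      addvec(S %*% params[[paste0("gcn.W", l)]], params[[paste0("gcn.b", l)]])
    }
    cache$S[[l]] <- S
    cache$H[[l]] <- H
  }
  hm <- rowsum(H, batch$gid)
  if (cfg$readout == "mean") hm <- hm / batch$n_each
  cache$batch <- batch
  list(h = hm, cache = cache)
}

gcn_backward <- function(dh, cache, params, cfg) {
  batch <- cache$batch
  grads <- list()
  dread <- if (cfg$readout == "mean") dh / batch$n_each else dh
  dH <- dread[batch$gid, , drop = FALSE]
  for (l in rev(seq_len(cfg$layers))) {
    # ReLU mask from the activations (H > 0 iff pre-activation > 0)
    dP <- if (cfg$activation == "relu") dH * (cache$H[[l]] > 0) else dH
    grads[[paste0("gcn.W", l)]] <- crossprod(cache$S[[l]], dP)
    grads[[paste0("gcn.b", l)]] <- colSums(dP)
    dS <- tcrossprod(dP, params[[paste0("gcn.W", l)]])
    # the normalized adjacency is symmetric, so its transpose reuses the op
    dH <- .gcn_scatter(dS, batch$src, batch$tgt, batch$w, batch$N)
  }
  grads
}

#' Encode one molecular graph with the GCN
#'
#' Runs the symmetric-normalized graph convolution stack on a single
#' featurized graph and returns the graph embedding under the configured
#' readout. Mainly a convenience for inspection and testing; training uses
#' the batched path internally.
#'
#' @param g a \code{vs_graph}.
#' @param params named parameter list (\code{gcn.W1}, \code{gcn.b1}, ...), as
#'   produced by the registry's \code{init}; any conforming matrices work.
#' @param cfg a \code{vs_encoder_config} with \code{encoder = "gcn"}.
#' @return numeric vector of length \code{cfg$hidden}.
#' @export
gcn_encode <- function(g, params, cfg) {
  stack <- gcn_prep(list(g), cfg)
  drop(gcn_forward(gcn_assemble(stack, 1L), params, cfg)$h)
}
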