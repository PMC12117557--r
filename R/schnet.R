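# SchNet-style continuous-filter convolution encoder on 3D coordinates.
# Element identity -> learned embedding; per interaction block the
# inter-atomic distance, expanded in a Gaussian radial basis, is mapped by a
# filter-generating network to per-channel weights; the continuous-filter
# convolution sums neighbor states (after an atom-wise linear map) elementwise
# multiplied by those filters; shifted-softplus nonlinearities and a residual
# update follow. Readout is a sum over atoms.

# Gaussian radial basis on [0, cutoff]: uniformly spaced centers, width equal
# to the spacing.
rbf_expand <- function(d, cutoff, n_rbf) {
  centers <- seq(0, cutoff, length.out = n_rbf)
  width <- centers[2] - centers[1]
  exp(-(outer(d, centers, "-"))^2 / (2 * width^2))
}

# Radius edges + RBF features for one graph, cached on the graph object.
prep_schnet_graph <- function(g, cfg) {
  if (is.null(g$coords))
    stop("encoder 'schnet' requires 3D coordinates, which graph '", g$id,
         "' does not carry", call. = FALSE)
  key <- sprintf("%g_%d", cfg$cutoff, cfg$n_rbf)
  if (identical(g$schnet_key, key)) return(g)
  re <- build_radius_edges(g$coords, cfg$cutoff)
  g$r_src <- re$edge_index[1, ]
  g$r_tgt <- re$edge_index[2, ]
  g$rbf <- rbf_expand(re$dist, cfg$cutoff, cfg$n_rbf)
  g$schnet_key <- key
  g
}

schnet_prep <- function(graphs, cfg) {
  graphs <- lapply(graphs, prep_schnet_graph, cfg = cfg)
  n_each <- vapply(graphs, function(g) g$n_atoms, integer(1))
  off <- c(0L, cumsum(n_each))
  e_counts <- vapply(graphs, function(g) length(g$r_src), integer(1))
  eoff <- c(0L, cumsum(e_counts))
  list(
    elem = unlist(lapply(graphs, function(g) g$element_idx)),
    n_each = n_each, off = off, e_counts = e_counts, eoff = eoff,
    src = unlist(lapply(seq_along(graphs),
                        function(k) graphs[[k]]$r_src + off[k])),
    tgt = unlist(lapply(seq_along(graphs),
                        function(k) graphs[[k]]$r_tgt + off[k])),
    rbf = do.call(rbind, lapply(graphs, function(g) g$rbf)),
    y = vapply(graphs, function(g) as.numeric(g$label), numeric(1))
  )
}

schnet_assemble <- function(stack, idx) {
  sl <- slice_stack(stack, idx)
  list(elem = stack$elem[sl$nidx], src = sl$src, tgt = sl$tgt,
       rbf = stack$rbf[sl$eidx, , drop = FALSE], gid = sl$gid,
       n_each = sl$n_each, N = sl$N, y = sl$y)
}

schnet_init <- function(cfg, d_node, n_elements) {
  params <- list(schnet.emb = init_mat(n_elements, cfg$hidden))
  C <- cfg$hidden
  for (t in seq_len(cfg$layers)) {
    p <- paste0("schnet.b", t, ".")
    params[[paste0(p, "Win")]] <- init_mat(C, C)
    params[[paste0(p, "Wf1")]] <- init_mat(cfg$n_rbf, C)
    params[[paste0(p, "bf1")]] <- numeric(C)
    params[[paste0(p, "Wf2")]] <- init_mat(C, C)
    params[[paste0(p, "bf2")]] <- numeric(C)
    params[[paste0(p, "W1")]] <- init_mat(C, C)
    params[[paste0(p, "b1")]] <- numeric(C)
    params[[paste0(p, "W2")]] <- init_mat(C, C)
    params[[paste0(p, "b2")]] <- numeric(C)
  }
  params
}

# scatter-add of edge messages onto target nodes
scatter_rows <- function(M, idx, N) {
  out <- matrix(0, N, ncol(M))
  if (length(idx)) {
    s <- rowsum(M, idx)
    out[as.integer(rownames(s)), ] <- s
  }
  out
}

schnet_forward <- function(batch, params, cfg, training = FALSE) {
  H <- params[["schnet.emb"]][batch$elem, , drop = FALSE]
  cache <- list(H = list(H), blocks = list())
  for (t in seq_len(cfg$layers)) {
    p <- paste0("schnet.b", t, ".")
    A <- H %*% params[[paste0(p, "Win")]]
    F1p <- addvec(batch$rbf %*% params[[paste0(p, "Wf1")]],
                  params[[paste0(p, "bf1")]])
    F1 <- ssp(F1p)
    F2p <- addvec(F1 %*% params[[paste0(p, "Wf2")]],
                  params[[paste0(p, "bf2")]])
    Fg <- ssp(F2p)
    Msg <- A[batch$src, , drop = FALSE] * Fg
    M <- scatter_rows(Msg, batch$tgt, batch$N)
    U1p <- addvec(M %*% params[[paste0(p, "W1")]], params[[paste0(p, "b1")]])
    U1 <- ssp(U1p)
    U2 <- addvec(U1 %*% params[[paste0(p, "W2")]], params[[paste0(p, "b2")]])
    H <- H + U2
    cache$blocks[[t]] <- list(A = A, F1p = F1p, F1 = F1, F2p = F2p, Fg = Fg,
                              M = M, U1p = U1p, U1 = U1)
    cache$H[[t + 1]] <- H
  }
  h <- rowsum(H, batch$gid)
  if (cfg$readout == "mean") h <- h / batch$n_each
  cache$batch <- batch
  list(h = h, cache = cache)
}

schnet_backward <- function(dh, cache, params, cfg) {
  batch <- cache$batch
  grads <- list()
  dread <- if (cfg$readout == "mean") dh / batch$n_each else dh
  dH <- dread[batch$gid, , drop = FALSE]
  for (t in rev(seq_len(cfg$layers))) {
    p <- paste0("schnet.b", t, ".")
    bl <- cache$blocks[[t]]
    dU2 <- dH  # residual: dH flows to both H_{t-1} and the block output
    grads[[paste0(p, "W2")]] <- crossprod(bl$U1, dU2)
    grads[[paste0(p, "b2")]] <- colSums(dU2)
    dU1 <- tcrossprod(dU2, params[[paste0(p, "W2")]])
    dU1p <- dU1 * ssp_grad(bl$U1p)
    grads[[paste0(p, "W1")]] <- crossprod(bl$M, dU1p)
    grads[[paste0(p, "b1")]] <- colSums(dU1p)
    dM <- tcrossprod(dU1p, params[[paste0(p, "W1")]])
    dMsg <- dM[batch$tgt, , drop = FALSE]
    dFg <- dMsg * bl$A[batch$src, , drop = FALSE]
    dA <- scatter_rows(dMsg * bl$Fg, batch$src, batch$N)
    dF2p <- dFg * ssp_grad(bl$F2p)
    grads[[paste0(p, "Wf2")]] <- crossprod(bl$F1, dF2p)
    grads[[paste0(p, "bf2")]] <- colSums(dF2p)
    dF1 <- tcrossprod(dF2p, params[[paste0(p, "Wf2")]])
    dF1p <- dF1 * ssp_grad(bl$F1p)
    grads[[paste0(p, "Wf1")]] <- crossprod(batch$rbf, dF1p)
    grads[[paste0(p, "bf1")]] <- colSums(dF1p)
    grads[[paste0(p, "Win")]] <- crossprod(cache$H[[t]], dA)
    dH <- dH + tcrossprod(dA, params[[paste0(p, "Win")]])
  }
  grads[["schnet.emb"]] <- rowsum(dH, batch$elem)
  # rowsum drops absent element rows; re-expand to the full table
  full <- params[["schnet.emb"]] * 0
  full[as.integer(rownames(grads[["schnet.emb"]])), ] <- grads[["schnet.emb"]]
  grads[["schnet.emb"]] <- full
  grads
}

#' Encode one molecular graph with the SchNet-style encoder
#'
#' Requires 3D coordinates on the graph. The embedding is invariant under
#' rigid rotations and translations of the coordinates because only
#' inter-atomic distances enter the computation.
#'
#' @param g a \code{vs_graph} with coordinates.
#' @param params named parameter list as produced by the registry's
#'   \code{init} for "schnet".
#' @param cfg a \code{vs_encoder_config} with \code{encoder = "schnet"}.
#' @return numeric vector of length \code{cfg$hidden}.
#' @export
schnet_encode <- function(g, params, cfg) {
  stack <- schnet_prep(list(g), cfg)
  drop(schnet_forward(schnet_assemble(stack, 1L), params, cfg)$h)
}

# built-in registry entries
register_encoder("gcn", list(
  init = gcn_init, prep = gcn_prep, assemble = gcn_assemble,
  forward = gcn_forward, backward = gcn_backward, needs_coords = FALSE
))
register_encoder("schnet", list(
  init = schnet_init, prep = schnet_prep, assemble = schnet_assemble,
  forward = schnet_forward, backward = schnet_backward, needs_coords = TRUE
))
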