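# Shared fixtures, all built in code at test time.

# Load a labelled molecule set from SMILES strings.
mols_from_smiles <- function(smiles, labels = rep(0L, length(smiles)),
                             ids = sprintf("m%03d", seq_along(smiles))) {
  f <- tempfile(fileext = ".smi")
  on.exit(unlink(f))
  writeLines(paste(smiles, ids, labels), f)
  load_molecules(f, "smiles")
}

one_mol <- function(smiles) mols_from_smiles(smiles)$molecules[[1]]

# Memoized synthetic data sets (generation shells out to OpenBabel, so reuse
# across test files).
.fixture_cache <- new.env(parent = emptyenv())
fixture_synth <- function(n = 300, active_fraction = 0.05, seed = 7, ...) {
  key <- paste(n, active_fraction, seed, deparse(list(...)), collapse = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_dataset(
      synth_config(n = n, active_fraction = active_fraction, seed = seed, ...))
  }
  .fixture_cache[[key]]
}

# Random small featurized graph with a given number of nodes (a random tree
# plus extra edges), for encoder oracle checks.
random_graph <- function(n_nodes, d_node = 7) {
  n_nodes <- as.integer(n_nodes)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n_nodes > 1) {
    parent <- vapply(2:n_nodes, function(k) sample.int(k - 1L, 1), integer(1))
    bonds <- data.frame(i = parent, j = 2:n_nodes, order = 1L)
  }
  deg <- tabulate(c(bonds$i, bonds$j), n_nodes)
  ai <- c(bonds$i, bonds$j, seq_len(n_nodes))
  aj <- c(bonds$j, bonds$i, seq_len(n_nodes))
  dt <- deg + 1
  structure(list(
    x = matrix(rnorm(n_nodes * d_node), n_nodes, d_node),
    edge_index = rbind(c(bonds$i, bonds$j), c(bonds$j, bonds$i)),
    n_atoms = n_nodes, label = 0L, id = "rg",
    element_idx = rep(1L, n_nodes),
    adj_i = ai, adj_j = aj, adj_w = 1 / sqrt(dt[ai] * dt[aj])
  ), class = "vs_graph")
}

# Independent fine Riemann-sum oracle for the ranged logAUC: its own
# threshold-sweep ROC and a midpoint rule on a very fine log grid.
logauc_oracle <- function(scores, labels, lo = 0.001, hi = 0.1, K = 2e5) {
  thr <- sort(unique(scores), decreasing = TRUE)
  fpr <- vapply(thr, function(t) mean(scores[labels == 0] >= t), numeric(1))
  tpr <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  if (max(fpr) < 1) { fpr <- c(fpr, 1); tpr <- c(tpr, 1) }
  u <- seq(log10(lo), log10(hi), length.out = K + 1)
  mid <- 10^((u[-1] + u[-(K + 1)]) / 2)
  tm <- stats::approx(fpr, tpr, xout = mid, ties = max, rule = 2)$y
  sum(tm) * (u[2] - u[1]) / (log10(hi) - log10(lo))
}

# Dense-matrix GCN propagation oracle: D^{-1/2} (A + I) D^{-1/2} X W layer by
# layer, straight from the definition.
gcn_dense_oracle <- function(g, params, cfg) {
  n <- g$n_atoms
  A <- matrix(0, n, n)
  if (ncol(g$edge_index) > 0) {
    A[t(g$edge_index)] <- 1
  }
  At <- A + diag(n)
  Dm <- diag(1 / sqrt(rowSums(At)), n)
  An <- Dm %*% At %*% Dm
  H <- g$x
  for (l in seq_len(cfg$layers)) {
    P <- An %*% H %*% params[[paste0("gcn.W", l)]]
    P <- sweep(P, 2, params[[paste0("gcn.b", l)]], "+")
    H <- if (cfg$activation == "relu") pmax(P, 0) else P
  }
  if (cfg$readout == "mean") colMeans(H) else colSums(H)
}
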