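#' Feature scheme for graph featurization
#'
#' Declares which node and edge features are computed and over which
#' vocabularies, so an alternative scheme can be dropped in. Node features:
#' element one-hot over the allowed set, heavy-atom degree one-hot (0-5),
#' formal charge one-hot (clipped to [-2, 2]), aromaticity flag,
#' ring-membership flag, attached-hydrogen-count one-hot (0-4, clipped).
#' Edge features: bond-order one-hot \{single, double, triple, aromatic\}
#' plus a ring flag. Graphs are heavy-atom by default (hydrogens implicit via
#' the H-count feature); set \code{explicit_h = TRUE} to keep explicit
#' hydrogen atoms from the input.
#'
#' @param elements element vocabulary (order fixes the one-hot layout).
#' @param node_features,edge_features feature names to include.
#' @param explicit_h keep explicit hydrogens as graph nodes.
#' @return object of class \code{vs_feature_scheme}.
#' @export
feature_scheme <- function(elements = c("H", "C", "N", "O", "S", "P",
                                        "F", "Cl", "Br", "I"),
                           node_features = c("element", "degree", "charge",
                                             "aromatic", "ring", "h_count"),
                           edge_features = c("bond_order", "ring"),
                           explicit_h = FALSE) {
  known_node <- c("element", "degree", "charge", "aromatic", "ring", "h_count")
  known_edge <- c("bond_order", "ring")
  bad <- setdiff(node_features, known_node)
  if (length(bad)) stop("unknown node feature name(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(edge_features, known_edge)
  if (length(bad)) stop("unknown edge feature name(s): ", paste(bad, collapse = ", "))
  dims <- c(element = length(elements), degree = 6L, charge = 5L,
            aromatic = 1L, ring = 1L, h_count = 5L)
  edims <- c(bond_order = 4L, ring = 1L)
  structure(list(elements = elements, node_features = node_features,
                 edge_features = edge_features, explicit_h = explicit_h,
                 d_node = sum(dims[node_features]),
                 d_edge = sum(edims[edge_features])),
            class = "vs_feature_scheme")
}

#' Featurize one molecule as numeric graph input
#'
#' Every undirected bond yields both directed edges. Output is deterministic
#' for identical input, and featurizing a relabelled molecule yields the
#' corresponding row/edge permutation.
#'
#' @param mol a \code{vs_molecule}.
#' @param scheme a \code{vs_feature_scheme}.
#' @return object of class \code{vs_graph}: \code{x} (n x d_node),
#'   \code{edge_index} (2 x 2E directed), \code{edge_attr} (2E x d_edge),
#'   \code{coords} (n x 3 or NULL), \code{element_idx}, \code{label},
#'   and precomputed symmetric-normalized self-loop adjacency triplets
#'   (\code{adj_i}, \code{adj_j}, \code{adj_w}) for GCN propagation.
#' @export
featurize_graph <- function(mol, scheme = feature_scheme()) {
  a <- mol$atoms; b <- mol$bonds
  if (!scheme$explicit_h && any(a$symbol == "H")) {
    keep <- which(a$symbol != "H")
    if (!length(keep)) stop("molecule ", mol$id, " has no heavy atoms")
    remap <- match(seq_len(nrow(a)), keep)
    h_idx <- which(a$symbol == "H")
    for (h in h_idx) {
      nb <- c(b$j[b$i == h], b$i[b$j == h])
      nb <- nb[a$symbol[nb] != "H"]
      if (length(nb)) a$n_h[nb[1]] <- a$n_h[nb[1]] + 1L
    }
    b <- b[a$symbol[b$i] != "H" & a$symbol[b$j] != "H", , drop = FALSE]
    b$i <- remap[b$i]; b$j <- remap[b$j]
    a <- a[keep, , drop = FALSE]
  }
  n <- nrow(a)
  deg <- integer(n)
  if (nrow(b)) {
    tb <- table(factor(c(b$i, b$j), levels = seq_len(n)))
    deg <- as.integer(tb)
  }
  one_hot <- function(idx, k) {
    m <- matrix(0, length(idx), k)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  blocks <- list()
  for (f in scheme$node_features) {
    blocks[[f]] <- switch(f,
      element = {
        ei <- match(a$symbol, scheme$elements)
        if (anyNA(ei)) stop("element outside scheme vocabulary: ",
                            paste(unique(a$symbol[is.na(ei)]), collapse = ", "))
        one_hot(ei, length(scheme$elements))
      },
      degree = one_hot(pmin(deg, 5L) + 1L, 6L),
      charge = one_hot(pmax(pmin(a$charge, 2L), -2L) + 3L, 5L),
      aromatic = matrix(as.numeric(a$aromatic), n, 1),
      ring = matrix(as.numeric(a$in_ring), n, 1),
      h_count = one_hot(pmin(a$n_h, 4L) + 1L, 5L)
    )
  }
  x <- do.call(cbind, blocks)

  if (nrow(b)) {
    src <- c(b$i, b$j); tgt <- c(b$j, b$i)
    ord <- ifelse(rep(b$aromatic, 2), 4L, rep(pmin(b$order, 3L), 2))
    eblocks <- list()
    for (f in scheme$edge_features) {
      eblocks[[f]] <- switch(f,
        bond_order = one_hot(ord, 4L),
        ring = matrix(as.numeric(rep(b$in_ring, 2)), length(src), 1)
      )
    }
    edge_attr <- do.call(cbind, eblocks)
    edge_index <- rbind(src, tgt)
  } else {
    edge_index <- matrix(integer(0), 2, 0)
    edge_attr <- matrix(0, 0, scheme$d_edge)
  }

  # symmetric-normalized adjacency with self-loops (degrees counted with them)
  dt <- deg + 1
  ai <- c(edge_index[1, ], seq_len(n))
  aj <- c(edge_index[2, ], seq_len(n))
  aw <- 1 / sqrt(dt[ai] * dt[aj])

  coords <- if (mol$has_coords) {
    unname(as.matrix(a[, c("x", "y", "z")]))
  } else NULL
  structure(list(
    x = x, edge_index = edge_index, edge_attr = edge_attr,
    coords = coords, label = mol$activity, id = mol$id,
    element_idx = match(a$symbol, scheme$elements),
    n_atoms = n, adj_i = ai, adj_j = aj, adj_w = aw
  ), class = "vs_graph")
}

#' Featurize every molecule of a set
#' @param ms a \code{vs_molecule_set}.
#' @param scheme a \code{vs_feature_scheme}.
#' @return list of \code{vs_graph}.
#' @export
featurize_set <- function(ms, scheme = feature_scheme()) {
  lapply(ms$molecules, featurize_graph, scheme = scheme)
}

#' Radius neighbor graph from 3D coordinates
#'
#' Includes the directed edge (i, j), i != j, iff the Euclidean distance
#' between atoms i and j is at most \code{cutoff}; (j, i) is always included
#' with (i, j).
#'
#' @param coords numeric matrix n x 3 (Angstrom).
#' @param cutoff neighbor cutoff in Angstrom (> 0).
#' @return list with \code{edge_index} (2 x E directed) and \code{dist}
#'   (length E).
#' @export
build_radius_edges <- function(coords, cutoff) {
  stopifnot(is.matrix(coords), ncol(coords) == 3, cutoff > 0)
  if (any(!is.finite(coords))) stop("non-finite coordinate in radius graph input")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  sel <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  src <- c(sel[, 1], sel[, 2]); tgt <- c(sel[, 2], sel[, 1])
  list(edge_index = rbind(src, tgt), dist = c(d[sel], d[sel]))
}
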