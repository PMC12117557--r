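#' Random train/test split
#'
#' Uniformly random permutation under the seed; the first
#' \code{floor(frac * N)} molecules go to training. Deterministic per seed.
#'
#' @param ms a \code{vs_molecule_set} (>= 2 molecules).
#' @param frac train fraction in (0, 1).
#' @param seed integer seed.
#' @return object of class \code{vs_split}: \code{train} and \code{test} id
#'   vectors, \code{kind}, \code{seed}, \code{frac}; attribute
#'   \code{"test_single_class"} flags a test side missing a class.
#' @export
random_split <- function(ms, frac = 0.8, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  ids <- molecule_ids(ms)
  N <- length(ids)
  if (N < 2L) stop("need at least 2 molecules to split")
  n_train <- floor(frac * N)
  if (n_train < 1L || n_train >= N) stop("split leaves an empty side")
  perm <- with_preserved_rng(seed, sample.int(N))
  make_split(ids[perm[seq_len(n_train)]], ids[perm[(n_train + 1L):N]],
             "random", seed, frac, ms)
}

make_split <- function(train, test, kind, seed, frac, ms) {
  y <- activities(ms)
  names(y) <- molecule_ids(ms)
  flag <- length(unique(y[test])) < 2L
  structure(list(train = train, test = test, kind = kind,
                 seed = as.integer(seed), frac = frac),
            test_single_class = flag, class = "vs_split")
}

#' @export
print.vs_split <- function(x, ...) {
  cat(sprintf("<vs_split %s: %d train / %d test (seed %d)>\n",
              x$kind, length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Bemis-Murcko scaffold keys for a molecule set
#'
#' The scaffold is obtained by iteratively removing all non-ring atoms that
#' are not on a path between rings (i.e. repeatedly pruning terminal atoms),
#' leaving ring systems plus their linkers with atom types and bond orders
#' retained. The key is the canonical SMILES of that framework; acyclic
#' molecules map to the reserved key \code{""}.
#'
#' @param ms a \code{vs_molecule_set}.
#' @return character vector of scaffold keys, one per molecule.
#' @export
scaffold_keys <- function(ms) {
  frames <- lapply(ms$molecules, scaffold_subgraph)
  has_ring <- !vapply(frames, is.null, logical(1))
  keys <- character(length(frames))
  if (any(has_ring)) {
    blocks <- vapply(which(has_ring), function(k) {
      f <- frames[[k]]
      mol <- list(id = sprintf("S%06d", k), atoms = f$atoms, bonds = f$bonds,
                  has_coords = FALSE)
      paste0(write_molblock_raw(mol, f$arom_bonds), "\n$$$$")
    }, character(1))
    can <- ob_canonical(paste(blocks, collapse = "\n"), from = "sdf")
    got <- can[sprintf("S%06d", which(has_ring))]
    if (anyNA(got))
      stop("scaffold canonicalization failed for ",
           sum(is.na(got)), " molecule(s)")
    keys[has_ring] <- unname(got)
  }
  keys
}

#' Bemis-Murcko scaffold key of one molecule
#' @param mol a \code{vs_molecule}.
#' @return scaffold key string ("" for acyclic molecules).
#' @export
murcko_scaffold_key <- function(mol) {
  scaffold_keys(molecule_set(list(mol), name = "single"))
}

# Iteratively prune terminal (degree <= 1) atoms; ring atoms are never
# terminal, and linker atoms lie on paths between rings (degree >= 2), so the
# fixed point is the ring-systems-plus-linkers framework. NULL when acyclic.
scaffold_subgraph <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  if (!any(a$in_ring)) return(NULL)
  keep <- rep(TRUE, nrow(a))
  repeat {
    deg <- integer(nrow(a))
    sel <- keep[b$i] & keep[b$j]
    if (any(sel)) {
      tb <- table(factor(c(b$i[sel], b$j[sel]), levels = seq_len(nrow(a))))
      deg <- as.integer(tb)
    }
    prune <- keep & deg <= 1L & !a$in_ring
    if (!any(prune)) break
    keep[prune] <- FALSE
  }
  remap <- match(seq_len(nrow(a)), which(keep))
  bsel <- b[keep[b$i] & keep[b$j], , drop = FALSE]
  arom <- bsel[bsel$aromatic, c("i", "j"), drop = FALSE]
  bsel$i <- remap[bsel$i]; bsel$j <- remap[bsel$j]
  arom_bonds <- if (nrow(arom)) cbind(remap[arom$i], remap[arom$j]) else NULL
  atoms <- a[keep, c("symbol", "charge"), drop = FALSE]
  atoms$x <- atoms$y <- atoms$z <- 0
  list(atoms = atoms, bonds = bsel, arom_bonds = arom_bonds)
}

#' Scaffold-based train/test split
#'
#' Molecules are grouped by scaffold key and groups are assigned whole to one
#' side, so no scaffold straddles the train/test boundary. Groups are taken
#' in descending size order (equal-size runs shuffled under the seed) and
#' assigned to training until it holds at least \code{floor(frac * N)}
#' molecules; the remaining groups form the test side, which is thereby
#' enriched for rare chemotypes. All acyclic molecules share the reserved
#' \code{""} scaffold group by default; set \code{acyclic_singletons = TRUE}
#' to give each its own group.
#'
#' @param ms a \code{vs_molecule_set}.
#' @param frac train fraction in (0, 1).
#' @param seed integer seed (governs the equal-size tie shuffle).
#' @param keys optional precomputed scaffold keys (from
#'   \code{\link{scaffold_keys}}).
#' @param acyclic_singletons treat each acyclic molecule as its own group.
#' @return a \code{vs_split} (kind "scaffold").
#' @export
scaffold_split <- function(ms, frac = 0.8, seed = 1L, keys = NULL,
                           acyclic_singletons = FALSE) {
  stopifnot(frac > 0, frac < 1)
  ids <- molecule_ids(ms)
  N <- length(ids)
  if (N < 2L) stop("need at least 2 molecules to split")
  if (is.null(keys)) keys <- scaffold_keys(ms)
  if (acyclic_singletons) {
    acy <- keys == ""
    keys[acy] <- paste0("acyclic:", ids[acy])
  }
  groups <- split(ids, keys)
  if (length(groups) < 2L)
    stop("only one scaffold group; scaffold split impossible")
  sizes <- lengths(groups)
  ord <- order(-sizes, names(groups))          # size desc, ties by key string
  ord <- with_preserved_rng(seed, {
    # shuffle within equal-size runs so repeated splits differ
    unlist(lapply(split(ord, sizes[ord]),
                  function(v) v[sample.int(length(v))]), use.names = FALSE)
  })
  ord <- ord[order(-sizes[ord])]
  target <- floor(frac * N)
  cum <- cumsum(sizes[ord])
  n_train_groups <- which(cum >= target)[1]
  if (n_train_groups >= length(groups))
    stop("scaffold split leaves an empty test side")
  train <- unlist(groups[ord[seq_len(n_train_groups)]], use.names = FALSE)
  test <- unlist(groups[ord[(n_train_groups + 1L):length(groups)]],
                 use.names = FALSE)
  make_split(train, test, "scaffold", seed, frac, ms)
}

#' Write / read a split as a two-column CSV for exact reuse across models
#' @param split a \code{vs_split}.
#' @param path CSV path.
#' @export
write_split <- function(split, path) {
  df <- data.frame(id = c(split$train, split$test),
                   side = c(rep("train", length(split$train)),
                            rep("test", length(split$test))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(train = df$id[df$side == "train"],
                 test = df$id[df$side == "test"],
                 kind = "file", seed = NA_integer_, frac = NA_real_),
            class = "vs_split")
}
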