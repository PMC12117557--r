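#' Built-in molecular descriptor set
#'
#' A compact expert-crafted, molecule-level descriptor vector computable for
#' any valid molecule: heavy-atom count, molecular weight, ring count
#' (circuit rank), aromatic ring count, aromatic atom count, hydrogen-bond
#' donor and acceptor counts, rotatable bond count, topological polar surface
#' area, logP estimate, molar refractivity, formal charge sum, fraction of
#' sp3 carbons, and per-element atom counts over the allowed set (hydrogens
#' counted including implicit ones). Fragment-based quantities (MW, logP,
#' TPSA, HBD, HBA, MR, rotatable bonds) are computed by OpenBabel; the rest
#' from the molecular graph. All values are invariant to atom ordering and
#' (being 2D) to coordinates. This set stands in for externally computed
#' descriptor tables, which can be supplied via
#' \code{\link{load_descriptor_table}} instead.
#'
#' @param elements element vocabulary for the per-element counts.
#' @return character vector of descriptor names.
#' @export
builtin_descriptor_names <- function(elements = c("H", "C", "N", "O", "S", "P",
                                                  "F", "Cl", "Br", "I")) {
  c("heavy_atoms", "mw", "ring_count", "aromatic_ring_count",
    "aromatic_atom_count", "hbd", "hba", "rotors", "tpsa", "logp", "mr",
    "formal_charge_sum", "fraction_csp3", paste0("n_", elements))
}

#' Compute built-in descriptors for every molecule of a set
#'
#' @param ms a \code{vs_molecule_set}.
#' @param elements element vocabulary for the per-element counts.
#' @return numeric matrix, one row per molecule (rownames = ids), columns
#'   \code{\link{builtin_descriptor_names}}.
#' @export
molecule_descriptors <- function(ms, elements = c("H", "C", "N", "O", "S", "P",
                                                  "F", "Cl", "Br", "I")) {
  ids <- molecule_ids(ms)
  props <- ob_properties(write_sdf_text(ms), from = "sdf")
  pi <- match(ids, props$id)
  if (anyNA(pi)) stop("OpenBabel property computation failed for: ",
                      paste(ids[is.na(pi)], collapse = ", "))
  props <- props[pi, ]

  graph_part <- t(vapply(ms$molecules, function(m) {
    a <- m$atoms; b <- m$bonds
    heavy <- sum(a$symbol != "H")
    comp <- if (nrow(b)) {
      g <- igraph::graph_from_edgelist(cbind(b$i, b$j), directed = FALSE)
      if (igraph::vcount(g) < nrow(a))
        g <- igraph::add_vertices(g, nrow(a) - igraph::vcount(g))
      igraph::count_components(g)
    } else nrow(a)
    ring_count <- nrow(b) - nrow(a) + comp
    ar_b <- b[b$aromatic, , drop = FALSE]
    ar_ring <- if (nrow(ar_b)) {
      verts <- unique(c(ar_b$i, ar_b$j))
      ga <- igraph::graph_from_edgelist(
        cbind(match(ar_b$i, verts), match(ar_b$j, verts)), directed = FALSE)
      nrow(ar_b) - length(verts) + igraph::count_components(ga)
    } else 0
    is_c <- a$symbol == "C"
    multi <- unique(c(b$i[b$order > 1L | b$aromatic], b$j[b$order > 1L | b$aromatic]))
    csp3 <- sum(is_c & !(seq_len(nrow(a)) %in% multi))
    frac_sp3 <- if (any(is_c)) csp3 / sum(is_c) else 0
    elem_counts <- vapply(elements, function(e) sum(a$symbol == e), numeric(1))
    if ("H" %in% elements) elem_counts["H"] <- elem_counts["H"] + sum(a$n_h)
    c(heavy, ring_count, ar_ring, sum(a$aromatic), sum(a$charge), frac_sp3,
      elem_counts)
  }, numeric(6 + length(elements))))

  out <- cbind(
    heavy_atoms = graph_part[, 1],
    mw = props$mw,
    ring_count = graph_part[, 2],
    aromatic_ring_count = graph_part[, 3],
    aromatic_atom_count = graph_part[, 4],
    hbd = props$hbd, hba = props$hba, rotors = props$rotors,
    tpsa = props$tpsa, logp = props$logp, mr = props$mr,
    formal_charge_sum = graph_part[, 5],
    fraction_csp3 = graph_part[, 6],
    graph_part[, 7:(6 + length(elements)), drop = FALSE]
  )
  colnames(out) <- builtin_descriptor_names(elements)
  rownames(out) <- ids
  out
}

#' Compute the built-in descriptor vector for a single molecule
#' @param mol a \code{vs_molecule}.
#' @param elements element vocabulary for the per-element counts.
#' @return named numeric vector.
#' @export
compute_builtin_descriptors <- function(mol, elements = c("H", "C", "N", "O",
                                                          "S", "P", "F", "Cl",
                                                          "Br", "I")) {
  ms <- molecule_set(list(mol), name = "single")
  drop(molecule_descriptors(ms, elements))
}

#' Load an externally computed descriptor table
#'
#' Reads a CSV whose first column \code{id} matches the molecule ids of
#' \code{ms} and whose remaining columns are numeric features (e.g. a
#' 391-column expert-descriptor export). Every molecule must be matched
#' exactly once. Missing values are imputed by per-feature means over the
#' training rows (never label-aware); the imputation count is recorded in the
#' \code{"imputed"} attribute.
#'
#' @param path CSV path (header row required, first column \code{id}).
#' @param ms a \code{vs_molecule_set}.
#' @param train_ids ids whose rows define the imputation means (default: all).
#' @return numeric matrix, rows ordered as \code{ms}.
#' @export
load_descriptor_table <- function(path, ms, train_ids = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "id") stop("descriptor CSV must have 'id' as its first column")
  ids <- molecule_ids(ms)
  if (anyDuplicated(tab$id))
    stop("duplicate descriptor rows for id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  ri <- match(ids, tab$id)
  if (anyNA(ri))
    stop("descriptor table missing row(s) for molecule id(s): ",
         paste(ids[is.na(ri)], collapse = ", "))
  m <- as.matrix(tab[ri, -1, drop = FALSE])
  if (!is.numeric(m)) stop("descriptor columns must be numeric")
  rownames(m) <- ids
  n_imp <- 0L
  if (anyNA(m)) {
    tr <- if (is.null(train_ids)) seq_len(nrow(m)) else match(train_ids, ids)
    mu <- colMeans(m[tr, , drop = FALSE], na.rm = TRUE)
    for (jc in which(colSums(is.na(m)) > 0)) {
      nas <- is.na(m[, jc])
      m[nas, jc] <- mu[jc]
      n_imp <- n_imp + sum(nas)
    }
  }
  attr(m, "imputed") <- n_imp
  m
}

#' Fit a z-score descriptor scaler on training rows and apply it
#'
#' Location and scale (population standard deviation) are estimated on the
#' training rows only; features with zero training variance are flagged and
#' mapped to 0. The transform is affine and invertible on retained features,
#' and values outside the training range pass through unclipped.
#'
#' @param train numeric matrix of training descriptor rows (>= 2 rows).
#' @param x numeric matrix to transform (defaults to \code{train}).
#' @return list with \code{scaled} (transformed \code{x}) and \code{scaler}
#'   (list \code{mean}, \code{sd}, \code{constant}).
#' @export
fit_apply_scaler <- function(train, x = train) {
  if (nrow(train) < 2L) stop("need at least 2 training rows to fit the scaler")
  mu <- colMeans(train)
  sd0 <- sqrt(colMeans(sweep(train, 2, mu)^2))  # population sd (ddof = 0)
  constant <- sd0 <= 1e-12
  scaler <- list(mean = mu, sd = ifelse(constant, 1, sd0), constant = constant)
  list(scaled = apply_scaler(scaler, x), scaler = scaler)
}

#' Apply a fitted descriptor scaler
#' @param scaler scaler from \code{\link{fit_apply_scaler}}.
#' @param x numeric matrix with the same columns as the training matrix.
#' @export
apply_scaler <- function(scaler, x) {
  if (ncol(x) != length(scaler$mean))
    stop("descriptor width ", ncol(x), " does not match the fitted scaler (",
         length(scaler$mean), ")")
  z <- sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
  z[, scaler$constant] <- 0
  z
}
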