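#' Molecule and MoleculeSet containers
#'
#' A \code{Molecule} is the unit of screening: a labelled molecular graph with
#' optional 3D coordinates. Atoms carry element symbol, formal charge,
#' perceived aromaticity/ring membership and an implicit hydrogen count; bonds
#' carry a (kekulized) order in \{1, 2, 3\} plus aromatic and ring flags.
#'
#' @param id character scalar; unique, whitespace-free identifier.
#' @param atoms data.frame with columns \code{symbol} (character),
#'   \code{charge} (integer formal charge) and optionally \code{x, y, z}
#'   (Angstrom coordinates; either all atoms have them or none do).
#' @param bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices) and \code{order} (1, 2 or 3; aromatic rings are kekulized and
#'   flagged via \code{aromatic}).
#' @param activity binary activity label (0/1).
#' @param aromatic_bonds optional integer matrix (columns i, j) of bonds to be
#'   flagged aromatic (from perception); row order need not match \code{bonds}.
#' @param canonical_key canonical structure string used for deduplication; may
#'   be \code{NA} and filled in later by batch canonicalization.
#' @return object of class \code{vs_molecule}.
#' @export
molecule <- function(id, atoms, bonds, activity,
                     aromatic_bonds = NULL, canonical_key = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (grepl("[ \t]", id)) stop("molecule id must not contain whitespace: ", id)
  n <- nrow(atoms)
  if (n < 1L) stop("molecule ", id, " has no atoms")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$symbol <- as.character(atoms$symbol)
  atoms$charge <- as.integer(atoms$charge)
  has_xyz <- all(c("x", "y", "z") %in% names(atoms)) &&
    !all(is.na(atoms$x)) && any(abs(c(atoms$x, atoms$y, atoms$z)) > 1e-12)
  if (!has_xyz) atoms$x <- atoms$y <- atoms$z <- NA_real_
  if (has_xyz && anyNA(c(atoms$x, atoms$y, atoms$z)))
    stop("molecule ", id, ": if any atom has coordinates, all must")

  if (nrow(bonds)) {
    bonds$i <- as.integer(bonds$i); bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(bonds$i == bonds$j)) stop("molecule ", id, ": self-bond")
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("molecule ", id, ": bond endpoint out of range")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("molecule ", id, ": duplicate bond")
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }

  percep <- perceive_graph(n, bonds, aromatic_bonds)
  atoms$aromatic <- percep$atom_aromatic
  atoms$in_ring <- percep$atom_in_ring
  bonds$aromatic <- percep$bond_aromatic
  bonds$in_ring <- percep$bond_in_ring
  atoms$n_h <- implicit_hydrogens(atoms, bonds)

  structure(list(
    id = id, atoms = atoms, bonds = bonds,
    activity = as.integer(activity),
    canonical_key = canonical_key,
    has_coords = has_xyz
  ), class = "vs_molecule")
}

# Ring membership from igraph bridge analysis; aromatic flags from a perceived
# aromatic-bond list (MOL2 route) when supplied.
perceive_graph <- function(n, bonds, aromatic_bonds) {
  atom_in_ring <- logical(n)
  bond_in_ring <- logical(nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    br <- igraph::bridges(g)
    bond_in_ring <- !(seq_len(nrow(bonds)) %in% as.integer(br))
    ring_atoms <- unique(c(bonds$i[bond_in_ring], bonds$j[bond_in_ring]))
    atom_in_ring[ring_atoms] <- TRUE
  }
  bond_aromatic <- logical(nrow(bonds))
  atom_aromatic <- logical(n)
  if (!is.null(aromatic_bonds) && nrow(aromatic_bonds)) {
    ak <- paste(pmin(aromatic_bonds[, 1], aromatic_bonds[, 2]),
                pmax(aromatic_bonds[, 1], aromatic_bonds[, 2]))
    bk <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    bond_aromatic <- bk %in% ak
    atom_aromatic[unique(c(bonds$i[bond_aromatic], bonds$j[bond_aromatic]))] <- TRUE
  }
  list(atom_in_ring = atom_in_ring, bond_in_ring = bond_in_ring,
       atom_aromatic = atom_aromatic, bond_aromatic = bond_aromatic)
}

# Standard-valence implicit hydrogen model over kekulized bond orders.
# Charge adjustment: +1 charge adds a bonding site for N/O/S, -1 removes one.
default_valences <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

implicit_hydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  deg_order <- numeric(n)
  if (nrow(bonds)) {
    s <- rowsum(c(bonds$order, bonds$order), c(bonds$i, bonds$j))
    deg_order[as.integer(rownames(s))] <- s[, 1]
  }
  val <- default_valences[atoms$symbol]
  val[is.na(val)] <- 0
  # hypervalent S/P: raise to the next standard valence when bonds exceed it
  for (alt in list(c("S", 4), c("S", 6), c("P", 5))) {
    sel <- atoms$symbol == alt[1] & deg_order > val
    val[sel] <- pmax(val[sel], as.numeric(alt[2]))
  }
  adj <- ifelse(atoms$symbol %in% c("N", "O", "S", "P"), atoms$charge,
                ifelse(atoms$symbol == "C", -abs(atoms$charge), 0))
  pmax(0, round(val + adj - deg_order))
}

#' @export
print.vs_molecule <- function(x, ...) {
  cat(sprintf("<vs_molecule %s: %d atoms, %d bonds, y=%d%s>\n",
              x$id, nrow(x$atoms), nrow(x$bonds), x$activity,
              if (x$has_coords) ", 3D" else ""))
  invisible(x)
}

#' Build a MoleculeSet
#'
#' @param molecules list of \code{vs_molecule}.
#' @param name data set name.
#' @param provenance free-text metadata (character).
#' @return object of class \code{vs_molecule_set}.
#' @export
molecule_set <- function(molecules, name = "unnamed", provenance = character()) {
  ids <- vapply(molecules, function(m) m$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  ys <- vapply(molecules, function(m) m$activity, integer(1))
  if (anyNA(ys) || !all(ys %in% c(0L, 1L)))
    stop("every molecule must carry a binary activity label")
  structure(list(molecules = molecules, name = name, provenance = provenance),
            class = "vs_molecule_set")
}

#' @export
print.vs_molecule_set <- function(x, ...) {
  ys <- activities(x)
  cat(sprintf("<vs_molecule_set '%s': %d molecules (%d active, %d inactive)>\n",
              x$name, length(x$molecules), sum(ys == 1), sum(ys == 0)))
  invisible(x)
}

#' @export
length.vs_molecule_set <- function(x) length(x$molecules)

#' Molecule ids of a set
#' @param ms a \code{vs_molecule_set}.
#' @export
molecule_ids <- function(ms) vapply(ms$molecules, function(m) m$id, character(1))

#' Activity labels of a set
#' @param ms a \code{vs_molecule_set}.
#' @export
activities <- function(ms) vapply(ms$molecules, function(m) m$activity, integer(1))

#' Subset a MoleculeSet by id
#' @param ms a \code{vs_molecule_set}.
#' @param ids character vector of molecule ids to keep (order respected).
#' @export
subset_molecules <- function(ms, ids) {
  all_ids <- molecule_ids(ms)
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stop("unknown molecule ids: ", paste(ids[is.na(idx)], collapse = ", "))
  molecule_set(ms$molecules[idx], name = ms$name, provenance = ms$provenance)
}

## ---- V2000 molblock serialization ----------------------------------------

#' Serialize one molecule as a V2000 molblock (without the "$$$$" terminator)
#' @param mol a \code{vs_molecule}.
#' @return character scalar.
#' @keywords internal
write_molblock <- function(mol) {
  a <- mol$atoms; b <- mol$bonds
  xyz <- if (mol$has_coords) cbind(a$x, a$y, a$z) else matrix(0, nrow(a), 3)
  header <- c(mol$id, "  vshybrid", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   xyz[, 1], xyz[, 2], xyz[, 3], a$symbol)
  bonds <- if (nrow(b)) sprintf("%3d%3d%3d  0", b$i, b$j, b$order) else character(0)
  chg <- which(a$charge != 0L)
  chg_lines <- character(0)
  if (length(chg)) {
    # M CHG lines hold at most 8 (index, charge) pairs each
    grp <- split(chg, ceiling(seq_along(chg) / 8))
    chg_lines <- vapply(grp, function(ix) {
      paste0("M  CHG", sprintf("%3d", length(ix)),
             paste0(sprintf("%4d%4d", ix, a$charge[ix]), collapse = ""))
    }, character(1))
  }
  paste(c(header, counts, atoms, bonds, chg_lines, "M  END"), collapse = "\n")
}

#' Serialize a MoleculeSet as SDF text with the activity label as an SD tag
#' @param ms a \code{vs_molecule_set}.
#' @param label_tag SD tag name for the activity label.
#' @keywords internal
write_sdf_text <- function(ms, label_tag = "activity") {
  blocks <- vapply(ms$molecules, function(m) {
    paste0(write_molblock(m), "\n> <", label_tag, ">\n", m$activity, "\n\n$$$$")
  }, character(1))
  paste(blocks, collapse = "\n")
}

# Parse the lines of a single V2000 molblock (up to and including M END).
# Returns list(title, atoms, bonds) or NULL if structurally unreadable.
parse_molblock_lines <- function(lines) {
  if (length(lines) < 4L) return(NULL)
  title <- trimws(lines[1])
  counts <- lines[4]
  n_at <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bd <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_at) || is.na(n_bd) || n_at < 1L) return(NULL)
  if (length(lines) < 4L + n_at + n_bd) return(NULL)
  at_lines <- lines[5:(4 + n_at)]
  atoms <- data.frame(
    x = as.numeric(substr(at_lines, 1, 10)),
    y = as.numeric(substr(at_lines, 11, 20)),
    z = as.numeric(substr(at_lines, 21, 30)),
    symbol = trimws(substr(at_lines, 32, 34)),
    stringsAsFactors = FALSE
  )
  # old-style charge column (0 none, 1:+3 2:+2 3:+1 5:-1 6:-2 7:-3)
  oldchg <- suppressWarnings(as.integer(substr(at_lines, 37, 39)))
  oldchg[is.na(oldchg)] <- 0L
  atoms$charge <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)[oldchg + 1L]
  if (n_bd > 0L) {
    bd_lines <- lines[(5 + n_at):(4 + n_at + n_bd)]
    bonds <- data.frame(
      i = as.integer(substr(bd_lines, 1, 3)),
      j = as.integer(substr(bd_lines, 4, 6)),
      order = as.integer(substr(bd_lines, 7, 9))
    )
  } else {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  # M CHG lines override the atom-block charge column
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    atoms$charge <- 0L
    for (cl in chg_lines) {
      vals <- scan(text = substr(cl, 7, nchar(cl)), what = integer(), quiet = TRUE)
      k <- vals[1]
      for (p in seq_len(k)) {
        atoms$charge[vals[2 * p]] <- vals[2 * p + 1]
      }
    }
  }
  # aromatic (4) bond orders may appear in third-party files; keep them as
  # order 1 placeholders and flag aromatic — OpenBabel-produced inputs are
  # kekulized so this branch is rare.
  arom4 <- bonds$order == 4L
  arom_bonds <- if (any(arom4)) cbind(bonds$i[arom4], bonds$j[arom4]) else NULL
  bonds$order[arom4] <- 1L
  list(title = title, atoms = atoms, bonds = bonds, arom_bonds = arom_bonds)
}

# Split raw SDF text lines into per-record line chunks at "$$$$".
split_sdf_records <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (!length(ends)) return(list(lines))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- starts <= ends - 1L
  mapply(function(s, e) lines[s:(e - 1L)], starts[keep], ends[keep], SIMPLIFY = FALSE)
}

# Extract one SD tag value from a record's data section; NA if absent.
sd_tag_value <- function(lines, tag) {
  hit <- grep(paste0("^>.*<", tag, ">"), lines)
  if (!length(hit)) return(NA_character_)
  v <- lines[hit[1] + 1L]
  trimws(v)
}
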