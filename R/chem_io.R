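#' Load a labelled molecule collection from a SMILES or SDF file
#'
#' SMILES files hold one record per line with whitespace-separated columns
#' (by default \code{structure id label}). SDF files are V2000 with the
#' activity label stored in an SD tag. Structures are parsed through
#' OpenBabel; records it cannot parse are counted and reported in the
#' \code{"rejections"} attribute of the returned set, not fatal.
#'
#' @param path file path.
#' @param format "smiles" or "sdf".
#' @param name data set name (defaults to the file name).
#' @param columns for SMILES input: the meaning of the whitespace-separated
#'   columns, a permutation of \code{c("smiles", "id", "label")}; "id" may be
#'   omitted, in which case sequential ids are generated.
#' @param label_tag for SDF input: the SD tag holding the binary label.
#' @return a \code{vs_molecule_set}; attribute \code{"rejections"} is a
#'   data.frame (id, reason) of unparsable records.
#' @export
load_molecules <- function(path, format = c("smiles", "sdf"),
                           name = basename(path),
                           columns = c("smiles", "id", "label"),
                           label_tag = "activity") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "smiles") {
    load_molecules_smiles(lines, name, columns)
  } else {
    load_molecules_sdf(lines, name, label_tag)
  }
}

load_molecules_smiles <- function(lines, name, columns) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records in SMILES input")
  if (!"smiles" %in% columns) stop("'columns' must name a 'smiles' column")
  if (!"label" %in% columns)
    stop("no label column configured for SMILES input (missing 'label' in 'columns')")
  parts <- strsplit(trimws(lines), "[ \t]+")
  get_col <- function(nm) {
    k <- match(nm, columns)
    vapply(parts, function(p) if (length(p) >= k) p[k] else NA_character_, character(1))
  }
  smi <- get_col("smiles")
  lab <- get_col("label")
  if (all(is.na(lab))) stop("label column '", which(columns == "label"),
                            "' absent from every record")
  ids <- if ("id" %in% columns) get_col("id") else sprintf("M%06d", seq_along(smi))
  ids[is.na(ids) | !nzchar(ids)] <- sprintf("M%06d", which(is.na(ids) | !nzchar(ids)))
  if (anyDuplicated(ids)) stop("duplicate record ids in SMILES input: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  yn <- suppressWarnings(as.numeric(lab))
  bad_lab <- is.na(yn) | !(yn %in% c(0, 1))
  if (all(bad_lab)) stop("activity labels are not binary 0/1 in SMILES input")

  input <- paste(smi, ids)
  structures <- structures_from_text(input, "smi")
  build_set_from_structures(structures, ids, as.integer(yn), bad_lab, name,
                            provenance = "loaded from SMILES")
}

load_molecules_sdf <- function(lines, name, label_tag) {
  recs <- split_sdf_records(lines)
  if (!length(recs)) stop("no records in SDF input")
  parsed <- lapply(recs, parse_molblock_lines)
  ids <- vapply(seq_along(parsed), function(k) {
    t <- if (is.null(parsed[[k]])) "" else parsed[[k]]$title
    if (nzchar(t)) t else sprintf("M%06d", k)
  }, character(1))
  ids <- gsub("[ \t]+", "_", ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_")
  labs <- vapply(recs, sd_tag_value, character(1), tag = label_tag)
  if (all(is.na(labs)))
    stop("SD tag <", label_tag, "> is missing from every record")
  if (anyNA(labs))
    stop("SD tag <", label_tag, "> missing for record(s): ",
         paste(ids[is.na(labs)], collapse = ", "))
  yn <- suppressWarnings(as.numeric(labs))
  if (anyNA(yn) || !all(yn %in% c(0, 1)))
    stop("SD tag <", label_tag, "> holds non-binary values")

  # re-emit records with normalized titles so OpenBabel outputs align by id
  ok_parse <- !vapply(parsed, is.null, logical(1))
  sdf_in <- vapply(which(ok_parse), function(k) {
    p <- parsed[[k]]
    mol <- list(id = ids[k], atoms = p$atoms, bonds = p$bonds,
                has_coords = any(abs(c(p$atoms$x, p$atoms$y, p$atoms$z)) > 1e-12))
    paste0(write_molblock_raw(mol, p$arom_bonds), "\n$$$$")
  }, character(1))
  structures <- structures_from_text(paste(sdf_in, collapse = "\n"), "sdf",
                                     parsed = parsed[ok_parse],
                                     parsed_ids = ids[ok_parse])
  build_set_from_structures(structures, ids, as.integer(yn),
                            bad_label = rep(FALSE, length(ids)), name,
                            provenance = "loaded from SDF")
}

# Serialize atoms/bonds even when aromatic flags are not yet perceived;
# aromatic bonds (if known) are written as order 4 so OpenBabel re-perceives.
write_molblock_raw <- function(mol, arom_bonds = NULL) {
  b <- mol$bonds
  if (!is.null(arom_bonds) && nrow(b)) {
    ak <- paste(pmin(arom_bonds[, 1], arom_bonds[, 2]),
                pmax(arom_bonds[, 1], arom_bonds[, 2]))
    bk <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
    b$order[bk %in% ak] <- 4L
  }
  m <- list(id = mol$id, atoms = mol$atoms, bonds = b,
            has_coords = isTRUE(mol$has_coords),
            activity = 0L)
  m$atoms$charge <- m$atoms$charge %||% 0L
  write_molblock(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One batched OpenBabel pass: structures (molblocks), aromatic annotations and
# canonical keys, all keyed by record id. For SMILES input the structure
# itself comes from the SMI->SDF conversion; for SDF input the caller already
# parsed the records and passes them through.
structures_from_text <- function(input, from, parsed = NULL, parsed_ids = NULL,
                                 sdf_args = character()) {
  can <- ob_canonical(input, from)
  mol2 <- parse_mol2_aromatic(ob_convert(input, from, "mol2"))
  if (is.null(parsed)) {
    sdf_txt <- ob_convert(input, from, "sdf", args = sdf_args)
    recs <- split_sdf_records(strsplit(sdf_txt, "\n", fixed = TRUE)[[1]])
    parsed <- lapply(recs, parse_molblock_lines)
    parsed <- parsed[!vapply(parsed, is.null, logical(1))]
    parsed_ids <- vapply(parsed, function(p) p$title, character(1))
  }
  names(parsed) <- parsed_ids
  list(parsed = parsed, canonical = can, mol2 = mol2)
}

build_set_from_structures <- function(structures, ids, y, bad_label, name, provenance) {
  mols <- vector("list", length(ids))
  reject <- character(0); reason <- character(0)
  for (k in seq_along(ids)) {
    id <- ids[k]
    p <- structures$parsed[[id]]
    key <- structures$canonical[id]
    if (bad_label[k]) {
      reject <- c(reject, id); reason <- c(reason, "label"); next
    }
    if (is.null(p) || is.na(key)) {
      reject <- c(reject, id); reason <- c(reason, "parse"); next
    }
    arom <- structures$mol2[[id]]
    mols[[k]] <- molecule(
      id = id, atoms = p$atoms, bonds = p$bonds, activity = y[k],
      aromatic_bonds = if (!is.null(arom)) arom$arom_bonds else p$arom_bonds,
      canonical_key = unname(key)
    )
  }
  mols <- mols[!vapply(mols, is.null, logical(1))]
  if (!length(mols)) stop("zero parsable records")
  ms <- molecule_set(mols, name = name, provenance = provenance)
  attr(ms, "rejections") <- data.frame(id = reject, reason = reason,
                                       stringsAsFactors = FALSE)
  ms
}

#' Write a molecule collection to disk
#'
#' @param ms a \code{vs_molecule_set} whose canonical keys are filled in.
#' @param path output file path.
#' @param format "smiles" (lines \code{structure id label}, the structure being
#'   the canonical SMILES) or "sdf" (V2000 with the label as an SD tag).
#' @param label_tag SD tag name used for \code{format = "sdf"}.
#' @export
write_molecules <- function(ms, path, format = c("smiles", "sdf"),
                            label_tag = "activity") {
  format <- match.arg(format)
  if (format == "smiles") {
    keys <- vapply(ms$molecules, function(m) m$canonical_key, character(1))
    if (anyNA(keys)) stop("canonical keys missing; load or canonicalize first")
    writeLines(paste(keys, molecule_ids(ms), activities(ms)), path)
  } else {
    writeLines(write_sdf_text(ms, label_tag = label_tag), path)
  }
  invisible(path)
}

#' Filter invalid element types and collapse exact structural duplicates
#'
#' Molecules containing elements outside \code{allowed_elements} are removed
#' (reason \code{"atom type"}). Molecules sharing a canonical structure key are
#' collapsed to one record; conflicting labels among duplicates are resolved by
#' \code{policy}: \code{"keep-active"} (a confirmed active outweighs an
#' inactive read), \code{"keep-first"}, or \code{"drop-conflict"} (the whole
#' duplicate group is dropped when labels disagree).
#'
#' @param ms a \code{vs_molecule_set} with canonical keys.
#' @param allowed_elements character vector of permitted element symbols.
#' @param policy duplicate label-conflict policy.
#' @return list with \code{set} (the filtered \code{vs_molecule_set}) and
#'   \code{report} (data.frame id, reason; attribute \code{"canonicalization"}
#'   records the key scheme used for deduplication).
#' @export
filter_and_deduplicate <- function(ms,
                                   allowed_elements = c("H", "C", "N", "O", "S",
                                                        "P", "F", "Cl", "Br", "I"),
                                   policy = c("keep-active", "keep-first",
                                              "drop-conflict")) {
  policy <- match.arg(policy)
  if (!length(ms$molecules)) stop("empty molecule set")
  keys <- vapply(ms$molecules, function(m) m$canonical_key, character(1))
  if (anyNA(keys)) stop("canonical keys missing; load molecules through chem_io first")

  rej_id <- character(0); rej_reason <- character(0)
  ok_elem <- vapply(ms$molecules, function(m) {
    all(m$atoms$symbol %in% allowed_elements)
  }, logical(1))
  rej_id <- c(rej_id, molecule_ids(ms)[!ok_elem])
  rej_reason <- c(rej_reason, rep("atom type", sum(!ok_elem)))

  mols <- ms$molecules[ok_elem]
  keys <- keys[ok_elem]
  keep <- logical(length(mols))
  grp <- split(seq_along(mols), keys)
  for (g in grp) {
    if (length(g) == 1L) { keep[g] <- TRUE; next }
    ys <- vapply(mols[g], function(m) m$activity, integer(1))
    conflict <- length(unique(ys)) > 1L
    if (policy == "drop-conflict" && conflict) {
      rej_id <- c(rej_id, vapply(mols[g], function(m) m$id, character(1)))
      rej_reason <- c(rej_reason, rep("label conflict", length(g)))
      next
    }
    surv <- if (policy == "keep-active" && conflict) g[which(ys == 1L)[1]] else g[1]
    keep[surv] <- TRUE
    dropped <- setdiff(g, surv)
    rej_id <- c(rej_id, vapply(mols[dropped], function(m) m$id, character(1)))
    rej_reason <- c(rej_reason, rep("duplicate", length(dropped)))
  }
  mols <- mols[keep]
  if (!length(mols)) stop("all molecules rejected by filtering/deduplication")
  report <- data.frame(id = rej_id, reason = rej_reason, stringsAsFactors = FALSE)
  attr(report, "canonicalization") <- "OpenBabel canonical SMILES"
  list(set = molecule_set(mols, name = ms$name,
                          provenance = c(ms$provenance, "filtered+deduplicated")),
       report = report)
}
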