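#' @title OpenBabel command-line interface
#' @description Thin wrappers around the \code{obabel} executable used for
#'   structure parsing, canonicalization, aromaticity perception, fragment-based
#'   descriptor computation and (optionally) 3D coordinate generation. All calls
#'   are batched: one process per molecule collection, never per molecule.
#' @name obabel
#' @keywords internal
NULL

ob_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("The 'obabel' executable was not found on the PATH. ",
         "Install OpenBabel (>= 3) to use vshybrid's molecule I/O.",
         call. = FALSE)
  }
  p
}

#' Run obabel on input text, returning output text
#'
#' @param input character scalar or vector of input lines.
#' @param from,to input/output format codes (e.g. "smi", "sdf", "mol2", "can").
#' @param args extra command-line arguments (character vector).
#' @return character scalar: the raw output.
#' @keywords internal
ob_convert <- function(input, from, to, args = character()) {
  bin <- ob_path()
  fin <- tempfile(fileext = paste0(".", from))
  fout <- tempfile(fileext = paste0(".", to))
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(system2(
    bin, c(fin, paste0("-o", to), "-O", fout, "-e", args),
    stdout = FALSE, stderr = FALSE
  ))
  if (!file.exists(fout)) {
    stop("obabel conversion ", from, " -> ", to, " produced no output (status ",
         status, ")", call. = FALSE)
  }
  paste(readLines(fout, warn = FALSE), collapse = "\n")
}

#' Canonical SMILES for a batch of records
#'
#' @param input input text (SMILES lines "structure id" or concatenated SDF).
#' @param from input format code.
#' @return named character vector: canonical SMILES keyed by record title.
#'   Records OpenBabel could not parse are absent.
#' @keywords internal
ob_canonical <- function(input, from = "smi") {
  out <- ob_convert(input, from, "can")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  ttl <- vapply(parts, function(p) if (length(p) > 1) trimws(p[[2]]) else "", character(1))
  stats::setNames(smi, ttl)
}

#' Fragment-based molecular properties via obabel --append
#'
#' Computes MW, logP, TPSA, HBD, HBA (Lipinski-style acceptor count), molar
#' refractivity and rotatable-bond count in one batched call.
#'
#' @param input input text; record titles must be unique, whitespace-free ids.
#' @param from input format code.
#' @return data.frame with columns id, mw, logp, tpsa, hbd, hba, mr, rotors.
#' @keywords internal
ob_properties <- function(input, from = "smi") {
  props <- c("MW", "logP", "TPSA", "HBD", "HBA2", "MR", "rotors")
  out <- ob_convert(input, from, "txt", args = c("--append", shQuote(paste(props, collapse = " "))))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  np <- length(props)
  ok <- vapply(fields, length, integer(1)) >= np + 1L
  fields <- fields[ok]
  id <- vapply(fields, function(f) paste(f[seq_len(length(f) - np)], collapse = " "), character(1))
  num <- t(vapply(fields, function(f) as.numeric(f[(length(f) - np + 1L):length(f)]),
                  numeric(np)))
  df <- data.frame(id = id, num, stringsAsFactors = FALSE)
  names(df) <- c("id", "mw", "logp", "tpsa", "hbd", "hba", "mr", "rotors")
  df
}

#' Parse a MOL2 multi-record string into aromatic bond annotations
#'
#' OpenBabel kekulizes V2000 output, so aromaticity is recovered from a
#' parallel MOL2 conversion ("ar" bond records; atom order is preserved).
#'
#' @param mol2_text MOL2 text, possibly many records.
#' @return named list keyed by record title; each element a list with
#'   \code{n_atoms} and \code{arom_bonds} (integer matrix, columns i, j).
#' @keywords internal
parse_mol2_aromatic <- function(mol2_text) {
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1]]
  starts <- grep("@<TRIPOS>MOLECULE", lines, fixed = TRUE)
  res <- list()
  ends <- c(starts[-1] - 1L, length(lines))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    title <- trimws(block[2])
    counts <- scan(text = block[3], what = integer(), quiet = TRUE)
    n_atoms <- counts[1]; n_bonds <- counts[2]
    bsec <- grep("@<TRIPOS>BOND", block, fixed = TRUE)
    ab <- matrix(integer(0), ncol = 2)
    if (length(bsec) == 1 && n_bonds > 0) {
      blines <- block[(bsec + 1):(bsec + n_bonds)]
      parts <- strsplit(trimws(blines), "[ \t]+")
      typ <- vapply(parts, function(p) p[4], character(1))
      arom <- typ == "ar"
      if (any(arom)) {
        ab <- cbind(
          as.integer(vapply(parts[arom], function(p) p[2], character(1))),
          as.integer(vapply(parts[arom], function(p) p[3], character(1)))
        )
      }
    }
    res[[title]] <- list(n_atoms = n_atoms, arom_bonds = ab)
  }
  res
}
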