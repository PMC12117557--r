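# Synthetic HTS-like molecule sets with a planted, auditable activity signal.
# Molecules are assembled by attaching 0-3 substituents from a built-in
# fragment list onto ring scaffolds (valence-safe attachment sites are marked
# in the templates). The latent activity score mixes a descriptor-visible
# global channel (z-scored topological polar surface area, a molecule-level
# quantity a shallow graph readout struggles to recover) with a graph-visible
# local channel (presence of a sulfonamide motif), plus Gaussian noise; the
# top ceiling(active_fraction * n) latent scores are labelled active, so the
# class balance is exact and deterministic.

# scaffold templates: {A}/{B}/{C} mark substitution sites on ring atoms with
# an available hydrogen; absent substituents collapse to "".
synth_scaffolds <- list(
  benzene       = "c1c{A}cc{B}c{C}c1",
  pyridine      = "n1cc{A}c{B}c{C}c1",
  pyrimidine    = "c1nc{A}c{B}c{C}n1",
  pyrazine      = "c1nc{A}c{B}nc1{C}",
  cyclohexane   = "C1C{A}CC{B}C{C}C1",
  cyclopentane  = "C1C{A}C{B}C{C}C1",
  piperidine    = "C1C{A}CC{B}NC1",
  piperazine    = "C1C{A}NC{B}C{C}N1",
  morpholine    = "O1C{A}C{B}NC{C}C1",
  tetrahydrofuran = "C1C{A}C{B}C{C}O1",
  pyrrole       = "c1c{A}c{B}c{C}[nH]1",
  furan         = "c1c{A}c{B}c{C}o1",
  thiophene     = "c1c{A}c{B}c{C}s1",
  imidazole     = "c1nc{A}c{B}[nH]1",
  indole        = "c1ccc2c(c1)c{A}c{B}[nH]2",
  naphthalene   = "c1ccc2c{A}c{B}c{C}c2c1"
)

# substituent fragments (SMILES, attachment at the first atom)
synth_substituents <- c(
  methyl = "C", ethyl = "CC", hydroxyl = "O", methoxy = "OC", amino = "N",
  fluoro = "F", chloro = "Cl", bromo = "Br", nitrile = "C#N",
  trifluoromethyl = "C(F)(F)F", amide = "C(=O)N", carboxyl = "C(=O)O",
  acetyl = "C(=O)C", sulfonamide = "S(=O)(=O)N", thiomethyl = "SC",
  nitro = "[N+](=O)[O-]"
)

synth_motif <- "sulfonamide"

fill_template <- function(template, subs) {
  # subs: named character (A/B/C), "" meaning unsubstituted
  for (slot in c("A", "B", "C")) {
    frag <- if (slot %in% names(subs) && nzchar(subs[[slot]]))
      paste0("(", subs[[slot]], ")") else ""
    template <- sub(paste0("{", slot, "}"), frag, template, fixed = TRUE)
  }
  template
}

n_sites <- function(template) {
  sum(vapply(c("A", "B", "C"), function(s)
    grepl(paste0("{", s, "}"), template, fixed = TRUE), logical(1)))
}

#' Synthetic-screen configuration
#'
#' Defaults emulate a (scaled-down) high-throughput screen: thousands of
#' molecules, a rare active class, and structure concentrated in a modest
#' number of scaffold families.
#'
#' @param n number of molecules.
#' @param active_fraction target active fraction, in (0, 0.5).
#' @param n_families number of scaffold families to draw from (2-16).
#' @param w_global weight of the global, descriptor-visible channel (z-scored
#'   topological polar surface area).
#' @param w_motif weight of the local, graph-visible channel (sulfonamide
#'   motif presence).
#' @param noise standard deviation of the Gaussian noise on the latent score.
#' @param seed integer seed; fixes structures, labels and coordinates.
#' @param emit_3d generate seeded 3D coordinates (heavy atoms) at build time.
#' @return object of class \code{vs_synth_config}.
#' @export
synth_config <- function(n = 2000L, active_fraction = 0.01, n_families = 10L,
                         w_global = 1, w_motif = 1, noise = 0.5, seed = 1L,
                         emit_3d = FALSE) {
  stopifnot(n >= 10, active_fraction > 0, active_fraction < 0.5,
            n_families >= 2, n_families <= length(synth_scaffolds),
            w_global >= 0, w_motif >= 0, noise >= 0)
  if (w_global == 0 && w_motif == 0)
    stop("at least one signal weight must be positive")
  if (ceiling(active_fraction * n) < 1) stop("requested actives < 1")
  structure(list(n = as.integer(n), active_fraction = active_fraction,
                 n_families = as.integer(n_families), w_global = w_global,
                 w_motif = w_motif, noise = noise, seed = as.integer(seed),
                 emit_3d = emit_3d),
            class = "vs_synth_config")
}

#' Generate a synthetic screening data set
#'
#' Structures are sampled (scaffold, number of substituents, sites,
#' fragments) and deduplicated on canonical SMILES until \code{cfg$n} unique
#' molecules exist; identical seeds give identical structures, labels and
#' coordinates. Labels come from a top-k cut of the latent score (see the
#' module header), so the realized active count is exactly
#' \code{ceiling(active_fraction * n)}.
#'
#' @param cfg a \code{vs_synth_config}.
#' @return list of class \code{vs_synth_data}: \code{set} (a
#'   \code{vs_molecule_set}), \code{scaffold_family} (family name per
#'   molecule), \code{family_key} (canonical scaffold SMILES per molecule),
#'   \code{latent} (latent scores), \code{motif} (motif presence),
#'   \code{global_z} (the z-scored global property), and \code{config}.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "vs_synth_config"))
  fam_names <- names(synth_scaffolds)[seq_len(cfg$n_families)]
  with_preserved_rng(cfg$seed, {
    smi <- character(0); fam <- character(0); motif <- logical(0)
    seen <- character(0)
    guard <- 0L
    while (length(smi) < cfg$n) {
      guard <- guard + 1L
      if (guard > 60L) stop("unable to generate ", cfg$n, " unique molecules; ",
                            "combinatorial space too small for this config")
      m <- max(200L, ceiling((cfg$n - length(smi)) * 1.6))
      f <- sample(fam_names, m, replace = TRUE)
      k <- sample(0:3, m, replace = TRUE, prob = c(0.1, 0.25, 0.35, 0.3))
      cand <- character(m); cmotif <- logical(m)
      for (q in seq_len(m)) {
        tpl <- synth_scaffolds[[f[q]]]
        ns <- n_sites(tpl)
        kk <- min(k[q], ns)
        slots <- c("A", "B", "C")[seq_len(ns)]
        use <- if (kk > 0) sample(slots, kk) else character(0)
        frg <- if (kk > 0) sample(names(synth_substituents), kk, replace = TRUE)
               else character(0)
        subs <- stats::setNames(rep("", 3), c("A", "B", "C"))
        subs[use] <- synth_substituents[frg]
        cand[q] <- fill_template(tpl, subs)
        cmotif[q] <- synth_motif %in% frg
      }
      # canonical dedup (against everything kept so far, first occurrence wins)
      can <- ob_canonical(paste(cand, sprintf("q%06d", seq_len(m))), "smi")
      ck <- unname(can[sprintf("q%06d", seq_len(m))])
      ok <- !is.na(ck) & !duplicated(ck) & !(ck %in% seen)
      take <- which(ok)[seq_len(min(sum(ok), cfg$n - length(smi)))]
      smi <- c(smi, cand[take]); fam <- c(fam, f[take])
      motif <- c(motif, cmotif[take]); seen <- c(seen, ck[take])
    }
    ids <- sprintf("syn%06d", seq_len(cfg$n))
    input <- paste(smi, ids)
    sdf_args <- if (cfg$emit_3d) c("--gen3d", "-d") else character(0)
    structures <- structures_from_text(input, "smi", sdf_args = sdf_args)
    ms <- build_set_from_structures(structures, ids, rep(0L, cfg$n),
                                    bad_label = rep(FALSE, cfg$n),
                                    name = "synthetic_screen",
                                    provenance = sprintf("synth seed=%d", cfg$seed))
    if (length(ms$molecules) != cfg$n)
      stop("generator emitted unparsable structures; this should not happen")

    tpsa <- molecule_descriptors(ms)[, "tpsa"]
    gz <- if (stats::sd(tpsa) > 0) (tpsa - mean(tpsa)) / stats::sd(tpsa)
          else tpsa * 0
    latent <- cfg$w_global * gz + cfg$w_motif * as.numeric(motif) +
      stats::rnorm(cfg$n, 0, cfg$noise)
    n_act <- ceiling(cfg$active_fraction * cfg$n)
    y <- integer(cfg$n)
    y[order(-latent, seq_len(cfg$n))[seq_len(n_act)]] <- 1L

    mols <- ms$molecules
    for (q in seq_len(cfg$n)) mols[[q]]$activity <- y[q]
    ms <- molecule_set(mols, name = ms$name, provenance = ms$provenance)

    fam_key <- scaffold_family_keys()[fam]
    structure(list(set = ms, scaffold_family = fam, family_key = unname(fam_key),
                   latent = latent, motif = motif, global_z = gz,
                   config = cfg),
              class = "vs_synth_data")
  })
}

# canonical SMILES of the bare (unsubstituted) scaffold cores, memoized
.synth_cache <- new.env(parent = emptyenv())
scaffold_family_keys <- function() {
  if (!is.null(.synth_cache$family_keys)) return(.synth_cache$family_keys)
  bare <- vapply(synth_scaffolds, function(t)
    fill_template(t, c(A = "", B = "", C = "")), character(1))
  can <- ob_canonical(paste(bare, names(bare)), "smi")
  keys <- stats::setNames(unname(can[names(bare)]), names(bare))
  .synth_cache$family_keys <- keys
  keys
}

#' Audit the planted signal of a generated data set
#'
#' Reports the realized active fraction, per-family active counts, motif
#' prevalence among actives versus inactives, and the Spearman correlation
#' between the built-in polar-surface descriptor and the latent score.
#'
#' @param sd_obj a \code{vs_synth_data} from \code{\link{generate_dataset}}.
#' @return list of class \code{vs_synth_audit}.
#' @export
planted_signal_audit <- function(sd_obj) {
  stopifnot(inherits(sd_obj, "vs_synth_data"))
  y <- activities(sd_obj$set)
  tpsa <- molecule_descriptors(sd_obj$set)[, "tpsa"]
  list(
    n = length(y),
    active_fraction = mean(y),
    n_active = sum(y),
    per_family_active = tapply(y, sd_obj$scaffold_family, sum),
    motif_prev_active = if (any(y == 1)) mean(sd_obj$motif[y == 1]) else NA_real_,
    motif_prev_inactive = if (any(y == 0)) mean(sd_obj$motif[y == 0]) else NA_real_,
    descriptor_latent_cor = stats::cor(tpsa, sd_obj$latent, method = "spearman")
  )
}
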