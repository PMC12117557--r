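#' Validate a benchmark run configuration
#'
#' A run configuration is a plain named list (optionally read from YAML or
#' JSON via \code{\link{read_run_config}}) with elements:
#' \describe{
#'   \item{data}{either \code{list(source = "synthetic", ...)} with
#'     \code{\link{synth_config}} arguments, or \code{list(source = "smiles"
#'     | "sdf", path = ...)} plus optional \code{load_molecules} arguments.}
#'   \item{descriptors}{\code{"builtin"} (default) or a descriptor CSV path.}
#'   \item{models}{list of model specs: \code{name}, \code{encoder} ("gcn",
#'     "schnet" or NULL for descriptor-only), \code{use_descriptors}, and any
#'     \code{\link{hybrid_config}} / \code{\link{encoder_config}} overrides.}
#'   \item{splits}{\code{kind} ("random" or "scaffold"), \code{frac},
#'     \code{replicates}, \code{seed}.}
#'   \item{metrics}{\code{alpha}, \code{cutoff}, \code{fpr_lo}, \code{fpr_hi}.}
#'   \item{comparisons}{optional list of \code{c(model_a, model_b)} pairs for
#'     the paired statistical comparison.}
#'   \item{output_dir}{results directory.}
#' }
#'
#' @param rc run-config list.
#' @return the normalized config (invisibly errors on problems).
#' @export
validate_run_config <- function(rc) {
  if (is.null(rc$data) || is.null(rc$data$source))
    stop("config needs data$source")
  if (rc$data$source %in% c("smiles", "sdf")) {
    if (is.null(rc$data$path) || !file.exists(rc$data$path))
      stop("data file not found: ", rc$data$path %||% "<missing>")
  } else if (rc$data$source != "synthetic") {
    stop("unknown data source: ", rc$data$source)
  }
  if (!is.null(rc$descriptors) && !identical(rc$descriptors, "builtin") &&
      !file.exists(rc$descriptors))
    stop("descriptor CSV not found: ", rc$descriptors)
  if (is.null(rc$models) || !length(rc$models)) stop("config needs >= 1 model")
  nms <- vapply(rc$models, function(m) m$name %||% "", character(1))
  if (any(!nzchar(nms)) || anyDuplicated(nms))
    stop("every model needs a unique name")
  rc$splits <- utils::modifyList(
    list(kind = "random", frac = 0.8, replicates = 5L, seed = 1L),
    rc$splits %||% list())
  if (rc$splits$replicates < 1L) stop("config needs >= 1 split replicate")
  rc$metrics <- utils::modifyList(
    list(alpha = 20, cutoff = 100L, fpr_lo = 0.001, fpr_hi = 0.1),
    rc$metrics %||% list())
  if (is.null(rc$descriptors)) rc$descriptors <- "builtin"
  if (is.null(rc$output_dir)) stop("config needs output_dir")
  rc
}

#' Read a run configuration from a YAML or JSON file
#' @param path config file path (.yml/.yaml/.json).
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

build_model_cfg <- function(spec, seed) {
  enc <- NULL
  if (!is.null(spec$encoder) && !identical(spec$encoder, "none")) {
    enc_args <- spec$encoder_args %||% list()
    enc <- do.call(encoder_config, c(list(encoder = spec$encoder), enc_args))
  }
  args <- spec[intersect(names(spec),
                         c("mlp_hidden", "dropout", "epochs", "batch_size",
                           "lr", "pos_weight"))]
  do.call(hybrid_config,
          c(list(encoder = enc,
                 use_descriptors = isTRUE(spec$use_descriptors %||% TRUE),
                 seed = seed),
            args))
}

#' Run the full screening benchmark
#'
#' End to end: load or simulate the data set, filter and deduplicate,
#' featurize, compute or load descriptors, then for each split replicate
#' train every configured model on the identical partition (split files are
#' written once and shared; the manifest records their checksums), score the
#' test side and evaluate the metric panel. Writes \code{metrics.csv},
#' \code{comparisons.csv} (when comparisons are configured),
#' \code{splits/*.csv}, a run log and \code{manifest.json} with every seed,
#' the config hash and output checksums. Rerunning with an identical config
#' reproduces \code{metrics.csv} bit for bit.
#'
#' @param rc run-config list (see \code{\link{validate_run_config}}).
#' @return the metrics table, invisibly; side effect: the results directory.
#' @export
run_benchmark <- function(rc) {
  rc <- validate_run_config(rc)
  out <- rc$output_dir
  dir.create(file.path(out, "splits"), recursive = TRUE, showWarnings = FALSE)
  log_file <- file.path(out, "run.log")
  cat("", file = log_file)
  logf <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    message(line)
    cat(line, "\n", file = log_file, append = TRUE)
  }

  logf("stage=data source=%s", rc$data$source)
  if (rc$data$source == "synthetic") {
    sc_args <- rc$data[setdiff(names(rc$data), "source")]
    sc <- do.call(synth_config, sc_args)
    sdat <- generate_dataset(sc)
    ms <- sdat$set
    logf("generated %d molecules (seed %d)", length(ms), sc$seed)
  } else {
    load_args <- rc$data[intersect(names(rc$data),
                                   c("columns", "label_tag", "name"))]
    ms <- do.call(load_molecules,
                  c(list(path = rc$data$path, format = rc$data$source),
                    load_args))
    logf("loaded %d molecules (%d rejected)", length(ms),
         nrow(attr(ms, "rejections")))
  }
  fd <- filter_and_deduplicate(ms)
  ms <- fd$set
  logf("stage=filter kept=%d rejected=%d", length(ms), nrow(fd$report))

  scheme <- do.call(feature_scheme, rc$scheme %||% list())
  graphs <- featurize_set(ms, scheme)
  desc <- if (identical(rc$descriptors, "builtin")) {
    molecule_descriptors(ms)
  } else {
    load_descriptor_table(rc$descriptors, ms)
  }
  logf("stage=featurize d_node=%d d_dp=%d", scheme$d_node, ncol(desc))

  ids <- molecule_ids(ms)
  y <- activities(ms)
  skeys <- if (rc$splits$kind == "scaffold") scaffold_keys(ms) else NULL

  mrows <- list()
  seeds_used <- list()
  split_files <- character(0)
  for (r in seq_len(rc$splits$replicates)) {
    split_seed <- rc$splits$seed + r - 1L
    sp <- if (rc$splits$kind == "scaffold") {
      scaffold_split(ms, rc$splits$frac, split_seed, keys = skeys)
    } else {
      random_split(ms, rc$splits$frac, split_seed)
    }
    sf <- file.path(out, "splits", sprintf("%s_%02d.csv", rc$splits$kind, r))
    write_split(sp, sf)
    split_files <- c(split_files, sf)
    logf("stage=split replicate=%d seed=%d train=%d test=%d md5=%s",
         r, split_seed, length(sp$train), length(sp$test),
         unname(tools::md5sum(sf)))
    tr <- match(sp$train, ids); te <- match(sp$test, ids)
    for (mi in seq_along(rc$models)) {
      spec <- rc$models[[mi]]
      model_seed <- rc$splits$seed + 7919L * r + 104729L * mi
      cfg <- build_model_cfg(spec, model_seed)
      seeds_used[[paste(spec$name, r, sep = "/")]] <- model_seed
      model <- train_hybrid(
        labels = y[tr], cfg = cfg,
        graphs = if (!is.null(cfg$encoder)) graphs[tr] else NULL,
        descriptors = if (cfg$use_descriptors) desc[tr, , drop = FALSE] else NULL,
        scheme = scheme
      )
      ranked <- score_test_set(
        model,
        graphs = if (!is.null(cfg$encoder)) graphs[te] else NULL,
        descriptors = if (cfg$use_descriptors) desc[te, , drop = FALSE] else NULL,
        ids = sp$test
      )
      if (is.null(cfg$encoder)) ranked$label <- y[te]
      mm <- metric_report(ranked, alpha = rc$metrics$alpha,
                          cutoff = rc$metrics$cutoff,
                          fpr_lo = rc$metrics$fpr_lo,
                          fpr_hi = rc$metrics$fpr_hi)
      logf("stage=train model=%s replicate=%d seed=%d final_loss=%.5f %s",
           spec$name, r, model_seed, model$history[length(model$history)],
           paste(sprintf("%s=%.4f", names(mm), mm), collapse = " "))
      mrows[[length(mrows) + 1L]] <- data.frame(
        dataset = ms$name, model = spec$name, split_kind = rc$splits$kind,
        replicate = r, metric = names(mm), value = unname(mm),
        stringsAsFactors = FALSE
      )
    }
  }
  metrics <- do.call(rbind, mrows)
  metrics_path <- file.path(out, "metrics.csv")
  utils::write.csv(metrics, metrics_path, row.names = FALSE, quote = FALSE)

  comp_path <- NULL
  if (!is.null(rc$comparisons) && length(rc$comparisons)) {
    pairs <- do.call(rbind, lapply(rc$comparisons, function(p)
      data.frame(model_a = p[[1]], model_b = p[[2]], stringsAsFactors = FALSE)))
    comp <- compare_models(metrics, pairs)
    comp_path <- file.path(out, "comparisons.csv")
    utils::write.csv(comp, comp_path, row.names = FALSE, quote = FALSE)
  }

  cfg_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(rc, cfg_tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  manifest <- list(
    config = rc,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    seeds = seeds_used,
    files = as.list(tools::md5sum(c(metrics_path, comp_path, split_files)))
  )
  unlink(cfg_tmp)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  logf("stage=done metrics_md5=%s", unname(tools::md5sum(metrics_path)))
  invisible(metrics)
}
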