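#' Hybrid model configuration
#'
#' Configures the descriptor-integrated classifier: a graph encoder producing
#' the learned representation h, optionally concatenated with the scaled
#' descriptor vector h_dp, classified by an MLP with sigmoid output and
#' trained under binary cross-entropy. At least one of the encoder and the
#' descriptor branch must be active; with \code{encoder = NULL} the model
#' reduces to an MLP on descriptors alone (the descriptor-only baseline), and
#' with \code{use_descriptors = FALSE} to the plain GNN baseline.
#'
#' @param encoder a \code{\link{encoder_config}} or NULL (descriptor-only).
#' @param use_descriptors include the descriptor branch.
#' @param mlp_hidden integer vector of MLP hidden widths.
#' @param dropout dropout rate in the MLP hidden layers (training only).
#' @param epochs number of training epochs (the returned model is always the
#'   final-epoch state; no early stopping).
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @param pos_weight optional positive-class weight in the loss (default 1,
#'   i.e. no reweighting).
#' @return object of class \code{vs_hybrid_config}.
#' @export
hybrid_config <- function(encoder = encoder_config("gcn"),
                          use_descriptors = TRUE,
                          mlp_hidden = c(128L, 64L), dropout = 0.2,
                          epochs = 30L, batch_size = 128L, lr = 1e-3,
                          seed = 1L, pos_weight = 1) {
  if (is.null(encoder) && !use_descriptors)
    stop("at least one of the encoder and the descriptor branch must be active")
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, dropout >= 0, dropout < 1,
            pos_weight > 0)
  structure(list(encoder = encoder, use_descriptors = use_descriptors,
                 mlp_hidden = as.integer(mlp_hidden), dropout = dropout,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, seed = as.integer(seed), pos_weight = pos_weight),
            class = "vs_hybrid_config")
}

#' Binary cross-entropy loss
#'
#' \deqn{L = -\frac{1}{n}\sum_i [y_i \log \hat p_i + (1-y_i)\log(1-\hat p_i)]}
#' with scores clipped to [eps, 1-eps] for numerical stability.
#'
#' @param scores predicted probabilities.
#' @param labels binary labels, same length.
#' @param eps clipping constant.
#' @param weights optional per-sample weights (e.g. positive-class weighting).
#' @return nonnegative scalar loss.
#' @export
bce_loss <- function(scores, labels, eps = 1e-7, weights = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  p <- pmin(pmax(scores, eps), 1 - eps)
  ll <- labels * log(p) + (1 - labels) * log(1 - p)
  if (is.null(weights)) -mean(ll) else -sum(weights * ll) / length(ll)
}

#' Score through the MLP head from representation vectors
#'
#' Evaluates \eqn{\hat p = f([h \| h_{dp}])}: the learned representation
#' (when present) concatenated with the descriptor vector (when present), in
#' that order, passed through the ReLU MLP with sigmoid output. Dropout is
#' disabled (inference behavior).
#'
#' @param h graph embedding vector or NULL.
#' @param h_dp (scaled) descriptor vector or NULL.
#' @param params MLP parameter list (\code{mlp.W1}, \code{mlp.b1}, ...,
#'   \code{mlp.Wout}, \code{mlp.bout}).
#' @param hidden MLP hidden widths matching \code{params}.
#' @return scalar score in (0, 1).
#' @export
predict_one <- function(h = NULL, h_dp = NULL, params, hidden = c(128L, 64L)) {
  if (is.null(h) && is.null(h_dp)) stop("at least one of h, h_dp must be given")
  z <- matrix(c(h, h_dp), nrow = 1)
  if (ncol(z) != nrow(params[["mlp.W1"]]))
    stop("MLP input width ", ncol(z), " does not match parameters (",
         nrow(params[["mlp.W1"]]), ")")
  mlp_forward(z, params, hidden, dropout = 0, training = FALSE)$p
}

# internal: one forward/backward pass over a slice of a prepped graph stack
# (may be NULL for descriptor-only) and a matrix of scaled descriptors (may
# be NULL).
hybrid_forward <- function(stack, idx, D, params, cfg, enc, training = FALSE) {
  h <- NULL; enc_cache <- NULL
  if (!is.null(enc)) {
    batch <- enc$impl$assemble(stack, idx)
    fw <- enc$impl$forward(batch, params, enc$cfg, training)
    h <- fw$h; enc_cache <- fw$cache
  }
  Z <- cbind(h, D)
  mf <- mlp_forward(Z, params, cfg$mlp_hidden, cfg$dropout, training)
  list(p = mf$p, mlp_cache = mf$cache, enc_cache = enc_cache, d_enc = ncol(h %||% matrix(0, 0, 0)))
}

#' Train a hybrid (or baseline) activity model
#'
#' Mini-batch Adam optimization of the binary cross-entropy for exactly
#' \code{cfg$epochs} epochs; the returned parameters are the final-epoch
#' state (no early stopping or validation-based selection). The descriptor
#' scaler is fitted on the training rows only. Fully reproducible given
#' \code{cfg$seed}.
#'
#' @param labels binary label vector.
#' @param cfg a \code{vs_hybrid_config}.
#' @param graphs list of \code{vs_graph} (required when an encoder is
#'   configured).
#' @param descriptors unscaled descriptor matrix, rows aligned with
#'   \code{labels} (required when \code{use_descriptors}).
#' @param scheme the \code{vs_feature_scheme} used for featurization (its
#'   dimensions size the encoder input).
#' @return object of class \code{vs_model}: parameters, config, fitted
#'   scaler, and per-epoch mean training loss.
#' @export
train_hybrid <- function(labels, cfg, graphs = NULL, descriptors = NULL,
                         scheme = feature_scheme()) {
  y <- as.numeric(labels)
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("training set must contain both classes")
  enc <- NULL; stack <- NULL
  if (!is.null(cfg$encoder)) {
    if (is.null(graphs) || length(graphs) != n)
      stop("encoder configured but featurized graphs are missing/misaligned")
    enc <- list(impl = get_encoder(cfg$encoder$encoder), cfg = cfg$encoder)
    stack <- enc$impl$prep(graphs, cfg$encoder)
  }
  D <- NULL; scaler <- NULL
  if (cfg$use_descriptors) {
    if (is.null(descriptors) || nrow(descriptors) != n)
      stop("use_descriptors = TRUE but descriptor rows are missing/misaligned")
    fs <- fit_apply_scaler(descriptors)
    D <- fs$scaled; scaler <- fs$scaler
  }
  d_in <- (if (!is.null(enc)) cfg$encoder$hidden else 0L) +
    (if (cfg$use_descriptors) ncol(D) else 0L)

  with_preserved_rng(cfg$seed, {
    params <- c(
      if (!is.null(enc)) enc$impl$init(cfg$encoder, scheme$d_node,
                                       length(scheme$elements)),
      mlp_init_params(d_in, cfg$mlp_hidden)
    )
    opt <- adam_init(params)
    w_pos <- cfg$pos_weight
    history <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        Db <- if (!is.null(D)) D[idx, , drop = FALSE] else NULL
        yb <- y[idx]
        fw <- hybrid_forward(stack, idx, Db, params, cfg, enc, training = TRUE)
        wts <- ifelse(yb == 1, w_pos, 1)
        ep_loss <- ep_loss + bce_loss(fw$p, yb, weights = wts) * length(idx)
        dlogit <- matrix(wts * (fw$p - yb) / length(idx), ncol = 1)
        mb <- mlp_backward(dlogit, fw$mlp_cache, params, cfg$mlp_hidden,
                           cfg$dropout, training = TRUE)
        grads <- mb$grads
        if (!is.null(enc)) {
          dh <- mb$dZ[, seq_len(fw$d_enc), drop = FALSE]
          grads <- c(grads, enc$impl$backward(dh, fw$enc_cache, params, enc$cfg))
        }
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params; opt <- st$state
      }
      history[ep] <- ep_loss / n
    }
    structure(list(params = params, config = cfg, scaler = scaler,
                   history = history, d_in = d_in,
                   scheme = scheme),
              class = "vs_model")
  })
}

#' @export
print.vs_model <- function(x, ...) {
  encn <- if (is.null(x$config$encoder)) "none" else x$config$encoder$encoder
  cat(sprintf("<vs_model encoder=%s descriptors=%s epochs=%d final loss=%.4f>\n",
              encn, x$config$use_descriptors, x$config$epochs,
              x$history[length(x$history)]))
  invisible(x)
}

#' Score a test set with a trained model
#'
#' Dropout off; one deterministic score per molecule. The descriptor matrix is
#' transformed with the scaler fitted at training time.
#'
#' @param model a \code{vs_model}.
#' @param graphs list of \code{vs_graph} for the test molecules (when the
#'   model has an encoder).
#' @param descriptors unscaled test descriptor matrix (when the model uses
#'   descriptors); must match the fitted scaler width.
#' @param ids molecule ids; defaults to the graph ids or descriptor rownames.
#' @return a ranked-result data.frame with columns \code{id}, \code{score},
#'   \code{label}.
#' @export
score_test_set <- function(model, graphs = NULL, descriptors = NULL, ids = NULL) {
  cfg <- model$config
  enc <- if (!is.null(cfg$encoder))
    list(impl = get_encoder(cfg$encoder$encoder), cfg = cfg$encoder) else NULL
  D <- NULL
  if (cfg$use_descriptors) {
    if (is.null(descriptors)) stop("model uses descriptors; none supplied")
    D <- apply_scaler(model$scaler, descriptors)
  }
  if (!is.null(enc) && is.null(graphs))
    stop("model has an encoder; featurized graphs required")
  n <- if (!is.null(graphs)) length(graphs) else nrow(D)
  if (is.null(ids)) {
    ids <- if (!is.null(graphs)) vapply(graphs, function(g) g$id, character(1))
    else rownames(descriptors) %||% sprintf("M%06d", seq_len(n))
  }
  labels <- if (!is.null(graphs)) {
    vapply(graphs, function(g) as.integer(g$label), integer(1))
  } else rep(NA_integer_, n)
  stack <- if (!is.null(enc)) enc$impl$prep(graphs, cfg$encoder) else NULL
  idx <- if (!is.null(stack)) seq_along(graphs) else NULL
  fw <- hybrid_forward(stack, idx, D, model$params, cfg, enc, training = FALSE)
  data.frame(id = ids, score = as.numeric(fw$p), label = labels,
             stringsAsFactors = FALSE)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a self-describing JSON archive holding every learned
#' parameter, the configuration, the fitted descriptor scaler and the loss
#' history.
#'
#' @param model a \code{vs_model}.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  ser <- list(
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), x = as.numeric(p))
      else list(dim = NULL, x = as.numeric(p))
    }),
    config = unclass_deep(model$config),
    scaler = model$scaler,
    history = model$history,
    d_in = model$d_in,
    scheme = unclass_deep(model$scheme)
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(ser$params, function(p) {
    if (!is.null(p$dim)) matrix(p$x, p$dim[1], p$dim[2]) else p$x
  })
  cfg <- ser$config
  if (!is.null(cfg$encoder)) class(cfg$encoder) <- "vs_encoder_config"
  class(cfg) <- "vs_hybrid_config"
  scheme <- ser$scheme
  class(scheme) <- "vs_feature_scheme"
  scaler <- ser$scaler
  structure(list(params = params, config = cfg, scaler = scaler,
                 history = ser$history, d_in = ser$d_in, scheme = scheme),
            class = "vs_model")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
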