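#' Paired t-test with confidence interval and effect size
#'
#' Computes the paired differences d = b - a over pairing units (typically
#' dataset x split replicate, with both models evaluated on byte-identical
#' splits), the two-sided paired t-test, the 95 percent confidence interval
#' of the mean difference, and the paired standardized mean difference
#' (Cohen's d_z = mean(d)/sd(d)). When all differences are identical the
#' variance is zero and the result is flagged degenerate (p and t undefined)
#' rather than an error.
#'
#' @param a,b equal-length metric value vectors for models A and B on the
#'   same units in the same order (length >= 2).
#' @param conf confidence level.
#' @return list: \code{mean_diff}, \code{ci_lo}, \code{ci_hi}, \code{t},
#'   \code{df}, \code{p}, \code{effect_size}, \code{degenerate}.
#' @export
paired_t <- function(a, b, conf = 0.95) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- b - a
  k <- length(d)
  if (stats::sd(d) <= .Machine$double.eps * max(1, abs(mean(d)))) {
    return(list(mean_diff = mean(d), ci_lo = mean(d), ci_hi = mean(d),
                t = NA_real_, df = k - 1, p = NA_real_,
                effect_size = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(b, a, paired = TRUE, conf.level = conf)
  list(mean_diff = unname(tt$estimate), ci_lo = tt$conf.int[1],
       ci_hi = tt$conf.int[2], t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value,
       effect_size = mean(d) / stats::sd(d), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (sorted p_(i) * m / i with monotonicity enforced
#' from the largest down, capped at 1), returned in the input order.
#'
#' @param p raw p-values in [0, 1] (NAs from degenerate comparisons pass
#'   through).
#' @return adjusted p-values.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Compare model pairs across datasets and metrics
#'
#' For every (dataset, metric, model pair) cell, pairs the two models' metric
#' values on identical (dataset, replicate) units and runs
#' \code{\link{paired_t}}; FDR adjustment is applied jointly across all cells
#' of the comparison family (all pairs x all metrics x all datasets) to
#' account for multiple comparisons.
#'
#' @param metrics long-format data.frame with columns \code{dataset},
#'   \code{model}, \code{replicate}, \code{metric}, \code{value} (row order
#'   irrelevant).
#' @param pairs data.frame with columns \code{model_a}, \code{model_b}.
#' @return data.frame, one row per comparison cell: dataset, metric, model_a,
#'   model_b, mean_diff (b - a), ci_lo, ci_hi, t, df, p_raw, p_fdr,
#'   effect_size, degenerate.
#' @export
compare_models <- function(metrics, pairs) {
  need <- c("dataset", "model", "replicate", "metric", "value")
  if (!all(need %in% names(metrics)))
    stop("metrics table must have columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (pr in seq_len(nrow(pairs))) {
    ma <- pairs$model_a[pr]; mb <- pairs$model_b[pr]
    for (ds in sort(unique(metrics$dataset))) {
      for (mt in sort(unique(metrics$metric))) {
        sub <- metrics[metrics$dataset == ds & metrics$metric == mt, ]
        va <- sub[sub$model == ma, ]
        vb <- sub[sub$model == mb, ]
        reps <- sort(unique(sub$replicate))
        ia <- match(reps, va$replicate); ib <- match(reps, vb$replicate)
        if (anyNA(ia) || anyNA(ib)) {
          miss <- c(
            if (anyNA(ia)) paste0("(", ds, ", replicate ", reps[is.na(ia)],
                                  ", ", ma, ")"),
            if (anyNA(ib)) paste0("(", ds, ", replicate ", reps[is.na(ib)],
                                  ", ", mb, ")")
          )
          stop("missing metric cell(s): ", paste(miss, collapse = "; "))
        }
        pt <- paired_t(va$value[ia], vb$value[ib])
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = ds, metric = mt, model_a = ma, model_b = mb,
          mean_diff = pt$mean_diff, ci_lo = pt$ci_lo, ci_hi = pt$ci_hi,
          t = pt$t, df = pt$df, p_raw = pt$p,
          effect_size = pt$effect_size, degenerate = pt$degenerate,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out[, c("dataset", "metric", "model_a", "model_b", "mean_diff", "ci_lo",
          "ci_hi", "t", "df", "p_raw", "p_fdr", "effect_size", "degenerate")]
}
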