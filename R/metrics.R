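#' ROC curve by descending-score threshold sweep
#'
#' Tied scores advance as one block, producing a single diagonal segment
#' across the tie. Coordinates are exact rationals of the counts, beginning
#' at (0, 0) and ending at (1, 1).
#'
#' @param scores predicted activity scores.
#' @param labels binary labels (>= 1 active and >= 1 inactive).
#' @return data.frame with columns \code{fpr}, \code{tpr}, both nondecreasing.
#' @export
roc_curve <- function(scores, labels) {
  check_two_class(labels, "roc_curve")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  o <- order(-scores)
  s <- scores[o]; y <- labels[o]
  block <- cumsum(!duplicated(s))        # tie blocks in descending order
  tp <- cumsum(y)[!duplicated(block, fromLast = TRUE)]
  fp <- cumsum(1 - y)[!duplicated(block, fromLast = TRUE)]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

check_two_class <- function(labels, what) {
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop(what, " requires at least one active and one inactive in the ranked list",
         call. = FALSE)
}

#' Ranged logarithmic ROC AUC (logAUC)
#'
#' Area under the ROC curve with the false positive rate on a log10 axis
#' restricted to [\code{fpr_lo}, \code{fpr_hi}], normalized by the log-width
#' of the range so a perfect classifier scores 1. A random ranking scores
#' about 0.0215 for the default range [0.001, 0.1], the ratio
#' \eqn{\int_{-3}^{-1} 10^u du / \int_{-3}^{-1} du}. TPR is interpolated
#' linearly in FPR between ROC vertices (the curve is anchored at (0, 0), so
#' FPRs below the empirical minimum are covered), and the integral is taken by
#' trapezoid in log10(FPR) over a dense log-uniform grid joined with all curve
#' vertices inside the range.
#'
#' @param scores,labels the ranked result.
#' @param fpr_lo,fpr_hi FPR bounds, 0 < fpr_lo < fpr_hi <= 1.
#' @param grid_points number of log-uniform grid points (>= 10001).
#' @return value in [0, 1].
#' @export
ranged_log_auc <- function(scores, labels, fpr_lo = 0.001, fpr_hi = 0.1,
                           grid_points = 10001L) {
  stopifnot(fpr_lo > 0, fpr_lo < fpr_hi, fpr_hi <= 1)
  rc <- roc_curve(scores, labels)
  # maximum TPR at each FPR (vertical climbs collapse to their top)
  u <- seq(log10(fpr_lo), log10(fpr_hi), length.out = max(grid_points, 10001L))
  verts <- log10(rc$fpr[rc$fpr >= fpr_lo & rc$fpr <= fpr_hi & rc$fpr > 0])
  u <- sort(unique(c(u, verts)))
  fgrid <- 10^u
  tpr_at <- stats::approx(x = rc$fpr, y = rc$tpr, xout = fgrid,
                          ties = max, rule = 2)$y
  integral <- sum(diff(u) * (utils::head(tpr_at, -1) + utils::tail(tpr_at, -1)) / 2)
  integral / (log10(fpr_hi) - log10(fpr_lo))
}

# deterministic descending ranks: score descending, ties by stable input order
rank_desc <- function(scores) {
  order(order(-scores, seq_along(scores)))
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' Early-recognition metric in [0, 1] that exponentially weights early ranks:
#' \deqn{RIE = \frac{\sum_{i \in actives} e^{-\alpha r_i / N}}
#'   {\frac{n}{N}\,\frac{1 - e^{-\alpha}}{e^{\alpha/N} - 1}}}, and
#' BEDROC = (RIE - RIE_min) / (RIE_max - RIE_min), where RIE_max and RIE_min
#' place the n actives at the very top and very bottom of the list. Ranks are
#' assigned from descending score with ties broken by stable input order.
#'
#' @param scores,labels the ranked result.
#' @param alpha early-recognition weight (> 0); 20 emphasizes roughly the top
#'   8 percent of the list.
#' @return value in [0, 1].
#' @export
bedroc <- function(scores, labels, alpha = 20) {
  check_two_class(labels, "bedroc")
  stopifnot(alpha > 0)
  N <- length(labels); n <- sum(labels == 1)
  r <- rank_desc(scores)[labels == 1]
  rie_of <- function(ranks) {
    sum(exp(-alpha * ranks / N)) / (n / N * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  }
  rie <- rie_of(r)
  rie_max <- rie_of(seq_len(n))
  rie_min <- rie_of(seq(N - n + 1, N))
  (rie - rie_min) / (rie_max - rie_min)
}

#' Enrichment factor at a rank cutoff
#'
#' \deqn{EF_{100} = \frac{n_{100}/N_{100}}{n/N}}: the active fraction among
#' the top \code{cutoff} ranked compounds divided by the active fraction of
#' the whole set. A random selection expects 1; no actives in the top
#' \code{cutoff} gives 0.
#'
#' @param scores,labels the ranked result.
#' @param cutoff selection-set size (default 100); must not exceed the list.
#' @return nonnegative value.
#' @export
enrichment_factor <- function(scores, labels, cutoff = 100L) {
  check_two_class(labels, "enrichment_factor")
  N <- length(labels)
  if (N < cutoff) stop("cutoff ", cutoff, " exceeds the data set size ", N)
  n <- sum(labels == 1)
  top <- rank_desc(scores) <= cutoff
  n_top <- sum(labels == 1 & top)
  (n_top / cutoff) / (n / N)
}

#' Discounted cumulative gain at a rank cutoff
#'
#' Relevance is 1 for actives and 0 for inactives. CG is the count of actives
#' in the top \code{cutoff}; DCG discounts each by log2(rank + 1):
#' \deqn{DCG_{100} = \sum_{i=1}^{100} y_i / \log_2(i + 1)}.
#'
#' @param scores,labels the ranked result.
#' @param cutoff selection-set size (default 100).
#' @return list with \code{dcg} and \code{cg}.
#' @export
dcg <- function(scores, labels, cutoff = 100L) {
  check_two_class(labels, "dcg")
  N <- length(labels)
  if (N < cutoff) stop("cutoff ", cutoff, " exceeds the data set size ", N)
  r <- rank_desc(scores)
  in_top <- r <= cutoff & labels == 1
  list(dcg = sum(1 / log2(r[in_top] + 1)), cg = sum(in_top))
}

#' Evaluate the standard virtual-screening metric panel
#'
#' @param ranked data.frame with \code{score} and \code{label} columns (as
#'   produced by \code{\link{score_test_set}}).
#' @param alpha BEDROC alpha.
#' @param cutoff EF/DCG cutoff.
#' @param fpr_lo,fpr_hi logAUC FPR range.
#' @return named numeric vector: \code{logauc_0.001_0.1}, \code{bedroc},
#'   \code{ef_100}, \code{dcg_100} (names track the chosen parameters).
#' @export
metric_report <- function(ranked, alpha = 20, cutoff = 100L,
                          fpr_lo = 0.001, fpr_hi = 0.1) {
  s <- ranked$score; y <- ranked$label
  out <- c(
    ranged_log_auc(s, y, fpr_lo, fpr_hi),
    bedroc(s, y, alpha),
    enrichment_factor(s, y, cutoff),
    dcg(s, y, cutoff)$dcg
  )
  names(out) <- c(sprintf("logauc_%g_%g", fpr_lo, fpr_hi), "bedroc",
                  sprintf("ef_%d", cutoff), sprintf("dcg_%d", cutoff))
  out
}
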