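# Paired model-comparison machinery against closed-form oracles.

test_that("paired_t matches the closed-form t statistic and CDF", {
  r <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * stats::pt(-2 * sqrt(3), df = 2), tolerance = 1e-10)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  expect_equal(r$mean_diff, 2)
  expect_equal(r$effect_size, 2)   # mean(d)/sd(d) = 2/1
  expect_false(r$degenerate)
  expect_true(r$ci_lo <= r$mean_diff && r$mean_diff <= r$ci_hi)
})

test_that("paired_t flags degenerate zero-variance differences", {
  a <- c(0.4, 0.5, 0.6)
  r <- paired_t(a, a)
  expect_true(r$degenerate)
  expect_equal(r$mean_diff, 0)
  expect_true(is.na(r$p))
  r2 <- paired_t(a, a + 0.1)
  expect_true(r2$degenerate)
  expect_equal(r2$mean_diff, 0.1)
})

test_that("swapping the two sides negates t, mean and CI but not p", {
  set.seed(4)
  a <- rnorm(8); b <- rnorm(8, 0.3)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$mean_diff, -r2$mean_diff)
  expect_equal(r1$ci_lo, -r2$ci_hi)
  expect_equal(r1$ci_hi, -r2$ci_lo)
  expect_equal(r1$p, r2$p)
})

test_that("paired_t agrees with an explicit-formula oracle on random vectors", {
  oracle <- function(a, b) {
    d <- b - a; k <- length(d)
    t <- mean(d) / (sd(d) / sqrt(k))
    half <- qt(0.975, k - 1) * sd(d) / sqrt(k)
    list(t = t, p = 2 * pt(-abs(t), k - 1),
         lo = mean(d) - half, hi = mean(d) + half, es = mean(d) / sd(d))
  }
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(3:12, 1)
    a <- rnorm(k); b <- rnorm(k, 0.2)
    r <- paired_t(a, b); o <- oracle(a, b)
    expect_equal(r$t, o$t, tolerance = 1e-8)
    expect_equal(r$p, o$p, tolerance = 1e-8)
    expect_equal(r$ci_lo, o$lo, tolerance = 1e-8)
    expect_equal(r$ci_hi, o$hi, tolerance = 1e-8)
    expect_equal(r$effect_size, o$es, tolerance = 1e-8)
  }
})

test_that("bh_fdr reproduces the hand-walked step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    adj <- p[o] * m / seq_len(m)
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-8)
  }
})

test_that("bh_fdr preserves the raw p-value ordering", {
  set.seed(12)
  p <- runif(30)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

make_metric_table <- function(models, datasets = "ds1", metrics = c("m1", "m2"),
                              reps = 3, shift = 0) {
  rows <- expand.grid(dataset = datasets, model = models, replicate = seq_len(reps),
                      metric = metrics, stringsAsFactors = FALSE)
  set.seed(42)
  rows$value <- runif(nrow(rows))
  rows$value[rows$model == models[2]] <-
    rows$value[rows$model == models[1]] + shift +
    if (shift == 0) rnorm(sum(rows$model == models[2]), 0, 0.05) else 0
  rows
}

test_that("compare_models produces one FDR-adjusted row per cell", {
  tab <- make_metric_table(c("A", "B"), metrics = c("m1", "m2", "m3", "m4"))
  out <- compare_models(tab, data.frame(model_a = "A", model_b = "B"))
  expect_equal(nrow(out), 4)                     # 1 dataset x 4 metrics
  expect_true(all(out$p_fdr >= out$p_raw, na.rm = TRUE))
  expect_true(all(out$p_fdr <= 1, na.rm = TRUE))
  expect_true(all(out$ci_lo <= out$mean_diff & out$mean_diff <= out$ci_hi))
})

test_that("a constant offset between models is degenerate with exact mean", {
  tab <- make_metric_table(c("A", "B"), shift = 0.1)
  out <- compare_models(tab, data.frame(model_a = "A", model_b = "B"))
  expect_true(all(out$degenerate))
  expect_equal(out$mean_diff, rep(0.1, nrow(out)), tolerance = 1e-12)
})

test_that("compare_models is invariant to row order and fails on holes", {
  tab <- make_metric_table(c("A", "B"))
  out1 <- compare_models(tab, data.frame(model_a = "A", model_b = "B"))
  set.seed(9)
  out2 <- compare_models(tab[sample(nrow(tab)), ],
                         data.frame(model_a = "A", model_b = "B"))
  expect_equal(out1, out2)
  hole <- tab[!(tab$model == "B" & tab$replicate == 2 & tab$metric == "m1"), ]
  expect_error(compare_models(hole, data.frame(model_a = "A", model_b = "B")),
               "replicate 2")
})
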