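# Early-recognition metric panel: analytic values, hand-derived examples,
# and ranking-theoretic properties.

test_that("roc_curve matches hand-derived sweeps", {
  # perfect separation, 2 actives / 2 inactives
  rc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(rc$fpr, c(0, 0, 0, 0.5, 1))
  expect_equal(rc$tpr, c(0, 0.5, 1, 1, 1))
  # all scores tied: a single diagonal segment
  rc <- roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 0, 0))
  expect_equal(rc$fpr, c(0, 1))
  expect_equal(rc$tpr, c(0, 1))
  # alternating example
  rc <- roc_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))
  expect_equal(rc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(rc$tpr, c(0, 0.5, 0.5, 1, 1))
  # monotone coordinates in [0, 1]
  set.seed(1)
  s <- runif(200); y <- rbinom(200, 1, 0.3)
  rc <- roc_curve(s, y)
  expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
  expect_true(all(rc$fpr >= 0 & rc$fpr <= 1 & rc$tpr >= 0 & rc$tpr <= 1))
  expect_error(roc_curve(1:3, c(1, 1, 1)), "at least one")
})

test_that("ranged logAUC reproduces its analytic anchor values", {
  # perfect ranking with >= 1000 inactives: TPR = 1 over the whole range
  y <- c(rep(1, 20), rep(0, 1200))
  s <- c(runif(20, 0.9, 1.0), runif(1200, 0, 0.5))
  expect_equal(ranged_log_auc(s, y), 1.0, tolerance = 1e-6)
  # all-tied scores: the diagonal, integral 0.0215
  y2 <- c(rep(1, 100), rep(0, 1100))
  expect_equal(ranged_log_auc(rep(0.5, 1200), y2),
               (0.1 - 0.001) / log(10) / 2, tolerance = 1e-6)
  expect_equal(ranged_log_auc(rep(0.5, 1200), y2), 0.0215, tolerance = 5e-4)
  # every active ranked below 10% of the inactives: 0 on the range
  y3 <- c(rep(0, 2000), rep(1, 20))
  s3 <- seq(1, 0, length.out = 2020)
  expect_equal(ranged_log_auc(s3, y3), 0.0)
})

test_that("ranged logAUC agrees with an independent Riemann-sum oracle", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(300:800, 1)
    y <- c(rep(1, sample(5:30, 1)), rep(0, n))
    s <- runif(length(y))
    expect_equal(ranged_log_auc(s, y), logauc_oracle(s, y), tolerance = 1e-4)
  }
})

test_that("BEDROC attains its closed-form limits and brute-force values", {
  # all 10 actives at the top of 1000
  y <- c(rep(1, 10), rep(0, 990))
  s <- seq(1, 0.001, length.out = 1000)
  expect_gt(bedroc(s, y), 0.95)
  expect_lte(bedroc(s, y), 1)
  # all actives at the bottom
  y2 <- c(rep(0, 990), rep(1, 10))
  expect_lt(bedroc(s, y2), 0.01)
  expect_gte(bedroc(s, y2), 0)
  # brute-force sum oracle (explicit rank loop, own normalization)
  bedroc_oracle <- function(scores, labels, alpha) {
    N <- length(labels); n <- sum(labels)
    o <- order(-scores, seq_along(scores))
    ssum <- 0
    for (i in seq_len(N)) if (labels[o[i]] == 1) ssum <- ssum + exp(-alpha * i / N)
    denom <- (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
    rie <- ssum / denom
    rmax <- sum(exp(-alpha * seq_len(n) / N)) / denom
    rmin <- sum(exp(-alpha * seq(N - n + 1, N) / N)) / denom
    (rie - rmin) / (rmax - rmin)
  }
  set.seed(5)
  for (alpha in c(0.05, 2, 20)) {
    y3 <- rep(c(1, 0), 50)               # alternating actives/inactives
    s3 <- seq(1, 0.01, length.out = 100)
    expect_equal(bedroc(s3, y3, alpha), bedroc_oracle(s3, y3, alpha),
                 tolerance = 1e-12)
    # as alpha -> 0 an alternating list approaches 0.5
    if (alpha == 0.05) expect_equal(bedroc(s3, y3, alpha), 0.5, tolerance = 0.03)
    s4 <- runif(400); y4 <- rbinom(400, 1, 0.1); y4[1] <- 1; y4[2] <- 0
    expect_equal(bedroc(s4, y4, alpha), bedroc_oracle(s4, y4, alpha),
                 tolerance = 1e-12)
  }
})

test_that("enrichment factor reproduces the printed formula values", {
  # top-100 active fraction equal to the global fraction -> exactly 1
  set.seed(2); y <- integer(1000); y[1:5] <- 1; y[sample(101:1000, 45)] <- 1
  s <- seq(1, 0.001, length.out = 1000)
  expect_identical(enrichment_factor(s, y), 1)
  # no actives in the top 100 -> 0
  y2 <- integer(1000); y2[900:949] <- 1
  expect_identical(enrichment_factor(s, y2), 0)
  # all 50 actives in the top 100 -> (50/100)/(50/1000) = 10
  y3 <- integer(1000); y3[1:50] <- 1
  expect_identical(enrichment_factor(s, y3), 10)
  expect_error(enrichment_factor(runif(50), rep(c(0, 1), 25)), "exceeds")
})

test_that("DCG and CG follow the discounted-gain definition", {
  s <- seq(1, 0.001, length.out = 200)
  y <- integer(200); y[1] <- 1
  expect_equal(dcg(s, y)$dcg, 1.0)
  y2 <- integer(200); y2[c(1, 3)] <- 1
  expect_equal(dcg(s, y2)$dcg, 1 + 1 / log2(4))
  expect_equal(dcg(s, y2)$cg, 2)
  y3 <- integer(200); y3[150:160] <- 1
  expect_equal(dcg(s, y3)$dcg, 0)
  expect_equal(dcg(s, y3)$cg, 0)
})

test_that("all four metrics depend only on the induced ranking", {
  set.seed(31)
  y <- c(rep(1, 15), rep(0, 400))
  s <- runif(length(y))
  base <- metric_report(data.frame(score = s, label = y))
  for (f in list(function(x) 2 * x + 1, function(x) exp(x),
                 function(x) x^3 + x, function(x) plogis(5 * x))) {
    tr <- metric_report(data.frame(score = f(s), label = y))
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("swapping an adjacent inactive-above-active pair never hurts", {
  set.seed(8)
  for (rep in 1:20) {
    y <- rbinom(150, 1, 0.2); y[1] <- 1; y[2] <- 0
    s <- sort(runif(150), decreasing = TRUE)
    base <- metric_report(data.frame(score = s, label = y))
    ord <- order(-s)
    k <- which(y[ord][-length(y)] == 0 & y[ord][-1] == 1)[1]
    if (is.na(k)) next
    y2 <- y; y2[ord[c(k, k + 1)]] <- y[ord[c(k + 1, k)]]
    swapped <- metric_report(data.frame(score = s, label = y2))
    expect_true(all(swapped >= base - 1e-12))
  }
})

test_that("CG is order-insensitive within the selection set but DCG is not", {
  s <- seq(1, 0.001, length.out = 300)
  y_front <- integer(300); y_front[1:10] <- 1        # actives at ranks 1-10
  y_back <- integer(300); y_back[91:100] <- 1        # actives at ranks 91-100
  expect_equal(dcg(s, y_front)$cg, dcg(s, y_back)$cg)
  expect_gt(dcg(s, y_front)$dcg, dcg(s, y_back)$dcg)
})
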