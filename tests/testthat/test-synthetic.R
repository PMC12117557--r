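# Synthetic screen generator: determinism, exact class balance, planted
# signal channels, and compatibility with the rest of the pipeline.

test_that("identical seeds give identical structures, labels and scores", {
  a <- generate_dataset(synth_config(n = 150, active_fraction = 0.06, seed = 9))
  b <- generate_dataset(synth_config(n = 150, active_fraction = 0.06, seed = 9))
  keys <- function(d) vapply(d$set$molecules, function(m) m$canonical_key,
                             character(1))
  expect_identical(keys(a), keys(b))
  expect_identical(activities(a$set), activities(b$set))
  expect_identical(a$latent, b$latent)
  c2 <- generate_dataset(synth_config(n = 150, active_fraction = 0.06, seed = 10))
  expect_false(identical(keys(a), keys(c2)))
})

test_that("top-k labelling yields the exact requested active count", {
  sd1 <- fixture_synth(300, 0.05, seed = 7)
  expect_equal(sum(activities(sd1$set)), ceiling(0.05 * 300))
  aud <- planted_signal_audit(sd1)
  expect_equal(aud$active_fraction, ceiling(0.05 * 300) / 300)
  expect_equal(aud$n_active, ceiling(0.05 * 300))
  expect_equal(sum(aud$per_family_active), aud$n_active)
})

test_that("with only the global channel, actives are the top polar molecules", {
  sd1 <- generate_dataset(synth_config(n = 200, active_fraction = 0.1,
                                       w_global = 1, w_motif = 0, noise = 0,
                                       seed = 15))
  tpsa <- molecule_descriptors(sd1$set)[, "tpsa"]
  y <- activities(sd1$set)
  # latent is a monotone function of the emitted structures' TPSA
  expect_equal(cor(tpsa, sd1$latent, method = "spearman"), 1.0,
               tolerance = 1e-12)
  k <- sum(y)
  expect_equal(sort(order(-sd1$latent)[seq_len(k)]), which(y == 1))
  expect_gte(min(tpsa[y == 1]), max(tpsa) * 0 + sort(tpsa, decreasing = TRUE)[k] - 1e-9)
})

test_that("with only the motif channel, the motif is enriched among actives", {
  sd1 <- generate_dataset(synth_config(n = 250, active_fraction = 0.1,
                                       w_global = 0, w_motif = 2, noise = 0.3,
                                       seed = 16))
  aud <- planted_signal_audit(sd1)
  expect_gt(aud$motif_prev_active, aud$motif_prev_inactive)
})

test_that("overwhelming noise washes out the descriptor-latent correlation", {
  cors <- vapply(1:3, function(s) {
    sd1 <- generate_dataset(synth_config(n = 250, active_fraction = 0.1,
                                         noise = 100, seed = 100 + s))
    planted_signal_audit(sd1)$descriptor_latent_cor
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.2)
})

test_that("emitted molecules pass filtering and deduplication unchanged", {
  sd1 <- fixture_synth(300, 0.05, seed = 7)
  fd <- filter_and_deduplicate(sd1$set)
  expect_equal(length(fd$set), length(sd1$set))
  expect_equal(nrow(fd$report), 0)
})

test_that("recorded scaffold families agree with perceived murcko keys", {
  sd1 <- fixture_synth(150, 0.06, seed = 9)
  keys <- scaffold_keys(sd1$set)
  # substituents are acyclic, so every molecule's scaffold is its core
  expect_equal(keys, sd1$family_key)
  # family count respects the configured cap
  expect_lte(length(unique(sd1$scaffold_family)), 10)
})

test_that("3D emission stores usable seeded coordinates", {
  sd1 <- fixture_synth(20, 0.2, seed = 5, emit_3d = TRUE)
  g <- featurize_graph(sd1$set$molecules[[3]])
  expect_false(is.null(g$coords))
  expect_true(all(is.finite(g$coords)))
  # coordinates span three dimensions (not a flat 2D layout)
  expect_gt(min(apply(g$coords, 2, function(v) diff(range(v)))), 1e-4)
  # regeneration under the same seed reproduces the geometry
  sd2 <- generate_dataset(synth_config(n = 20, active_fraction = 0.2, seed = 5,
                                       emit_3d = TRUE))
  g2 <- featurize_graph(sd2$set$molecules[[3]])
  expect_equal(g2$coords, g$coords)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(synth_config(n = 100, active_fraction = 0.6), "active_fraction")
  expect_error(synth_config(n = 100, w_global = 0, w_motif = 0),
               "signal weight")
  expect_error(synth_config(n = 100, n_families = 1), "n_families")
})
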