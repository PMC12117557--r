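# vshybrid

Hybrid graph-neural-network + descriptor models for ligand-based virtual
screening in R.

## The problem

In ligand-based virtual screening a compound library is ranked by predicted
activity against a target using only previously assayed actives and
inactives — no target structure. Screens are heavily imbalanced (a few
hundred actives in 10^5–10^6 molecules) and only the very top of the
ranking is ever tested experimentally, so what matters is *early
recognition*: placing actives in the first few hundred positions.

Graph neural networks learn a molecular representation `h = GNN(m)` from
the molecular graph `m`, but they are poor at non-additive molecule-level
properties (e.g. total polar surface area) and data-hungry. Expert-crafted
descriptors `h_dp` deliver exactly those global quantities directly.
`vshybrid` implements the integration strategy that concatenates the two
before classification,

    h  = GNN(m)
    p̂  = f([h ‖ h_dp])

with `f` an MLP with sigmoid output, trained by binary cross-entropy

    L = -(1/n) Σ_i [ y_i log p̂_i + (1 - y_i) log(1 - p̂_i) ],

together with everything needed to evaluate it like a screening
practitioner would:

* molecule I/O (SMILES, SDF V2000) with atom-type filtering, canonical
  deduplication and rejection reporting;
* graph featurization and two encoders — a GCN over the 2D graph and a
  SchNet-style continuous-filter network over 3D coordinates — behind an
  extensible registry, with hand-rolled reverse-mode gradients and Adam;
* a built-in molecule-level descriptor set (computed via OpenBabel plus
  graph perception) and an importer for external descriptor CSV tables;
* random and Bemis–Murcko scaffold train/test splits;
* the early-recognition metric panel: ranged logAUC[0.001, 0.1]
  (perfect = 1, random ≈ 0.0215), BEDROC(α = 20), EF_100, CG/DCG_100;
* paired t-tests with 95% CIs, paired Cohen's d_z and Benjamini–Hochberg
  FDR adjustment for model comparison on identical splits;
* a synthetic HTS-like data generator with a planted, auditable activity
  signal, and an end-to-end benchmark driver with deterministic artifacts.

Who it is for: computational chemists benchmarking descriptor-integration
strategies, and method developers who need a small, fully seeded,
dependency-light test bed for early-recognition ranking models.

## Worked example

Simulate a small screen, train the hybrid model and its ablations on one
80/20 split, and evaluate the metric panel:

```r
library(vshybrid)

sdat <- generate_dataset(synth_config(n = 1000, active_fraction = 0.02,
                                      w_global = 1, w_motif = 1,
                                      noise = 0.5, seed = 11))
ms     <- sdat$set                      # 1000 molecules, 20 actives
graphs <- featurize_set(ms)
desc   <- molecule_descriptors(ms)      # 23 built-in descriptors
ids    <- molecule_ids(ms); y <- activities(ms)

sp <- random_split(ms, 0.8, seed = 1)   # 800 train / 200 test
tr <- match(sp$train, ids); te <- match(sp$test, ids)

fit_eval <- function(encoder, use_desc, seed) {
  cfg <- hybrid_config(encoder = encoder, use_descriptors = use_desc,
                       seed = seed)
  m <- train_hybrid(y[tr], cfg,
                    graphs = if (!is.null(encoder)) graphs[tr],
                    descriptors = if (use_desc) desc[tr, ])
  r <- score_test_set(m, graphs = if (!is.null(encoder)) graphs[te],
                      descriptors = if (use_desc) desc[te, ], ids = sp$test)
  r$label <- y[te]
  metric_report(r, cutoff = 100)
}

rbind(gcn_desc  = fit_eval(encoder_config("gcn"), TRUE, 7),
      gcn_only  = fit_eval(encoder_config("gcn"), FALSE, 7),
      desc_only = fit_eval(NULL, TRUE, 7))
```

Output (exact values are seed-reproducible):

```
          logauc_0.001_0.1    bedroc ef_100  dcg_100
gcn_desc         0.6996120 0.7813161      2 1.875580
gcn_only         0.6666667 0.7217177      2 1.834725
desc_only        0.6527743 0.7678393      2 1.755958
```

Read: the test list holds 200 molecules with 3 actives. All three models
place all 3 actives inside the top 100 (EF_100 = 2, i.e. twice the 1.5%
global active fraction), but the descriptor-integrated GCN concentrates
more of them into the low-false-positive-rate region that matters
(ranged logAUC 0.70 vs 0.67 for the bare GCN and 0.65 for descriptors
alone; a random ranking scores ≈ 0.0215). A single small split is noisy —
`run_benchmark()` repeats this over seeded replicates and attaches paired
statistics:

```r
rc <- list(
  data = list(source = "synthetic", n = 1000L, active_fraction = 0.02,
              seed = 11L),
  models = list(
    list(name = "gcn_desc", encoder = "gcn", use_descriptors = TRUE),
    list(name = "gcn",      encoder = "gcn", use_descriptors = FALSE),
    list(name = "desc",     encoder = "none", use_descriptors = TRUE)),
  splits = list(kind = "random", frac = 0.8, replicates = 5L, seed = 1L),
  comparisons = list(c("gcn", "gcn_desc")),
  output_dir = "results/demo")
run_benchmark(rc)
```

which writes `metrics.csv` (one row per model × replicate × metric),
`comparisons.csv` (mean difference, 95% CI, t, raw and FDR-adjusted p,
paired d_z), shared split files, a run log and a checksummed manifest.
Rerunning the same config reproduces `metrics.csv` bit for bit.

A thin command-line wrapper with `simulate`, `run` and `evaluate`
subcommands is installed as `exec/vshybrid`.

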