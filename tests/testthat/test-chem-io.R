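# Molecule I/O: parsing, rejection reporting, deduplication, round trips.

test_that("SMILES files load one molecule per parsable record", {
  ms <- mols_from_smiles(c("c1ccccc1", "CCO", "CC(=O)N"), labels = c(0, 1, 0))
  expect_s3_class(ms, "vs_molecule_set")
  expect_length(ms, 3)
  expect_equal(activities(ms), c(0L, 1L, 0L))
  expect_equal(nrow(attr(ms, "rejections")), 0)
})

test_that("an invalid SMILES among ten is reported, not fatal", {
  smiles <- c("C", "CC", "CCC", "CCCC", "zz_invalid", "CCO", "c1ccccc1",
              "CCN", "CO", "CN")
  ms <- mols_from_smiles(smiles, labels = rep(0, 10))
  expect_length(ms, 9)
  rej <- attr(ms, "rejections")
  expect_equal(nrow(rej), 1)
  expect_equal(rej$id, "m005")
  expect_equal(rej$reason, "parse")
  # an independent parser pass agrees on which records are valid
  can <- vshybrid:::ob_canonical(paste(smiles, sprintf("m%03d", 1:10)))
  expect_setequal(molecule_ids(ms), names(can))
})

test_that("a missing label column or SD tag is fatal and names the tag", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 a", "CCO b"), f)
  expect_error(load_molecules(f, "smiles", columns = c("smiles", "id")),
               "label")
  ms <- mols_from_smiles(c("c1ccccc1", "CCO"), labels = c(1, 0))
  sdf <- tempfile(fileext = ".sdf")
  write_molecules(ms, sdf, "sdf", label_tag = "potency")
  expect_error(load_molecules(sdf, "sdf", label_tag = "activity"),
               "<activity>")
  ms2 <- load_molecules(sdf, "sdf", label_tag = "potency")
  expect_length(ms2, 2)
})

test_that("load -> write -> load round trips atoms, bonds and labels", {
  smiles <- c("c1ccccc1", "CCO", "CC(=O)Nc1ccc(Cl)cc1", "C1CCNCC1",
              "[O-][N+](=O)c1ccccc1")
  ms <- mols_from_smiles(smiles, labels = c(1, 0, 1, 0, 1))
  for (fmt in c("smiles", "sdf")) {
    f <- tempfile(fileext = paste0(".", substr(fmt, 1, 3)))
    write_molecules(ms, f, fmt)
    ms2 <- load_molecules(f, fmt)
    expect_length(ms2, length(ms))
    for (k in seq_along(ms$molecules)) {
      m1 <- ms$molecules[[k]]
      m2 <- ms2$molecules[[match(m1$id, molecule_ids(ms2))]]
      expect_equal(nrow(m2$atoms), nrow(m1$atoms), info = paste(fmt, m1$id))
      expect_equal(nrow(m2$bonds), nrow(m1$bonds), info = paste(fmt, m1$id))
      expect_equal(m2$activity, m1$activity)
      expect_equal(m2$canonical_key, m1$canonical_key)
    }
  }
})

test_that("deduplication collapses identical structures and keeps counts", {
  # benzene twice (different notations), plus two unique molecules
  ms <- mols_from_smiles(c("c1ccccc1", "C1=CC=CC=C1", "CCO", "CCN"),
                         labels = c(0, 0, 1, 0))
  fd <- filter_and_deduplicate(ms)
  expect_length(fd$set, 3)
  expect_equal(fd$report$reason, "duplicate")
  expect_equal(nrow(fd$report) + length(fd$set), length(ms))
})

test_that("elements outside the allowed set are rejected as atom type", {
  ms <- mols_from_smiles(c("c1ccccc1", "[Si](C)(C)C", "CC[Se]CC"),
                         labels = c(0, 1, 1))
  fd <- filter_and_deduplicate(ms)
  expect_length(fd$set, 1)
  expect_equal(sort(fd$report$reason), c("atom type", "atom type"))
  expect_error(filter_and_deduplicate(fd$set, allowed_elements = "Xx"),
               "all molecules rejected")
})

test_that("duplicate label conflicts follow the configured policy", {
  # 4-record toy: benzene appears 3x with labels 0/1/0, ethanol once
  ms <- mols_from_smiles(c("c1ccccc1", "C1=CC=CC=C1", "c1ccccc1", "CCO"),
                         labels = c(0, 1, 0, 0),
                         ids = c("b1", "b2", "b3", "e1"))
  keep_active <- filter_and_deduplicate(ms, policy = "keep-active")
  surv <- setdiff(molecule_ids(keep_active$set), "e1")
  expect_equal(surv, "b2")   # the active read survives
  expect_equal(activities(keep_active$set)[surv == molecule_ids(keep_active$set)], 1L)

  keep_first <- filter_and_deduplicate(ms, policy = "keep-first")
  expect_true("b1" %in% molecule_ids(keep_first$set))
  expect_equal(unname(activities(keep_first$set)[molecule_ids(keep_first$set) == "b1"]), 0L)

  dropped <- filter_and_deduplicate(ms, policy = "drop-conflict")
  expect_equal(molecule_ids(dropped$set), "e1")
  expect_equal(sum(dropped$report$reason == "label conflict"), 3)
})

test_that("filter_and_deduplicate is idempotent and conserves counts", {
  sd1 <- fixture_synth(120, 0.1, seed = 21)
  extra <- mols_from_smiles(c("c1ccccc1", "C1=CC=CC=C1", "[Si]CC"),
                            labels = c(0, 1, 0), ids = c("x1", "x2", "x3"))
  ms <- molecule_set(c(sd1$set$molecules, extra$molecules), name = "mix")
  fd1 <- filter_and_deduplicate(ms)
  expect_equal(length(fd1$set) + nrow(fd1$report), length(ms))
  fd2 <- filter_and_deduplicate(fd1$set)
  expect_equal(nrow(fd2$report), 0)
  expect_equal(molecule_ids(fd2$set), molecule_ids(fd1$set))
})

test_that("molecule invariants are enforced at construction", {
  at <- data.frame(symbol = c("C", "C"), charge = 0L)
  expect_error(molecule("x", at, data.frame(i = 1, j = 1, order = 1), 0),
               "self-bond")
  expect_error(molecule("x", at, data.frame(i = 1, j = 3, order = 1), 0),
               "out of range")
  expect_error(molecule("x", at, data.frame(i = c(1, 2), j = c(2, 1),
                                            order = c(1, 1)), 0),
               "duplicate bond")
  expect_error(molecule("bad id", at, data.frame(i = 1, j = 2, order = 1), 0),
               "whitespace")
  # set-level invariants
  m1 <- one_mol("CCO"); m2 <- one_mol("CCN"); m2$id <- m1$id
  expect_error(molecule_set(list(m1, m2)), "duplicate molecule ids")
})
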