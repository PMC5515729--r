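test_that("the pattern library carries the four complex ring transforms verbatim", {
  pats <- builtin_patterns()
  expect_gte(nrow(pats), 8)
  ring <- c(
    cyclization =
      "[C:1]([NH2])[C:2][C:3][C:4](=O)O>>[C:1]1[C:2][C:3][C:4](=O)N1",
    ring_opening =
      "[C:1][N:2]1[C:3][C:4][C:5][C:6][C:7]1>>[C:1][N:2][C:3][C:4][C:5][C:6][C:7](=O)O",
    ring_contraction =
      "[c:1]1[c:2][C:3]=[N:4][C:5](O)[C:6](=O)[N:7]1>>[c:1]1[c:2][C:3]=[N:4][C:5](=O)[N:7]1.[C:6]",
    ring_expansion =
      "[C:1]1[C:2][C:3][C:4][C:5]1(O)(C#C)>>[C:1]1[C:2][C:3][C:4]C[C:5]1(O)")
  for (id in names(ring)) {
    expect_identical(pats$reaction_smarts[pats$pattern_id == id],
                     unname(ring[id]), label = id)
  }
})

test_that("every pattern regenerates a product on its class template", {
  pats <- builtin_patterns()
  templates <- c(
    O_demethyl = "COc1ccccc1", N_demethyl = "CN(C)c1ccccc1",
    S_demethyl = "CSc1ccccc1", arom_hydroxyl = "Cc1ccccc1",
    O_glucuronide = "Oc1ccccc1", ester_hydrolysis = "CC(=O)OCC",
    cyclization = "NCCCC(=O)O", ring_opening = "CN1CCCCC1",
    ring_contraction = "O=C1Nc2ccccc2C=NC1O",
    ring_expansion = "C#CC1(O)CCCC1")
  for (id in names(templates)) {
    mol <- parse_smiles(templates[[id]])[[1]]
    rxn <- parse_reaction_smarts(
      pats$reaction_smarts[pats$pattern_id == id])
    res <- apply_reaction(mol, rxn)
    prods <- unlist(lapply(res, `[[`, "products"))
    expect_gte(length(prods), 1)
  }
  # demethylation of anisole gives phenol
  res <- apply_reaction(parse_smiles("COc1ccccc1")[[1]],
                        pats$reaction_smarts[pats$pattern_id == "O_demethyl"])
  expect_identical(res[[1]]$products, canonical_smiles("Oc1ccccc1"))
})

test_that("dataset generation is deterministic per seed", {
  m1 <- generate_dataset(seed = 7, n_per_class = 3)
  m2 <- generate_dataset(seed = 7, n_per_class = 3)
  expect_identical(m1$hash, m2$hash)
  expect_identical(m1$records$reaction_smiles, m2$records$reaction_smiles)
  m3 <- generate_dataset(seed = 8, n_per_class = 3)
  expect_false(identical(m1$hash, m3$hash))
  expect_equal(nrow(m1$records), 3 * 8)
})

test_that("every record's product equals its pattern applied at its SOM", {
  man <- fx_manifest()
  for (i in seq_len(nrow(man$records))) {
    rec <- man$records[i, ]
    mol <- parse_smiles(metsite:::substrate_smiles(rec$reaction_smiles))[[1]]
    pat <- as.list(man$patterns[man$patterns$pattern_id == rec$pattern_id, ])
    res <- apply_reaction(mol, pat$reaction_smarts,
                          anchor_atom = rec$som_atoms[[1]][1],
                          anchor_map = pat$center_map)
    prods <- unique(unlist(lapply(res, `[[`, "products")))
    stored <- metsite:::product_components(rec$reaction_smiles)
    expect_true(all(stored %in% prods), label = rec$record_id)
  }
})

test_that("the holdout split is disjoint, stratified and about 20%", {
  man <- generate_dataset(seed = 7, n_per_class = 10)
  r <- man$records
  expect_setequal(unique(r$split), c("train", "holdout"))
  expect_equal(sum(r$split == "holdout"), length(man$holdout_ids))
  expect_length(intersect(r$record_id[r$split == "train"],
                          man$holdout_ids), 0)
  per_class <- table(r$pattern_id[r$split == "holdout"])
  expect_true(all(per_class == 2))   # 20% of 10 per class
})

test_that("decoys parse and avoid the reactive chemistry", {
  man <- fx_manifest()
  mols <- parse_smiles(man$decoys)
  expect_false(any(vapply(mols, is.null, TRUE)))
  pats <- man$patterns
  for (m in mols) {
    for (i in seq_len(nrow(pats))) {
      if (pats$pattern_id[i] == "arom_hydroxyl") next
      rxn <- metsite:::compiled_reaction(pats$reaction_smarts[i])
      expect_length(
        metsite:::match_smarts(m, rxn$reactant),
        0)
    }
  }
})

test_that("an exhausted substituent vocabulary is a fatal error", {
  expect_error(generate_dataset(seed = 1, n_per_class = 99), "vocabulary")
  expect_error(generate_dataset(seed = 1, n_per_class = 1), "n_per_class")
  expect_error(generate_dataset(seed = 1, n_per_class = 3,
                                classes = "nope"), "unknown")
})

test_that("fixture files are written completely", {
  man <- generate_dataset(seed = 3, n_per_class = 2)
  dir <- withr::local_tempdir()
  write_fixture_files(man, dir)
  expect_true(all(file.exists(file.path(
    dir, c("reactions.tsv", "patterns.tsv", "holdout.tsv", "decoys.smi",
           "manifest.json")))))
  mjson <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mjson$n_records, nrow(man$records))
  expect_identical(mjson$hash, man$hash)
})
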