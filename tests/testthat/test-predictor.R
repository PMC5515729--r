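test_that("applicability anchors the reaction center at the query atom", {
  pats <- builtin_patterns()
  gaba <- parse_smiles("NCCCC(=O)O")[[1]]
  pat <- as.list(pats[pats$pattern_id == "cyclization", ])
  center <- soms_by_pattern(gaba, pat)
  res <- check_applicability(gaba, center, pat)
  expect_true(res$applicable)
  expect_identical(res$products, canonical_smiles("O=C1CCCN1"))
  # a different atom of the same molecule is not the center
  acid_c <- which(gaba$sybyl == "C.2")
  res2 <- check_applicability(gaba, acid_c, pat)
  expect_false(res2$applicable)
  # benzene has no match at all
  benz <- parse_smiles("c1ccccc1")[[1]]
  expect_false(check_applicability(benz, 1, pat)$applicable)
})

test_that("occurrence ratios follow the corrected-count formula", {
  db <- fx_db()
  sites <- predict_sites("COc1ccc(Br)cc1", db)
  expect_true(all(sites$x <= sites$n))
  expect_true(all(sites$n <= sites$m))
  for (i in seq_len(nrow(sites))) {
    want <- if (sites$m[i] > sites$x[i]) {
      (sites$n[i] - sites$x[i]) / (sites$m[i] - sites$x[i])
    } else 0
    expect_equal(sites$r[i], want)
  }
  # normalization: the best site scores exactly 1
  expect_true(any(sites$r > 0))
  expect_equal(max(sites$p), 1.0)
  expect_equal(sites$p, sites$r / max(sites$r))
})

test_that("molecules with no database chemistry score zero everywhere", {
  db <- fx_db()
  sites <- predict_sites("CCCC", db)
  expect_true(all(sites$p == 0))
  expect_true(all(sites$category == "very unlikely"))
  mets <- generate_metabolites(parse_smiles("CCCC")[[1]], sites)
  expect_equal(nrow(mets), 0)
})

test_that("likelihood categories use the printed half-open bins", {
  expect_identical(categorize(0.10), "very unlikely")
  expect_identical(categorize(0.1499), "very unlikely")
  expect_identical(categorize(0.15), "unlikely")
  expect_identical(categorize(0.42), "likely")
  expect_identical(categorize(0.66), "very likely")
  expect_identical(categorize(1.00), "very likely")
  expect_error(categorize(1.2), "\\[0, 1\\]")
  expect_error(categorize(-0.1), "\\[0, 1\\]")
})

test_that("ranking is by p descending with atom-index tie-break", {
  db <- fx_db()
  sites <- predict_sites("COc1ccc(Br)cc1", db)
  ord <- order(-sites$p, sites$atom_index)
  expect_identical(sites$rank[ord], seq_len(nrow(sites)))
})

test_that("fully corrected sites are excluded from metabolite generation", {
  # a center-db whose only pattern cannot apply to the query: train on
  # N-demethylation, query an anisole-like oxygen environment
  recs <- data.frame(record_id = "r1",
                     reaction_smiles = "CN(C)c1ccccc1>>CNc1ccccc1",
                     pattern_id = "N_demethyl", stringsAsFactors = FALSE)
  recs$som_atoms <- list(2L)
  ann <- annotate_dataset(recs, builtin_patterns())
  db <- build_databases(recs, ann, builtin_patterns())
  # query with the same molecule: N applies, so no correction there
  sites <- predict_sites("CN(C)c1ccccc1", db)
  n_at <- which(sites$element == "N")
  expect_gt(sites$r[n_at], 0)
  expect_equal(sites$x[n_at], 0)
})

test_that("injecting centers with inapplicable patterns never raises r", {
  man <- fx_manifest()
  tr <- fx_train()
  ann <- annotate_dataset(tr, man$patterns)
  db0 <- build_databases(tr, ann, man$patterns)

  # forge records whose center fingerprints mimic the O-demethylation
  # environment but carry a pattern that can never apply there
  forged <- tr[grepl("O_demethyl", tr$record_id), ]
  forged$record_id <- paste0(forged$record_id, "_forged")
  forged$pattern_id <- "cyclization"
  aug <- rbind(tr, forged)
  ann_aug <- annotate_dataset(aug, man$patterns)
  db1 <- build_databases(aug, ann_aug, man$patterns)

  bench <- fx_benchmark()
  for (id in names(bench$mols)[1:4]) {
    s0 <- predict_sites(bench$mols[[id]], db0)
    s1 <- predict_sites(bench$mols[[id]], db1)
    expect_true(all(s1$r <= s0$r + 1e-12), label = id)
  }
})

test_that("metabolites deduplicate by product and symmetric site", {
  db <- fx_db()
  res <- predict_metabolism("COc1ccc(Br)cc1", db)
  mets <- res$metabolites
  expect_gte(nrow(mets), 1)
  key <- paste(mets$product_smiles, mets$site_atom)
  expect_false(any(duplicated(key)))
  expect_identical(mets$rank, seq_len(nrow(mets)))
  # every product's generating pattern matches the parent at the stated site
  mol <- parse_smiles("COc1ccc(Br)cc1")[[1]]
  pats <- db$patterns
  for (i in seq_len(nrow(mets))) {
    pat <- as.list(pats[pats$pattern_id == mets$pattern_id[i], ])
    chk <- check_applicability(mol, mets$site_atom[i], pat)
    expect_true(chk$applicable)
    expect_true(mets$product_smiles[i] %in% chk$products)
  }
})

test_that("predictions are deterministic and build-order invariant", {
  man <- fx_manifest()
  tr <- fx_train()
  ann <- annotate_dataset(tr, man$patterns)
  db1 <- build_databases(tr, ann, man$patterns)
  set.seed(2)
  perm <- sample(nrow(tr))
  db2 <- build_databases(tr[perm, ], ann[perm, ], man$patterns)
  r1 <- predict_metabolism("COc1ccc(Cl)cc1", db1)
  r2 <- predict_metabolism("COc1ccc(Cl)cc1", db2)
  expect_identical(r1$sites[, -1], r2$sites[, -1])
  expect_identical(r1$metabolites$product_smiles,
                   r2$metabolites$product_smiles)
})

test_that("symmetric sites receive identical scores", {
  db <- fx_db()
  sites <- predict_sites("COc1ccccc1", db)
  mol <- parse_smiles("COc1ccccc1")[[1]]
  eq <- metsite:::atom_equiv_classes(mol)
  for (cl in unique(eq)) {
    expect_length(unique(sites$p[eq == cl]), 1)
  }
})
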