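one_record_db <- function() {
  recs <- data.frame(record_id = "r1",
                     reaction_smiles = "COc1ccccc1>>Oc1ccccc1",
                     pattern_id = "O_demethyl", stringsAsFactors = FALSE)
  recs$som_atoms <- list(2L)   # the ether oxygen
  ann <- annotate_dataset(recs, builtin_patterns())
  build_databases(recs, ann, builtin_patterns())
}

test_that("occurrence counts aggregate every substrate atom and SOM", {
  db <- one_record_db()
  expect_equal(db$manifest$substrate_occurrences, 8)  # anisole heavy atoms
  expect_equal(db$manifest$center_occurrences, 1)
  # duplicate substrates aggregate under the same keys
  recs2 <- data.frame(
    record_id = c("r1", "r2"),
    reaction_smiles = c("COc1ccccc1>>Oc1ccccc1", "COc1ccccc1>>COc1ccccc1O"),
    pattern_id = c("O_demethyl", "arom_hydroxyl"), stringsAsFactors = FALSE)
  recs2$som_atoms <- list(2L, 4L)
  ann2 <- annotate_dataset(recs2, builtin_patterns())
  db2 <- build_databases(recs2, ann2, builtin_patterns())
  expect_equal(db2$manifest$substrate_occurrences, 16)
  o_key <- fp_key(atom_fingerprint(parse_smiles("COc1ccccc1")[[1]], 2))
  expect_equal(db2$substrate[[o_key]]$count, 2)
})

test_that("annotations referencing unknown records are fatal", {
  recs <- data.frame(record_id = "r1",
                     reaction_smiles = "COc1ccccc1>>Oc1ccccc1",
                     pattern_id = "O_demethyl", stringsAsFactors = FALSE)
  recs$som_atoms <- list(2L)
  ann <- annotate_dataset(recs, builtin_patterns())
  ann$record_id <- "ghost"
  expect_error(build_databases(recs, ann, builtin_patterns()),
               "unknown record")
})

test_that("center keys are contained in substrate keys with <= counts", {
  db <- fx_db()
  for (k in names(db$center)) {
    expect_true(k %in% names(db$substrate), label = k)
    expect_lte(db$center[[k]]$count, db$substrate[[k]]$count)
    expect_equal(db$center[[k]]$count, sum(db$center[[k]]$patterns))
  }
})

test_that("identical stored fingerprints are retrieved as exact hits", {
  db <- one_record_db()
  mol <- parse_smiles("COc1ccccc1")[[1]]
  fp <- atom_fingerprint(mol, 2)
  q <- db_query(db, fp)
  expect_gte(q$m, 1)
  expect_equal(q$n, 1)
  keys <- vapply(q$m_hits, `[[`, "", "key")
  expect_true(fp_key(fp) %in% keys)
})

test_that("a layer-1 mismatch defeats retrieval regardless of score", {
  db <- one_record_db()
  fp <- fp_from_key("O.3=1|N.3=1;C.ar=1|C.3=1;C.ar=2|C.ar=2|C.ar=1|PAD=1")
  q <- db_query(db, fp)
  expect_equal(q$m, 0)
  expect_equal(q$n, 0)
})

test_that("query results equal a brute-force linear scan on the fixture db", {
  db <- fx_db()
  bench <- fx_benchmark()
  params <- similarity_params()
  for (id in names(bench$mols)[1:4]) {
    mol <- bench$mols[[id]]
    for (fp in molecule_fingerprints(mol)) {
      got <- db_query(db, fp, params)
      want <- naive_db_scan(db, fp, params$exact_depth, params$threshold)
      expect_equal(got$m, want$m, label = paste(id, "m"))
      expect_equal(got$n, want$n, label = paste(id, "n"))
    }
  }
})

test_that("shallow exact-match depths fall back to the full scan", {
  db <- fx_db()
  mol <- fx_benchmark()$mols[[1]]
  fp <- molecule_fingerprints(mol)[[1]]
  for (d in c(1L, 2L)) {
    params <- similarity_params(exact_depth = d)
    got <- db_query(db, fp, params)
    want <- naive_db_scan(db, fp, d, params$threshold)
    expect_equal(got$m, want$m)
    expect_equal(got$n, want$n)
  }
})

test_that("alphabet and layer mismatches are version errors", {
  db <- one_record_db()
  fp <- atom_fingerprint(parse_smiles("CO")[[1]], 1)
  attr(fp, "alphabet_version") <- "other/9"
  expect_error(db_query(db, fp), "alphabet")
  fp8 <- atom_fingerprint(parse_smiles("CO")[[1]], 1, n_layers = 4)
  expect_error(db_query(db, fp8), "layers")
})

test_that("save/load round-trips to identical query behavior", {
  db <- fx_db()
  dir <- withr::local_tempdir()
  db_save(db, dir)
  db2 <- db_load(dir)
  expect_identical(db2$manifest$content_hash, db$manifest$content_hash)
  mol <- fx_benchmark()$mols[[1]]
  for (fp in molecule_fingerprints(mol)[1:4]) {
    a <- db_query(db, fp)
    b <- db_query(db2, fp)
    expect_equal(a$m, b$m)
    expect_equal(a$n, b$n)
  }
  # truncation is detected
  jl <- file.path(dir, "substrate.jsonl")
  lines <- readLines(jl)
  writeLines(lines[-1], jl)
  expect_error(db_load(dir), "corrupt")
})

test_that("an empty database round-trips", {
  recs <- data.frame(record_id = character(0),
                     reaction_smiles = character(0),
                     pattern_id = character(0), stringsAsFactors = FALSE)
  recs$som_atoms <- list()
  ann <- data.frame(record_id = character(0), method = character(0),
                    stringsAsFactors = FALSE)
  ann$som_atoms <- list()
  db <- build_databases(recs, ann, builtin_patterns())
  dir <- withr::local_tempdir()
  db_save(db, dir)
  db2 <- db_load(dir)
  expect_length(db2$substrate, 0)
  expect_length(db2$center, 0)
})

test_that("the build is order-independent", {
  man <- fx_manifest()
  tr <- man$records[man$records$split == "train", ]
  ann <- annotate_dataset(tr, man$patterns)
  db1 <- build_databases(tr, ann, man$patterns)
  set.seed(5)
  perm <- sample(nrow(tr))
  db2 <- build_databases(tr[perm, ], ann[perm, ], man$patterns)
  expect_identical(db1$manifest$content_hash, db2$manifest$content_hash)
})
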