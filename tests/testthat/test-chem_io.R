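write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("reaction TSV records map fields and 0-based SOM indices", {
  path <- write_tsv_lines(c(
    "# fixture",
    "r1\tCOc1ccccc1>>Oc1ccccc1\tO_demethyl\t1",
    "r2\tCc1ccccc1>>OCc1ccccc1"))
  recs <- read_reactions(path)
  expect_equal(nrow(recs), 2)
  expect_identical(recs$record_id, c("r1", "r2"))
  expect_identical(recs$pattern_id, c("O_demethyl", NA))
  expect_identical(recs$som_atoms[[1]], 2L)   # file index 1 -> R index 2
  expect_null(recs$som_atoms[[2]])
})

test_that("unparseable reaction lines are skipped and counted", {
  path <- write_tsv_lines(c(
    "r1\tCOc1ccccc1>>Oc1ccccc1",
    "bad\tC(>>C",
    "noarrow\tCCO"))
  expect_warning(recs <- read_reactions(path), "skipped 2")
  expect_equal(nrow(recs), 1)
  expect_equal(attr(recs, "n_skipped"), 2)
  empty <- write_tsv_lines("zz\tC(>>C")
  expect_error(suppressWarnings(read_reactions(empty)), "no parseable")
  expect_error(read_reactions(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("fixture files round-trip through the reaction reader", {
  man <- fx_manifest()
  dir <- withr::local_tempdir()
  write_fixture_files(man, dir)
  recs <- read_reactions(file.path(dir, "reactions.tsv"))
  expect_equal(nrow(recs), nrow(man$records))
  i <- match("O_demethyl_01", recs$record_id)
  j <- match("O_demethyl_01", man$records$record_id)
  expect_identical(recs$som_atoms[[i]], man$records$som_atoms[[j]])
})

test_that("curation applies the five filters and is idempotent", {
  path <- write_tsv_lines(c(
    "a1\tCOc1ccccc1>>Oc1ccccc1\tO_demethyl\t1",
    "a2\tCOc1ccccc1>>Oc1ccccc1\tO_demethyl\t1",      # duplicate
    "a3\t[CH2]CC>>CCC",                               # radical reactant
    "a4\tCC(=O)O[Pt]>>[Pt]",                          # single-element product
    "a5\tc1ccccc1>>c1ccccc1",                         # identity: ambiguous
    "a6\tCc1ccccc1>>OCc1ccccc1"))
  recs <- suppressWarnings(read_reactions(path))
  cur <- curate_reactions(recs)
  expect_setequal(cur$record_id, c("a1", "a6"))
  fc <- attr(cur, "filter_counts")
  expect_equal(unname(fc["duplicate"]), 1L)
  expect_gte(unname(fc["dummy_or_radical"]), 1L)
  expect_equal(unname(fc["single_element"]), 1L)
  expect_equal(unname(fc["ambiguous_center"]), 1L)
  # idempotence
  cur2 <- curate_reactions(cur)
  expect_identical(cur2$record_id, cur$record_id)
  expect_identical(cur2$reaction_smiles, cur$reaction_smiles)
})

test_that("dedup uses canonical reaction identity, not the literal string", {
  path <- write_tsv_lines(c(
    "b1\tCOc1ccccc1>>Oc1ccccc1",
    "b2\tc1ccccc1OC>>c1ccccc1O"))   # same reaction, different writing
  recs <- read_reactions(path)
  cur <- curate_reactions(recs)
  expect_equal(nrow(cur), 1)
})

test_that("pattern libraries are read with compile validation", {
  path <- write_tsv_lines(c(
    "pattern_id\tname\treaction_smarts\tcenter_map",
    paste0("cycl\tCyclization\t",
           "[C:1]([NH2])[C:2][C:3][C:4](=O)O>>[C:1]1[C:2][C:3][C:4](=O)N1",
           "\t1"),
    "bad\tEmpty product\tC>>",
    "bad2\tNo maps\tCC>>CC"))
  # both bad patterns warn: one per rejection
  expect_warning(expect_warning(pats <- read_patterns(path), "rejected"),
                 "rejected")
  expect_equal(nrow(pats), 1)
  expect_identical(pats$pattern_id, "cycl")
  expect_equal(pats$center_map, 1L)
})

test_that("the built-in pattern library compiles completely", {
  pats <- builtin_patterns()
  expect_gte(nrow(pats), 8)
  for (i in seq_len(nrow(pats))) {
    expect_error(parse_reaction_smarts(pats$reaction_smarts[i]), NA)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patterns(pats, path)
  back <- read_patterns(path)
  expect_identical(back$reaction_smarts, pats$reaction_smarts)
  expect_identical(back$center_map, pats$center_map)
})

test_that("prediction writers emit one TSV row per site, one SDF record per metabolite", {
  db <- fx_db()
  res <- predict_metabolism("COc1ccc(Br)cc1", db)
  prefix <- file.path(withr::local_tempdir(), "out")
  paths <- write_predictions(res$sites, res$metabolites, prefix)
  tsv <- read.delim(paths[["sites"]])
  expect_equal(nrow(tsv), 9)   # bromoanisole: 9 heavy atoms
  expect_true(all(c("m", "n", "x", "r", "p", "category", "rank") %in%
                    names(tsv)))
  expect_equal(sort(tsv$atom_index), 0:8)
  sdf_text <- readLines(paths[["metabolites"]])
  expect_equal(sum(sdf_text == "$$$$"), nrow(res$metabolites))
  # SDF round-trip: stored structures equal the in-memory products
  mols <- read_molecules(paths[["metabolites"]])
  expect_setequal(
    vapply(mols, function(m) m$smiles, ""),
    unique(canonical_smiles(res$metabolites$product_smiles)))
})

test_that("zero metabolites still creates an (empty) SDF", {
  db <- fx_db()
  res <- predict_metabolism("CCCC", db)   # no database chemistry
  expect_equal(nrow(res$metabolites), 0)
  prefix <- file.path(withr::local_tempdir(), "none")
  paths <- write_predictions(res$sites, res$metabolites, prefix)
  expect_true(file.exists(paths[["metabolites"]]))
  expect_equal(sum(readLines(paths[["metabolites"]]) == "$$$$"), 0)
})
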