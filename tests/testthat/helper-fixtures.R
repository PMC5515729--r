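# Shared fixture objects, built once per test run.

.fx <- new.env()

fx_manifest <- function() {
  if (is.null(.fx$manifest)) {
    .fx$manifest <- generate_dataset(seed = 7, n_per_class = 4)
  }
  .fx$manifest
}

fx_train <- function() {
  man <- fx_manifest()
  man$records[man$records$split == "train", , drop = FALSE]
}

fx_db <- function() {
  if (is.null(.fx$db)) {
    man <- fx_manifest()
    tr <- fx_train()
    ann <- annotate_dataset(tr, man$patterns)
    .fx$db <- build_databases(tr, ann, man$patterns)
  }
  .fx$db
}

fx_holdout <- function() {
  man <- fx_manifest()
  man$records[man$records$split == "holdout", , drop = FALSE]
}

# Named molgraphs + truth for the holdout split.
fx_benchmark <- function() {
  if (is.null(.fx$benchmark)) {
    ho <- fx_holdout()
    smis <- metsite:::substrate_smiles(ho$reaction_smiles)
    mols <- parse_smiles(smis, ids = ho$record_id)
    truth <- ho$som_atoms
    names(truth) <- ho$record_id
    truth_mets <- lapply(ho$reaction_smiles, function(rs)
      metsite:::product_components(rs))
    names(truth_mets) <- ho$record_id
    .fx$benchmark <- list(mols = mols, truth = truth,
                          truth_metabolites = truth_mets)
  }
  .fx$benchmark
}
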