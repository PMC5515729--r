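# Deterministic synthetic metabolic-reaction dataset.
#
# Emulates the statistical structure the similarity model relies on: each
# reaction class contributes many substrates that share the reaction-center
# atom environment (substituent decoration of a class template), plus
# decoy molecules with similar non-center chemistry.  Every record carries
# its generating pattern and ground-truth SOMs, and its stored product is
# exactly the pattern applied at the SOM, so annotation methods can be
# validated against the generator.

#' Built-in reaction SMARTS pattern library
#'
#' Covers O/N/S-demethylation, aromatic hydroxylation, phenol
#' O-glucuronidation, ester hydrolysis, and the four complex ring reaction
#' classes (cyclization, ring opening, ring contraction, ring expansion).
#' All patterns compile; each carries its designated reaction-center map
#' number.
#'
#' @return a pattern record data frame (`pattern_id`, `name`,
#'   `reaction_smarts`, `center_map`).
#' @export
#' @examples
#' nrow(builtin_patterns()) >= 8
builtin_patterns <- function() {
  p <- rbind(
    c("O_demethyl", "O-demethylation",
      "[OX2:1][CH3]>>[O:1]", 1),
    c("N_demethyl", "N-demethylation",
      "[NX3:1][CH3]>>[N:1]", 1),
    c("S_demethyl", "S-demethylation",
      "[SX2:1][CH3]>>[S:1]", 1),
    c("arom_hydroxyl", "Aromatic hydroxylation",
      "[cH:1]>>[c:1]O", 1),
    c("O_glucuronide", "Phenol O-glucuronidation",
      "[OH:1][c:2]>>[c:2][O:1]C1OC(C(=O)O)C(O)C(O)C1O", 1),
    c("ester_hydrolysis", "Ester hydrolysis",
      "[C:1](=[O:2])[O:3][CX4:4]>>[C:1](=[O:2])[O:3].O[C:4]", 1),
    c("cyclization", "Cyclization",
      "[C:1]([NH2])[C:2][C:3][C:4](=O)O>>[C:1]1[C:2][C:3][C:4](=O)N1", 1),
    c("ring_opening", "Ring opening",
      "[C:1][N:2]1[C:3][C:4][C:5][C:6][C:7]1>>[C:1][N:2][C:3][C:4][C:5][C:6][C:7](=O)O", 7),
    c("ring_contraction", "Ring contraction",
      "[c:1]1[c:2][C:3]=[N:4][C:5](O)[C:6](=O)[N:7]1>>[c:1]1[c:2][C:3]=[N:4][C:5](=O)[N:7]1.[C:6]", 6),
    c("ring_expansion", "Ring expansion",
      "[C:1]1[C:2][C:3][C:4][C:5]1(O)(C#C)>>[C:1]1[C:2][C:3][C:4]C[C:5]1(O)", 5)
  )
  data.frame(pattern_id = p[, 1], name = p[, 2], reaction_smarts = p[, 3],
             center_map = as.integer(p[, 4]), stringsAsFactors = FALSE)
}

# Class templates: substituent decoration site marked %s; para-substituted
# aromatics and branch-substituted aliphatics keep the reaction-center
# environment constant across a class while varying the periphery.
.fixture_classes <- list(
  O_demethyl      = "COc1ccc(%s)cc1",
  N_demethyl      = "CN(C)c1ccc(%s)cc1",
  S_demethyl      = "CSc1ccc(%s)cc1",
  O_glucuronide   = "Oc1ccc(%s)cc1",
  cyclization     = "NCC(%s)CC(=O)O",
  ring_opening    = "CN1CCC(%s)CC1",
  ring_contraction = "O=C1Nc2ccc(%s)cc2C=NC1O",
  ring_expansion  = "C#CC1(O)CCC(%s)C1",
  arom_hydroxyl   = "Cc1ccc(%s)cc1"
)

# Chemically inert substituents (no competing reactive group).
.fixture_substituents <- c("", "C", "CC", "CCC", "C(C)C", "C(C)(C)C",
                           "CC(C)C", "Cl", "F", "Br", "I", "C#N",
                           "C(F)(F)F", "CCl")

.fixture_decoys <- c("c1ccccc1", "Clc1ccccc1", "Fc1ccccc1", "Brc1ccccc1",
                     "C1CCCCC1", "CC1CCCCC1", "CCCCCC", "CCOCC",
                     "FC(F)(F)c1ccccc1", "CC(C)CC(C)C", "ClCCCl",
                     "Cc1ccc(C)cc1")

attach_substituent <- function(template, sub) {
  if (nzchar(sub)) sprintf(template, sub)
  else gsub("(%s)", "", template, fixed = TRUE)
}

#' Generate the synthetic reaction dataset
#'
#' For each reaction class, decorates the class template with substituents
#' from a fixed vocabulary (order shuffled by `seed`), computes the product
#' by applying the class pattern at its reaction center, and records the
#' pattern-derived ground-truth SOMs.  One in five records is tagged as
#' holdout.  Identical seeds give byte-identical manifests.
#'
#' @param seed integer seed controlling substituent selection and the
#'   holdout split.
#' @param n_per_class records per class (>= 2; the substituent vocabulary
#'   bounds it).
#' @param classes class names to generate (default: eight classes — the
#'   O/N/S-demethylations, phenol glucuronidation and the four ring
#'   reaction classes; aromatic hydroxylation is available on request, see
#'   the package vignette for why it is not a default).
#' @return an object of class `fixture_manifest`: a list with `seed`,
#'   `n_per_class`, `classes`, `records` (reaction record data frame with
#'   `som_atoms` and a `split` column), `patterns`, `decoys` (SMILES
#'   vector), `holdout_ids` and `hash`.
#' @export
generate_dataset <- function(seed = 7L, n_per_class = 10L,
                             classes = setdiff(names(.fixture_classes),
                                               "arom_hydroxyl")) {
  stopifnot(n_per_class >= 2)
  unknown <- setdiff(classes, names(.fixture_classes))
  if (length(unknown)) stop("unknown reaction class: ",
                            paste(unknown, collapse = ", "))
  if (n_per_class > length(.fixture_substituents)) {
    stop("substituent vocabulary exhausted: n_per_class must be <= ",
         length(.fixture_substituents))
  }
  patterns <- builtin_patterns()

  # seeded, state-restoring RNG use
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  rows <- list()
  for (cls in classes) {
    template <- .fixture_classes[[cls]]
    subs <- sample(.fixture_substituents)[seq_len(n_per_class)]
    pat <- as.list(patterns[patterns$pattern_id == cls, ])
    for (si in seq_along(subs)) {
      smi <- attach_substituent(template, subs[si])
      mol <- parse_smiles(smi)[[1]]
      if (is.null(mol)) stop("fixture template failed to parse: ", smi)
      som <- soms_by_pattern(mol, pat)
      res <- apply_reaction(mol, compiled_reaction(pat$reaction_smarts),
                            anchor_atom = som[1],
                            anchor_map = pat$center_map)
      prods <- res[[1]]$products
      if (!length(prods)) stop("fixture pattern failed on its template: ",
                               cls, " / ", smi)
      rows[[length(rows) + 1L]] <- list(
        record_id = sprintf("%s_%02d", cls, si),
        reaction_smiles = paste0(mol$smiles, ">>",
                                 paste(prods, collapse = ".")),
        pattern_id = cls,
        som_atoms = som)
    }
  }
  records <- data.frame(
    record_id = vapply(rows, `[[`, "", "record_id"),
    reaction_smiles = vapply(rows, `[[`, "", "reaction_smiles"),
    pattern_id = vapply(rows, `[[`, "", "pattern_id"),
    stringsAsFactors = FALSE)
  records$som_atoms <- lapply(rows, `[[`, "som_atoms")

  # 20% holdout, stratified by class
  split <- rep("train", nrow(records))
  for (cls in classes) {
    ix <- which(records$pattern_id == cls)
    n_hold <- max(1L, floor(length(ix) / 5))
    split[sample(ix)[seq_len(n_hold)]] <- "holdout"
  }
  records$split <- split

  decoys <- canonical_smiles(.fixture_decoys)
  decoys <- decoys[!is.na(decoys)]

  man <- list(seed = as.integer(seed), n_per_class = as.integer(n_per_class),
              classes = classes, records = records,
              patterns = patterns[patterns$pattern_id %in%
                                    c(classes, "arom_hydroxyl",
                                      "ester_hydrolysis"), ],
              decoys = decoys,
              holdout_ids = records$record_id[split == "holdout"])
  man$hash <- digest::digest(
    list(man$seed, man$n_per_class, man$classes, man$records$record_id,
         man$records$reaction_smiles, man$records$pattern_id,
         lapply(man$records$som_atoms, as.integer), man$records$split,
         man$decoys),
    algo = "sha256")
  class(man) <- "fixture_manifest"
  man
}

#' @export
print.fixture_manifest <- function(x, ...) {
  cat(sprintf(
    "<fixture_manifest seed=%d: %d records in %d classes (%d holdout), %d decoys>\n",
    x$seed, nrow(x$records), length(x$classes), length(x$holdout_ids),
    length(x$decoys)))
  invisible(x)
}

#' Write fixture dataset files
#'
#' Writes `reactions.tsv` (all records), `patterns.tsv`, `holdout.tsv`
#' (record ids), `decoys.smi` and `manifest.json` under `dir`.
#'
#' @param manifest a `fixture_manifest`.
#' @param dir output directory (created if missing).
#' @return invisibly, `dir`.
#' @export
write_fixture_files <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- manifest$records
  tsv <- data.frame(
    record_id = r$record_id,
    reaction_smiles = r$reaction_smiles,
    pattern_id = r$pattern_id,
    som_atoms = vapply(r$som_atoms, function(x)
      paste(x - 1L, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tsv, file.path(dir, "reactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_patterns(manifest$patterns, file.path(dir, "patterns.tsv"))
  writeLines(manifest$holdout_ids, file.path(dir, "holdout.tsv"))
  writeLines(manifest$decoys, file.path(dir, "decoys.smi"))
  jsonlite::write_json(
    list(seed = manifest$seed, n_per_class = manifest$n_per_class,
         classes = manifest$classes, n_records = nrow(r),
         holdout_ids = manifest$holdout_ids, hash = manifest$hash),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
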