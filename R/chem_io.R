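# Reading, curating and writing the artifact's tabular and chemical formats.
#
# Reaction datasets are tables with one record per metabolic reaction:
# record_id, reaction SMILES "substrate(s)>>product(s)", an optional
# reaction-SMARTS pattern id, and optional ground-truth SOM atom indices.
# Atom indices are 0-based over heavy atoms in canonical substrate order in
# all files; in memory, R-style 1-based indices are used throughout.

#' Read a metabolic reaction dataset
#'
#' @param path input file (or directory for `dialect = "rxn-dir"`).
#' @param dialect one of `"tsv"` (tab-separated: record_id,
#'   reaction_smiles, optional pattern_id, optional comma-separated 0-based
#'   som_atoms; `#` comments), `"rxn-dir"` (a directory of MDL `.rxn`
#'   files) or `"sdf-pairs"` (an SDF whose records alternate substrate,
#'   product).
#' @return a data frame of reaction records with columns `record_id`,
#'   `reaction_smiles`, `pattern_id` (`NA` when absent) and `som_atoms`
#'   (list column of 1-based integer vectors, `NULL` when absent).
#'   Unparseable lines are skipped with a warning; the number skipped is
#'   attached as attribute `n_skipped`.
#' @export
read_reactions <- function(path, dialect = c("tsv", "rxn-dir", "sdf-pairs")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("reaction input not found: ", path)
  if (dialect == "tsv") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    recs <- lapply(parts, function(p) {
      if (length(p) < 2) return(NULL)
      list(record_id = p[1], reaction_smiles = p[2],
           pattern_id = if (length(p) >= 3 && nzchar(p[3])) p[3]
                        else NA_character_,
           som_raw = if (length(p) >= 4 && nzchar(p[4])) p[4]
                     else NA_character_)
      })
  } else if (dialect == "rxn-dir") {
    files <- sort(list.files(path, pattern = "\\.rxn$", full.names = TRUE))
    recs <- lapply(files, function(f) {
      smi <- ob_convert("RXN", "SMI",
                        paste(readLines(f, warn = FALSE), collapse = "\n"))
      smi <- trimws(strsplit(smi, "\n")[[1]][1])
      smi <- strsplit(smi, "[[:space:]]+")[[1]][1]
      if (!nzchar(smi) || is.na(smi)) return(NULL)
      smi <- sub(">[^>]*>", ">>", smi)   # drop agents
      list(record_id = sub("\\.rxn$", "", basename(f)),
           reaction_smiles = smi, pattern_id = NA_character_,
           som_raw = NA_character_)
    })
  } else {
    mols <- read_molecules(path)
    mols <- mols[!vapply(mols, is.null, TRUE)]
    if (length(mols) %% 2 != 0) {
      warning("sdf-pairs input has an odd molecule count; last one dropped")
      mols <- mols[-length(mols)]
    }
    recs <- lapply(seq_len(length(mols) / 2), function(i) {
      s <- mols[[2 * i - 1]]; p <- mols[[2 * i]]
      list(record_id = paste0("pair", i),
           reaction_smiles = paste0(s$smiles, ">>", p$smiles),
           pattern_id = NA_character_, som_raw = NA_character_)
    })
  }

  n_skipped <- sum(vapply(recs, is.null, TRUE))
  recs <- recs[!vapply(recs, is.null, TRUE)]
  # validate: reaction SMILES must have >= 1 parseable molecule per side
  keep <- logical(length(recs))
  som_atoms <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    sides <- strsplit(r$reaction_smiles, ">>", fixed = TRUE)[[1]]
    ok <- length(sides) == 2 && all(nzchar(trimws(sides))) &&
      all(vapply(sides, smiles_syntax_ok, TRUE))
    if (ok) {
      can <- canonical_smiles(sides)
      ok <- !anyNA(can)
    }
    if (ok && !is.na(r$som_raw)) {
      idx <- suppressWarnings(as.integer(strsplit(r$som_raw, ",")[[1]]))
      if (anyNA(idx) || any(idx < 0)) {
        ok <- FALSE
      } else {
        som_atoms[[i]] <- idx + 1L   # file 0-based -> memory 1-based
      }
    }
    keep[i] <- ok
  }
  n_skipped <- n_skipped + sum(!keep)
  if (n_skipped > 0) {
    warning(sprintf("skipped %d unparseable reaction record(s)", n_skipped))
  }
  recs <- recs[keep]
  som_atoms <- som_atoms[keep]
  if (!length(recs)) stop("no parseable reaction records in ", path)
  out <- data.frame(
    record_id = vapply(recs, `[[`, "", "record_id"),
    reaction_smiles = vapply(recs, `[[`, "", "reaction_smiles"),
    pattern_id = vapply(recs, `[[`, "", "pattern_id"),
    stringsAsFactors = FALSE
  )
  out$som_atoms <- som_atoms
  attr(out, "n_skipped") <- n_skipped
  out
}

# Cheap syntactic screen (OpenBabel silently repairs some broken SMILES):
# parentheses, brackets and ring-bond digits must balance.
smiles_syntax_ok <- function(s) {
  chars <- strsplit(s, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")")) return(FALSE)
  if (sum(chars == "[") != sum(chars == "]")) return(FALSE)
  digits <- gsub("\\[[^]]*\\]", "", s)          # maps inside brackets aside
  digits <- gsub("%[0-9]{2}", "", digits)
  counts <- table(strsplit(gsub("[^0-9]", "", digits), "")[[1]])
  all(counts %% 2 == 0)
}

# Canonical reaction SMILES: both sides' components canonicalized, sorted
# and dot-joined.  Defines reaction identity for deduplication.
canonical_reaction_smiles <- function(reaction_smiles) {
  vapply(reaction_smiles, function(rs) {
    sides <- strsplit(rs, ">>", fixed = TRUE)[[1]]
    if (length(sides) != 2) return(NA_character_)
    side_can <- vapply(sides, function(s) {
      comps <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
      can <- canonical_smiles(comps)
      if (anyNA(can)) return(NA_character_)
      paste(sort(can), collapse = ".")
    }, "")
    if (anyNA(side_can)) return(NA_character_)
    paste(side_can, collapse = ">>")
  }, "", USE.NAMES = FALSE)
}

# Substrate of a record: the largest reactant component by heavy atoms
# (cofactors on multi-substrate records are retained on the pattern side
# only).  Returns a canonical SMILES string.
substrate_smiles <- function(reaction_smiles) {
  vapply(reaction_smiles, function(rs) {
    left <- strsplit(rs, ">>", fixed = TRUE)[[1]][1]
    comps <- strsplit(trimws(left), ".", fixed = TRUE)[[1]]
    if (length(comps) == 1) return(comps)
    sizes <- nchar(gsub("[^A-Za-z]", "", comps))   # crude but order-stable
    comps[which.max(sizes)]
  }, "", USE.NAMES = FALSE)
}

product_components <- function(reaction_smiles) {
  right <- strsplit(reaction_smiles, ">>", fixed = TRUE)[[1]][2]
  strsplit(trimws(right), ".", fixed = TRUE)[[1]]
}

# Unfilled valence on C/N/O under standard valences marks a free radical.
has_radical <- function(mol) {
  for (i in seq_len(mol$n)) {
    el <- mol$elem[i]
    if (!el %in% c("C", "N", "O")) next
    bsum <- 0
    for (k in seq_along(mol$adj[[i]])) {
      bsum <- bsum + bond_order_num(mol$border[[i]][k])
    }
    if (bsum + mol$hcount[i] < .default_valence[el] + mol$charge[i]) {
      return(TRUE)
    }
  }
  FALSE
}

#' Curate a reaction dataset
#'
#' Applies the five curation filters: (1) duplicate reactions (by canonical
#' reaction SMILES) collapse to one record; (2) records with R-group dummy
#' atoms or free radicals are dropped; (3) records with missing/invalid
#' structures are dropped; (4) records with ambiguous reaction centers (no
#' pattern id, no provided SOMs, and an empty/undefined MCS diff) are
#' dropped; (5) records whose reactant or product side is a lone
#' single-element molecule are dropped.
#'
#' @param records a reaction record data frame from [read_reactions()].
#' @return the surviving records, with attribute `filter_counts` reporting
#'   removals per filter.  Curation is idempotent.
#' @export
curate_reactions <- function(records) {
  counts <- c(duplicate = 0L, dummy_or_radical = 0L, invalid = 0L,
              ambiguous_center = 0L, single_element = 0L)
  keep <- rep(TRUE, nrow(records))

  # (3) invalid structures (+ R-group "*" dummies textually)
  canrxn <- canonical_reaction_smiles(records$reaction_smiles)
  bad <- is.na(canrxn)
  counts["invalid"] <- sum(bad & keep)
  keep <- keep & !bad

  dummy <- grepl("*", records$reaction_smiles, fixed = TRUE)
  counts["dummy_or_radical"] <- sum(dummy & keep)
  keep <- keep & !dummy

  # (1) dedup on canonical reaction SMILES
  dup <- duplicated(canrxn) & keep
  counts["duplicate"] <- sum(dup)
  keep <- keep & !dup

  # per-record structural checks
  for (i in which(keep)) {
    rs <- records$reaction_smiles[i]
    sides <- strsplit(rs, ">>", fixed = TRUE)[[1]]
    comp_l <- strsplit(trimws(sides[1]), ".", fixed = TRUE)[[1]]
    comp_r <- strsplit(trimws(sides[2]), ".", fixed = TRUE)[[1]]
    mols <- parse_smiles(c(comp_l, comp_r))
    if (any(vapply(mols, is.null, TRUE))) {
      counts["invalid"] <- counts["invalid"] + 1L
      keep[i] <- FALSE
      next
    }
    # (5) a side that is a lone single-atom molecule
    nl <- vapply(mols[seq_along(comp_l)], function(m) m$n, 1L)
    nr <- vapply(mols[-seq_along(comp_l)], function(m) m$n, 1L)
    if ((length(nl) == 1 && nl == 1) || (length(nr) == 1 && nr == 1)) {
      counts["single_element"] <- counts["single_element"] + 1L
      keep[i] <- FALSE
      next
    }
    # (2) radicals
    if (any(vapply(mols, has_radical, TRUE))) {
      counts["dummy_or_radical"] <- counts["dummy_or_radical"] + 1L
      keep[i] <- FALSE
      next
    }
    # (4) ambiguous center: no pattern, no provided SOMs, MCS diff empty
    if (is.na(records$pattern_id[i]) &&
        is.null(records$som_atoms[[i]])) {
      sub <- parse_smiles(substrate_smiles(rs))[[1]]
      prods <- parse_smiles(comp_r)
      pn <- vapply(prods, function(m) m$n, 1L)
      main <- prods[[which.max(pn)]]
      diff_ok <- tryCatch({
        length(soms_by_mcs(sub, main)) > 0
      }, error = function(e) FALSE)
      if (!diff_ok) {
        counts["ambiguous_center"] <- counts["ambiguous_center"] + 1L
        keep[i] <- FALSE
      }
    }
  }

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- counts
  out
}

#' Read a reaction SMARTS pattern library
#'
#' @param path TSV with columns `pattern_id`, `name`, `reaction_smarts` and
#'   optionally `center_map` (the designated reaction-center map number);
#'   `#` comments allowed; a header line is detected and skipped.
#' @return data frame of pattern records whose SMARTS all compile;
#'   uncompilable patterns are rejected with a warning naming the id.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) stop("pattern file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && identical(parts[[1]][1], "pattern_id")) {
    parts <- parts[-1]
  }
  rows <- list()
  for (p in parts) {
    if (length(p) < 3) next
    ok <- tryCatch({
      parse_reaction_smarts(p[3])
      TRUE
    }, error = function(e) {
      warning(sprintf("pattern '%s' rejected: %s", p[1], conditionMessage(e)))
      FALSE
    })
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(
      pattern_id = p[1], name = p[2], reaction_smarts = p[3],
      center_map = if (length(p) >= 4 && nzchar(p[4])) as.integer(p[4])
                   else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no valid patterns in ", path)
  do.call(rbind, rows)
}

#' Write a pattern library as TSV
#'
#' Inverse of [read_patterns()].
#'
#' @param patterns pattern data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_patterns <- function(patterns, path) {
  df <- patterns[, c("pattern_id", "name", "reaction_smarts")]
  df$center_map <- ifelse(is.na(patterns$center_map), "",
                          as.character(patterns$center_map))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write site and metabolite predictions
#'
#' Writes `<prefix>.sites.tsv` (molecule_id, atom_index 0-based, element,
#' m, n, x, r, p, category, rank) and `<prefix>.metabolites.sdf` (V2000,
#' one record per metabolite, with properties parent_id, site_atom,
#' pattern_id, p, rank).  The SDF is created even when there are no
#' metabolites.
#'
#' @param sites site prediction data frame (see [predict_sites()]).
#' @param metabolites metabolite prediction data frame
#'   (see [generate_metabolites()]); may have zero rows.
#' @param out_prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
write_predictions <- function(sites, metabolites, out_prefix) {
  sites_path <- paste0(out_prefix, ".sites.tsv")
  sdf_path <- paste0(out_prefix, ".metabolites.sdf")
  s <- sites
  s$atom_index <- s$atom_index - 1L   # memory 1-based -> file 0-based
  cols <- c("molecule_id", "atom_index", "element", "m", "n", "x", "r",
            "p", "category", "rank")
  ok <- tryCatch({
    utils::write.table(s[, cols], sites_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write predictions to ", sites_path)

  blocks <- character(0)
  if (!is.null(metabolites) && nrow(metabolites) > 0) {
    for (i in seq_len(nrow(metabolites))) {
      m <- metabolites[i, ]
      sdf <- ob_convert("SMI", "SDF",
                        paste0(m$product_smiles, "\t", m$parent_id, "_M",
                               m$rank))
      sdf <- sub("\\$\\$\\$\\$\n?$", "", sdf)
      # OpenBabel stamps the program line with a timestamp; fix it so
      # identical inputs give byte-identical files
      sl <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
      if (length(sl) >= 2) sl[2] <- " metsite"
      sdf <- paste0(paste(sl, collapse = "\n"), "\n")
      props <- sprintf(
        ">  <%s>\n%s\n",
        c("parent_id", "site_atom", "pattern_id", "p", "rank"),
        c(m$parent_id, m$site_atom - 1L, m$pattern_id,
          format(m$site_p, digits = 6), m$rank))
      blocks <- c(blocks, paste0(sdf, paste(props, collapse = "\n"),
                                 "\n$$$$"))
    }
  }
  writeLines(paste(blocks, collapse = "\n"), sdf_path)
  invisible(c(sites = sites_path, metabolites = sdf_path))
}
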