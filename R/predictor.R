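# End-to-end SOM and metabolite prediction.
#
# For each heavy atom of a query molecule: count occurrence-weighted
# similar fingerprints in the substrate database (m) and the center
# database (n); correct n by the occurrences x whose reaction SMARTS
# patterns cannot actually be applied at that atom (a center hit is a
# "true" similar pair only if at least one of its patterns generates a
# sanitizable metabolite anchored there); score each site with the
# occurrence ratio r = (n - x)/(m - x), normalize to p = r/max(r), bin
# into likelihood categories and rank.  Applicable patterns at top-ranked
# sites then generate the metabolite structures.

# Compiled reaction SMARTS cache (keyed by the SMARTS text).
.rxn_cache <- new.env(parent = emptyenv())

compiled_reaction <- function(smarts) {
  key <- smarts
  rxn <- .rxn_cache[[key]]
  if (is.null(rxn)) {
    rxn <- parse_reaction_smarts(smarts)
    .rxn_cache[[key]] <- rxn
  }
  rxn
}

#' Check whether a reaction SMARTS pattern applies at an atom
#'
#' The pattern applies when its reactant side matches the molecule with the
#' designated reaction-center map atom landing on `atom_index` and at least
#' one product set sanitizes.
#'
#' @param mol a `molgraph`.
#' @param atom_index 1-based heavy-atom index.
#' @param pattern one-row pattern record (or list with `reaction_smarts`,
#'   optional `center_map`).
#' @return list with `applicable` (logical) and `products` (character
#'   vector of canonical product SMILES from all matches anchored there).
#' @export
#' @examples
#' gaba <- parse_smiles("NCCCC(=O)O")[[1]]
#' pat <- list(pattern_id = "cycl", center_map = 1,
#'   reaction_smarts =
#'     "[C:1]([NH2])[C:2][C:3][C:4](=O)O>>[C:1]1[C:2][C:3][C:4](=O)N1")
#' check_applicability(gaba, which(gaba$elem == "C")[1], pat)
check_applicability <- function(mol, atom_index, pattern) {
  rxn <- tryCatch(compiled_reaction(pattern$reaction_smarts),
                  error = function(e) NULL)
  if (is.null(rxn)) return(list(applicable = FALSE, products = character(0)))
  cm <- pattern$center_map
  if (is.null(cm) || is.na(cm)) cm <- default_center_map(rxn)
  res <- tryCatch(
    apply_reaction(mol, rxn, anchor_atom = atom_index, anchor_map = cm),
    error = function(e) list())
  products <- unique(unlist(lapply(res, `[[`, "products")))
  if (is.null(products)) products <- character(0)
  list(applicable = length(products) > 0, products = products)
}

#' Predict the metabolic likelihood of every site of a molecule
#'
#' @param mol a `molgraph` (or a single SMILES string).
#' @param db a `som_db` (must be non-empty).
#' @param patterns pattern library data frame; defaults to the one stored
#'   in the database.
#' @param params [similarity_params()].
#' @return a data frame with one row per heavy atom: `molecule_id`,
#'   `atom_index` (1-based), `element`, `m`, `n`, `x`, `r`, `p`,
#'   `category`, `rank`.  Attribute `site_details` carries, per atom, the
#'   applicable patterns with their generated products and support counts
#'   (consumed by [generate_metabolites()]).
#' @export
predict_sites <- function(mol, db, patterns = NULL,
                          params = similarity_params()) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  stopifnot(inherits(mol, "molgraph"), inherits(db, "som_db"))
  if (!length(db$substrate)) stop("empty fingerprint database")
  if (is.null(patterns)) patterns <- db$patterns
  if (mol$n == 0) {
    return(empty_sites_frame())
  }
  fps <- molecule_fingerprints(mol, db$n_layers)
  n_atoms <- mol$n
  m <- integer(n_atoms); n <- integer(n_atoms); x <- integer(n_atoms)
  details <- vector("list", n_atoms)
  app_cache <- new.env(parent = emptyenv())

  for (a in seq_len(n_atoms)) {
    q <- db_query(db, fps[[a]], params)
    m[a] <- q$m
    n[a] <- q$n
    pat_support <- integer(0)
    pat_products <- list()
    xa <- 0L
    for (e in q$n_hits) {
      pids <- names(e$patterns)
      any_ok <- FALSE
      for (pid in pids) {
        ck <- paste0(a, "\r", pid)
        res <- app_cache[[ck]]
        if (is.null(res)) {
          row <- if (!is.null(patterns)) {
            patterns[patterns$pattern_id == pid, , drop = FALSE]
          } else NULL
          res <- if (!is.null(row) && nrow(row) == 1) {
            check_applicability(mol, a, as.list(row[1, ]))
          } else {
            list(applicable = FALSE, products = character(0))
          }
          app_cache[[ck]] <- res
        }
        if (res$applicable) {
          any_ok <- TRUE
          pat_support[pid] <- (if (pid %in% names(pat_support))
            pat_support[[pid]] else 0L) + e$patterns[[pid]]
          pat_products[[pid]] <- res$products
        }
      }
      if (!any_ok) xa <- xa + e$count
    }
    x[a] <- xa
    details[[a]] <- list(support = pat_support, products = pat_products)
  }

  r <- ifelse(m > x, (n - x) / (m - x), 0)
  r[m == 0] <- 0
  rmax <- max(r)
  p <- if (rmax > 0) r / rmax else rep(0, n_atoms)
  out <- data.frame(
    molecule_id = if (is.na(mol$id)) "query" else mol$id,
    atom_index = seq_len(n_atoms),
    element = mol$elem,
    m = m, n = n, x = x, r = r, p = p,
    category = vapply(p, categorize, ""),
    stringsAsFactors = FALSE
  )
  out$rank <- rank_sites(out$p, out$atom_index)
  attr(out, "site_details") <- details
  out
}

empty_sites_frame <- function() {
  out <- data.frame(molecule_id = character(0), atom_index = integer(0),
                    element = character(0), m = integer(0), n = integer(0),
                    x = integer(0), r = numeric(0), p = numeric(0),
                    category = character(0), rank = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "site_details") <- list()
  out
}

# Rank: p descending, ties broken by lower atom index.
rank_sites <- function(p, atom_index) {
  ord <- order(-p, atom_index)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk
}

#' Categorize a normalized occurrence ratio
#'
#' Likelihood bins: very unlikely `[0, 0.15)`, unlikely `[0.15, 0.33)`,
#' likely `[0.33, 0.66)`, very likely `[0.66, 1]` (the top bin is closed
#' at 1, which max-normalization always produces for the best site).
#'
#' @param p normalized occurrence ratio in `[0, 1]`.
#' @return one of `"very unlikely"`, `"unlikely"`, `"likely"`,
#'   `"very likely"`.
#' @export
categorize <- function(p) {
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1], got ", p)
  if (p < 0.15) "very unlikely"
  else if (p < 0.33) "unlikely"
  else if (p < 0.66) "likely"
  else "very likely"
}

#' Generate ranked metabolite structures
#'
#' Collects the products of all applicable patterns at sites ranked at or
#' above `top_k` with `p > 0`, deduplicates by canonical product SMILES
#' within a site equivalence class (graph-automorphic sites collapse), sums
#' the support of entries generating the same product, and ranks by
#' (site rank, support descending, canonical SMILES).
#'
#' @param mol a `molgraph`.
#' @param sites site predictions from [predict_sites()] (whose
#'   `site_details` attribute must be present).
#' @param top_k how many top-ranked sites generate metabolites (default 3).
#' @return data frame with columns `parent_id`, `product_smiles`,
#'   `site_atom`, `pattern_id`, `support`, `site_p`, `rank` (possibly zero
#'   rows).
#' @export
generate_metabolites <- function(mol, sites, top_k = 3L) {
  details <- attr(sites, "site_details")
  if (is.null(details)) stop("sites lack the site_details attribute; ",
                             "pass the object returned by predict_sites()")
  equiv <- atom_equiv_classes(mol)
  rows <- list()
  sel <- which(sites$rank <= top_k & sites$p > 0)
  for (a in sel) {
    det <- details[[sites$atom_index[a]]]
    for (pid in names(det$products)) {
      for (smi in det$products[[pid]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          parent_id = sites$molecule_id[a],
          product_smiles = smi,
          site_atom = sites$atom_index[a],
          pattern_id = pid,
          support = unname(det$support[[pid]]),
          site_p = sites$p[a],
          site_rank = sites$rank[a],
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(parent_id = character(0), product_smiles = character(0),
                      site_atom = integer(0), pattern_id = character(0),
                      support = integer(0), site_p = numeric(0),
                      rank = integer(0), stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  df <- do.call(rbind, rows)
  df$equiv_class <- equiv[df$site_atom]
  # dedup: same product from the same site equivalence class
  keygrp <- paste(df$product_smiles, df$equiv_class)
  agg <- lapply(split(seq_len(nrow(df)), keygrp), function(ix) {
    g <- df[ix, , drop = FALSE]
    g <- g[order(g$site_rank, -g$support), , drop = FALSE]
    out <- g[1, , drop = FALSE]
    out$support <- sum(g$support[!duplicated(g$pattern_id)])
    out
  })
  df <- do.call(rbind, agg)
  df <- df[order(df$site_rank, -df$support, df$product_smiles), ,
           drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df[, c("parent_id", "product_smiles", "site_atom", "pattern_id",
         "support", "site_p", "rank")]
}

#' Predict SOMs and metabolites for a query molecule
#'
#' The full workflow: per-atom fingerprints, database search, applicability
#' correction, occurrence-ratio scoring and metabolite generation.
#' Deterministic for fixed inputs.
#'
#' @param mol a `molgraph` or SMILES string.
#' @param db a `som_db`.
#' @param patterns pattern library (defaults to the database's).
#' @param params [similarity_params()].
#' @param top_k metabolite generation depth (default 3).
#' @return list with `sites` and `metabolites` data frames.
#' @export
predict_metabolism <- function(mol, db, patterns = NULL,
                               params = similarity_params(), top_k = 3L) {
  if (is.character(mol)) mol <- parse_smiles(mol)[[1]]
  sites <- predict_sites(mol, db, patterns, params)
  mets <- generate_metabolites(mol, sites, top_k)
  list(sites = sites, metabolites = mets)
}
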