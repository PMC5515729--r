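# Evaluation protocol: top-k SOM accuracy, atom-level ROC AUC, metabolite
# recall/precision/F1 with false-positive counts, and the exact-match
# depth sweep.

#' Top-k SOM prediction accuracy
#'
#' Fraction of molecules for which at least one of the k top-ranked sites
#' is a true SOM.  Credit is symmetry-aware: a predicted atom counts when
#' it lies in the same graph-automorphism (atom-environment equivalence)
#' class as a true SOM.
#'
#' @param predictions named list of site data frames ([predict_sites()]),
#'   one per molecule id.
#' @param truth named list of 1-based true SOM atom vectors (every truth
#'   molecule has at least one SOM).
#' @param k rank cutoff.
#' @param mols named list of `molgraph` objects (for equivalence classes).
#' @return the accuracy in `[0, 1]`.
#' @export
topk_som_accuracy <- function(predictions, truth, k, mols) {
  hits <- 0L
  for (id in names(truth)) {
    sites <- predictions[[id]]
    if (is.null(sites) || nrow(sites) == 0) {
      warning("molecule ", id, " has no predictions; counted as a miss")
      next
    }
    mol <- mols[[id]]
    eq <- atom_equiv_classes(mol)
    true_classes <- unique(eq[truth[[id]]])
    top <- sites$atom_index[sites$rank <= k]
    if (any(eq[top] %in% true_classes)) hits <- hits + 1L
  }
  hits / length(truth)
}

# Mann-Whitney AUC from scores and binary labels (ties handled by
# midranks).  Returns NA when only one class is present.
.auc_mw <- function(scores, labels) {
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Atom-level ROC AUC of SOM predictions
#'
#' Pooled (all atoms of all molecules), mean and median per-molecule AUC.
#' Molecules whose atoms are all positive or all negative are excluded
#' from the per-molecule statistics (with a message).
#'
#' @inheritParams topk_som_accuracy
#' @return list with `overall`, `mean`, `median`, `n_molecules` (used for
#'   the per-molecule statistics).
#' @export
auc_metrics <- function(predictions, truth) {
  all_scores <- numeric(0)
  all_labels <- logical(0)
  per_mol <- numeric(0)
  excluded <- 0L
  for (id in names(predictions)) {
    sites <- predictions[[id]]
    if (is.null(sites) || nrow(sites) == 0) next
    lab <- sites$atom_index %in% (truth[[id]] %||% integer(0))
    all_scores <- c(all_scores, sites$p)
    all_labels <- c(all_labels, lab)
    a <- .auc_mw(sites$p, lab)
    if (is.na(a)) excluded <- excluded + 1L else per_mol <- c(per_mol, a)
  }
  if (excluded > 0) {
    message(excluded,
            " molecule(s) with one-class labels excluded from per-molecule AUC")
  }
  overall <- .auc_mw(all_scores, all_labels)
  if (is.na(overall)) {
    stop("AUC undefined: all atom labels belong to one class")
  }
  list(overall = overall,
       mean = mean(per_mol),
       median = stats::median(per_mol),
       n_molecules = length(per_mol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical, stereo-stripped SMILES used for metabolite identity.
metabolite_identity <- function(smiles) {
  s <- gsub("[@\\\\/]", "", smiles)
  canonical_smiles(s)
}

#' Metabolite prediction recall / precision / F1 and false positives
#'
#' Pooled (micro-averaged) over molecules: recall is the number of
#' experimentally known metabolites recovered in the top-k positions over
#' the total number of experimental metabolites; precision is the number
#' recovered over the number predicted in the top-k; the false-positive
#' count is the total number of predicted-but-not-experimental structures.
#' Identity is canonical-SMILES equality with stereochemistry stripped.
#'
#' @param predicted named list of metabolite data frames
#'   ([generate_metabolites()]).
#' @param truth named list of character vectors of experimental metabolite
#'   SMILES; molecules with none are excluded from the recall denominator
#'   (with a warning).
#' @param k metabolite rank cutoff.
#' @return list with `recall`, `precision`, `f1`, `fp_count`.
#' @export
metabolite_prf <- function(predicted, truth, k) {
  n_real_hit <- 0L
  n_pred <- 0L
  n_truth <- 0L
  fp <- 0L
  for (id in names(predicted)) {
    tm <- truth[[id]]
    if (is.null(tm) || !length(tm)) {
      warning("molecule ", id,
              " has no experimental metabolites; excluded from recall")
      tm <- character(0)
    }
    tcan <- if (length(tm)) metabolite_identity(tm) else character(0)
    pm <- predicted[[id]]
    pcan <- if (!is.null(pm) && nrow(pm)) {
      metabolite_identity(pm$product_smiles[pm$rank <= k])
    } else character(0)
    n_truth <- n_truth + length(tcan)
    n_pred <- n_pred + length(pcan)
    n_real_hit <- n_real_hit + sum(pcan %in% tcan)
    fp <- fp + sum(!pcan %in% tcan)
  }
  recall <- if (n_truth > 0) n_real_hit / n_truth else 0
  precision <- if (n_pred > 0) n_real_hit / n_pred else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(recall = recall, precision = precision, f1 = f1, fp_count = fp)
}

#' Exact-match depth sweep
#'
#' Re-runs site prediction at each exact-match depth and reports the
#' per-molecule AUC together with whether the molecule retrieved any
#' database hit at that depth.
#'
#' @param mols named list of query `molgraph` objects.
#' @param truth named list of true SOM atom vectors.
#' @param db a `som_db`.
#' @param depths integer vector of exact-match depths (subset of
#'   `1..n_layers`).
#' @param params base [similarity_params()] (threshold reused).
#' @return data frame with columns `depth`, `molecule_id`, `auc` (`NA` for
#'   one-class molecules) and `any_hit`; one row per depth x molecule.
#' @export
depth_sweep <- function(mols, truth, db, depths = 1:6,
                        params = similarity_params()) {
  stopifnot(all(depths >= 1), all(depths <= db$n_layers))
  rows <- list()
  for (d in depths) {
    pd <- similarity_params(exact_depth = d, threshold = params$threshold,
                            n_layers = params$n_layers)
    for (id in names(mols)) {
      sites <- predict_sites(mols[[id]], db, params = pd)
      lab <- sites$atom_index %in% (truth[[id]] %||% integer(0))
      rows[[length(rows) + 1L]] <- data.frame(
        depth = d, molecule_id = id,
        auc = .auc_mw(sites$p, lab),
        any_hit = any(sites$m > 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analytic random-ranking top-k baseline
#'
#' Expected top-k accuracy of a uniformly random atom ranking: per
#' molecule with N rankable atoms of which s are true-SOM-equivalent,
#' `1 - choose(N-s, k)/choose(N, k)`, averaged over molecules.
#'
#' @inheritParams topk_som_accuracy
#' @return the baseline accuracy.
#' @export
random_topk_baseline <- function(truth, mols, k) {
  vals <- vapply(names(truth), function(id) {
    mol <- mols[[id]]
    eq <- atom_equiv_classes(mol)
    s <- sum(eq %in% unique(eq[truth[[id]]]))
    n <- mol$n
    if (k >= n) return(1)
    1 - choose(n - s, k) / choose(n, k)
  }, 1)
  mean(vals)
}

#' Run the full evaluation protocol on a benchmark
#'
#' Predicts every benchmark molecule against a database and computes
#' top-k SOM accuracies, the AUC summary, and (when experimental
#' metabolites are supplied) metabolite precision/recall/F1 and
#' false-positive counts.
#'
#' @param mols named list of `molgraph` queries.
#' @param truth named list of true SOM atoms (1-based).
#' @param db a `som_db`.
#' @param params [similarity_params()].
#' @param ks rank cutoffs for the top-k metrics (default 1:3).
#' @param truth_metabolites optional named list of experimental metabolite
#'   SMILES vectors.
#' @param top_k metabolite generation depth (default `max(ks)`).
#' @return list with `topk` (named vector), `auc`, `metabolites` (per-k
#'   list, `NULL` when no truth metabolites), and the raw `predictions`.
#' @export
evaluate_benchmark <- function(mols, truth, db, params = similarity_params(),
                               ks = 1:3, truth_metabolites = NULL,
                               top_k = max(ks)) {
  predictions <- list()
  metabolites <- list()
  for (id in names(mols)) {
    res <- predict_metabolism(mols[[id]], db, params = params, top_k = top_k)
    predictions[[id]] <- res$sites
    metabolites[[id]] <- res$metabolites
  }
  topk <- vapply(ks, function(k)
    topk_som_accuracy(predictions, truth, k, mols), 1)
  names(topk) <- paste0("top", ks)
  auc <- auc_metrics(predictions, truth)
  met <- NULL
  if (!is.null(truth_metabolites)) {
    met <- lapply(ks, function(k)
      metabolite_prf(metabolites, truth_metabolites, k))
    names(met) <- paste0("top", ks)
  }
  list(topk = topk, auc = auc, metabolites = met,
       predictions = predictions, predicted_metabolites = metabolites)
}
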