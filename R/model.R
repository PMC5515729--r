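# Fitted-model interface: a som_model is the curated, annotated and
# fingerprint-indexed form of a metabolic reaction dataset, ready to score
# query molecules.

#' Fit a site-of-metabolism model from a reaction dataset
#'
#' Curates the records, annotates SOMs (provided > pattern > MCS diff),
#' and builds the substrate / reaction-center fingerprint database pair.
#'
#' @param records reaction record data frame ([read_reactions()] or a
#'   fixture manifest's `records`).
#' @param patterns pattern library (default [builtin_patterns()]).
#' @param params [similarity_params()] stored with the model and used as
#'   prediction defaults.
#' @param curate apply the curation filters first (default TRUE).
#' @param n_layers fingerprint depth (default 6).
#' @return an object of class `som_model`.
#' @export
#' @examples
#' \donttest{
#' man <- generate_dataset(seed = 7, n_per_class = 3)
#' fit <- som_model(man$records[man$records$split == "train", ],
#'                  man$patterns)
#' predict(fit, "COc1ccccc1")$sites
#' }
som_model <- function(records, patterns = builtin_patterns(),
                      params = similarity_params(), curate = TRUE,
                      n_layers = .n_layers_default) {
  cur <- if (curate) curate_reactions(records) else records
  ann <- annotate_dataset(cur, patterns)
  db <- build_databases(cur, ann, patterns, n_layers = n_layers)
  structure(list(
    db = db,
    params = params,
    n_records = nrow(cur),
    filter_counts = attr(cur, "filter_counts"),
    method_census = attr(ann, "method_census"),
    call = match.call()
  ), class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat("Site-of-metabolism model\n")
  m <- x$db$manifest
  cat(sprintf("  reactions: %d   substrate atoms: %d   reaction centers: %d\n",
              x$n_records, m$substrate_occurrences, m$center_occurrences))
  cat(sprintf("  fingerprint: %d layers, alphabet %s\n",
              x$db$n_layers, x$db$alphabet_version))
  cat(sprintf("  similarity: exact depth %d, threshold %g\n",
              x$params$exact_depth, x$params$threshold))
  invisible(x)
}

#' @export
summary.som_model <- function(object, ...) {
  out <- list(
    manifest = object$db$manifest,
    params = object$params,
    filter_counts = object$filter_counts,
    method_census = object$method_census,
    patterns = object$db$patterns$pattern_id
  )
  class(out) <- "summary.som_model"
  out
}

#' @export
print.summary.som_model <- function(x, ...) {
  cat("Site-of-metabolism model summary\n")
  cat("  database hash:", substr(x$manifest$content_hash, 1, 12), "...\n")
  cat(sprintf("  substrate keys: %d (%d occurrences)\n",
              x$manifest$n_substrate_keys, x$manifest$substrate_occurrences))
  cat(sprintf("  center keys: %d (%d occurrences)\n",
              x$manifest$n_center_keys, x$manifest$center_occurrences))
  if (!is.null(x$filter_counts)) {
    cat("  curation removals:",
        paste(names(x$filter_counts), x$filter_counts, sep = "=",
              collapse = " "), "\n")
  }
  if (!is.null(x$method_census)) {
    cat("  annotation methods:",
        paste(names(x$method_census), x$method_census, sep = "=",
              collapse = " "), "\n")
  }
  cat("  patterns:", paste(x$patterns, collapse = ", "), "\n")
  invisible(x)
}

#' Predict SOMs and metabolites for new molecules
#'
#' @param object a `som_model`.
#' @param newdata SMILES character vector (names become molecule ids), a
#'   list of `molgraph` objects, or a path to a `.smi`/`.sdf` file.
#' @param top_k metabolite generation depth (default 3).
#' @param params override the model's similarity parameters.
#' @param ... unused.
#' @return list with `sites` and `metabolites`: row-bound data frames over
#'   all query molecules.
#' @export
predict.som_model <- function(object, newdata, top_k = 3L, params = NULL,
                              ...) {
  if (is.null(params)) params <- object$params
  mols <- query_molecules(newdata)
  sites <- list()
  mets <- list()
  for (id in names(mols)) {
    if (is.null(mols[[id]])) next
    res <- predict_metabolism(mols[[id]], object$db, params = params,
                              top_k = top_k)
    res$sites$molecule_id <- id
    if (nrow(res$metabolites)) res$metabolites$parent_id <- id
    sites[[id]] <- res$sites
    mets[[id]] <- res$metabolites
  }
  list(sites = do.call(rbind, c(sites, list(make.row.names = FALSE))),
       metabolites = do.call(rbind, c(mets, list(make.row.names = FALSE))))
}

# Normalize the accepted query inputs to a named molgraph list.
query_molecules <- function(newdata) {
  if (inherits(newdata, "molgraph")) {
    id <- if (is.na(newdata$id)) "query" else newdata$id
    return(stats::setNames(list(newdata), id))
  }
  if (is.list(newdata)) {
    ids <- names(newdata)
    if (is.null(ids)) {
      ids <- vapply(seq_along(newdata), function(i) {
        m <- newdata[[i]]
        if (inherits(m, "molgraph") && !is.na(m$id)) m$id
        else paste0("mol", i)
      }, "")
    }
    return(stats::setNames(newdata, ids))
  }
  if (is.character(newdata) && length(newdata) == 1 &&
      file.exists(newdata)) {
    return(read_molecules(newdata))
  }
  if (is.character(newdata)) {
    ids <- names(newdata)
    if (is.null(ids)) ids <- paste0("mol", seq_along(newdata))
    return(parse_smiles(newdata, ids = ids))
  }
  stop("unsupported newdata type for predict.som_model")
}
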