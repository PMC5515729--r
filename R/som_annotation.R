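# SOM annotation of curated reaction records.
#
# A SOM (site of metabolism) is any substrate position where a heavy atom
# is added, removed or altered by the reaction.  Simple reactions are
# annotated by the MCS diff (with the heteroatom convention for
# dealkylations); complex reactions by the structural changes encoded in
# their reaction SMARTS pattern; explicitly provided SOMs take precedence.

#' SOM atoms of a substrate from a reaction SMARTS pattern
#'
#' Matches the pattern's reactant side against the substrate and returns
#' the substrate atoms on which the pattern's designated reaction-center
#' map atom lands, over all matches.  The center is the pattern's
#' `center_map` when set, otherwise [default_center_map()].
#'
#' @param substrate a `molgraph`.
#' @param pattern a one-row pattern record (or a list with
#'   `reaction_smarts` and optional `center_map`).
#' @return integer vector of 1-based substrate atom indices.
#' @export
soms_by_pattern <- function(substrate, pattern) {
  rxn <- parse_reaction_smarts(pattern$reaction_smarts)
  cm <- pattern$center_map
  if (is.null(cm) || is.na(cm)) cm <- default_center_map(rxn)
  pa <- rxn$rmap[as.character(cm)]
  if (is.na(pa)) {
    stop("center map ", cm, " is not a mapped reactant atom of pattern ",
         pattern$pattern_id)
  }
  ms <- match_smarts(substrate, rxn$reactant)
  if (!length(ms)) {
    stop("pattern ", pattern$pattern_id %||na% "<unnamed>",
         " does not match the substrate")
  }
  sort(unique(vapply(ms, function(m) m[pa], 1L)))
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Annotate a curated reaction dataset with SOMs
#'
#' Per record: explicitly provided `som_atoms` win; otherwise the pattern
#' method is used when a `pattern_id` is set; otherwise the MCS diff
#' against the largest product.  Records failing every method are removed.
#'
#' @param records curated reaction record data frame.
#' @param patterns pattern library data frame ([read_patterns()] /
#'   [builtin_patterns()]).
#' @return data frame with columns `record_id`, `method` (`provided`,
#'   `pattern` or `mcs-diff`) and list column `som_atoms` (1-based
#'   substrate atom indices); attribute `method_census` counts methods and
#'   failures.
#' @export
annotate_dataset <- function(records, patterns) {
  n <- nrow(records)
  method <- character(n)
  soms <- vector("list", n)
  failed <- 0L
  subs <- substrate_smiles(records$reaction_smiles)
  mols <- parse_smiles(subs, ids = records$record_id)
  for (i in seq_len(n)) {
    if (!is.null(records$som_atoms[[i]])) {
      method[i] <- "provided"
      soms[[i]] <- sort(unique(records$som_atoms[[i]]))
      next
    }
    sub <- mols[[i]]
    if (is.null(sub)) { method[i] <- "failed"; next }
    pid <- records$pattern_id[i]
    if (!is.na(pid)) {
      row <- patterns[patterns$pattern_id == pid, , drop = FALSE]
      if (nrow(row) == 1) {
        res <- tryCatch(soms_by_pattern(sub, as.list(row[1, ])),
                        error = function(e) NULL)
        if (!is.null(res) && length(res)) {
          method[i] <- "pattern"
          soms[[i]] <- res
          next
        }
      }
    }
    prods <- product_components(records$reaction_smiles[i])
    pmols <- parse_smiles(prods)
    pmols <- pmols[!vapply(pmols, is.null, TRUE)]
    if (length(pmols)) {
      main <- pmols[[which.max(vapply(pmols, function(m) m$n, 1L))]]
      res <- tryCatch(soms_by_mcs(sub, main), error = function(e) NULL)
      if (!is.null(res) && length(res)) {
        method[i] <- "mcs-diff"
        soms[[i]] <- res
        next
      }
    }
    method[i] <- "failed"
    failed <- failed + 1L
  }
  keep <- method != "failed"
  if (any(!keep)) {
    warning(sprintf("%d record(s) could not be annotated and were removed",
                    sum(!keep)))
  }
  out <- data.frame(record_id = records$record_id[keep],
                    method = method[keep], stringsAsFactors = FALSE)
  out$som_atoms <- soms[keep]
  attr(out, "method_census") <- c(table(method))
  out
}

#' Write SOM annotations as TSV
#'
#' Columns: record_id, som_atoms (comma-separated, 0-based), method.
#'
#' @param annotations data frame from [annotate_dataset()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    record_id = annotations$record_id,
    som_atoms = vapply(annotations$som_atoms, function(x)
      paste(x - 1L, collapse = ","), ""),
    method = annotations$method,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
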