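# The two topological atom fingerprint databases.
#
# The substrate database aggregates the fingerprint of every heavy atom of
# every curated substrate; the reaction-center database aggregates the
# fingerprints of annotated SOM atoms together with the multiset of
# reaction SMARTS pattern ids observed at each fingerprint.  Entries are
# keyed by the exact fingerprint serialization; a prefix index over the
# first three layers accelerates queries without changing their results.

.db_prefix_layers <- 3L

#' Build the substrate / reaction-center fingerprint database pair
#'
#' Every heavy atom of every record's substrate contributes one occurrence
#' to the substrate database; every annotated SOM atom contributes one
#' occurrence to the center database under the record's pattern id.
#'
#' @param records curated reaction record data frame.
#' @param annotations SOM annotations from [annotate_dataset()]; every
#'   annotation must reference a record (fatal error otherwise).
#' @param patterns pattern library data frame.
#' @param n_layers fingerprint depth (default 6).
#' @return an object of class `som_db` with components `substrate`
#'   (key -> entry), `center` (key -> entry), `prefix_index`, `alphabet_version`,
#'   `n_layers` and `manifest`.
#' @export
build_databases <- function(records, annotations, patterns,
                            n_layers = .n_layers_default) {
  unknown <- setdiff(annotations$record_id, records$record_id)
  if (length(unknown)) {
    stop("annotation references unknown record(s): ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  ab <- atom_type_alphabet()
  sub_counts <- new.env(parent = emptyenv())
  ctr_counts <- new.env(parent = emptyenv())
  ctr_patterns <- new.env(parent = emptyenv())
  fp_cache <- new.env(parent = emptyenv())

  ann_idx <- match(records$record_id, annotations$record_id)
  subs <- substrate_smiles(records$reaction_smiles)
  mols <- parse_smiles(subs, ids = records$record_id)

  for (i in seq_len(nrow(records))) {
    mol <- mols[[i]]
    if (is.null(mol)) next
    fps <- molecule_fingerprints(mol, n_layers)
    keys <- vapply(fps, fp_key, "")
    for (k in keys) {
      sub_counts[[k]] <- null0(sub_counts[[k]]) + 1L
      if (is.null(fp_cache[[k]])) fp_cache[[k]] <- fps[[match(k, keys)]]
    }
    ai <- ann_idx[i]
    if (is.na(ai)) next
    som <- annotations$som_atoms[[ai]]
    som <- som[som >= 1 & som <= mol$n]
    pid <- records$pattern_id[i]
    if (is.na(pid)) pid <- ".none"
    for (a in som) {
      k <- keys[a]
      ctr_counts[[k]] <- null0(ctr_counts[[k]]) + 1L
      pc <- ctr_patterns[[k]]
      if (is.null(pc)) pc <- integer(0)
      pc[pid] <- (if (pid %in% names(pc)) pc[[pid]] else 0L) + 1L
      ctr_patterns[[k]] <- pc
    }
  }

  sub_keys <- sort(ls(sub_counts))
  ctr_keys <- sort(ls(ctr_counts))
  substrate <- lapply(sub_keys, function(k) list(
    key = k, count = sub_counts[[k]], fp = fp_cache[[k]]))
  names(substrate) <- sub_keys
  center <- lapply(ctr_keys, function(k) list(
    key = k, count = ctr_counts[[k]],
    patterns = ctr_patterns[[k]][sort(names(ctr_patterns[[k]]))],
    fp = fp_cache[[k]]))
  names(center) <- ctr_keys

  db <- structure(list(
    substrate = substrate,
    center = center,
    prefix_index = build_prefix_index(sub_keys, ctr_keys, n_layers),
    alphabet_version = ab$version,
    n_layers = as.integer(n_layers),
    patterns = patterns,
    manifest = NULL
  ), class = "som_db")
  db$manifest <- db_manifest(db, n_records = nrow(records))
  db
}

null0 <- function(x) if (is.null(x)) 0L else x

build_prefix_index <- function(sub_keys, ctr_keys, n_layers) {
  pfx <- function(keys) {
    if (!length(keys)) return(list())
    p <- vapply(strsplit(keys, "|", fixed = TRUE), function(x)
      paste(x[seq_len(min(.db_prefix_layers, length(x)))], collapse = "|"),
      "")
    split(keys, p)
  }
  list(substrate = pfx(sub_keys), center = pfx(ctr_keys))
}

# Deterministic content description + SHA-256 hash.
db_manifest <- function(db, n_records = NA_integer_) {
  lines <- c(
    paste0("alphabet=", db$alphabet_version),
    paste0("n_layers=", db$n_layers),
    vapply(db$substrate, function(e) paste0("S\t", e$key, "\t", e$count), ""),
    vapply(db$center, function(e) paste0(
      "C\t", e$key, "\t", e$count, "\t",
      paste(names(e$patterns), e$patterns, sep = "=", collapse = ";")), "")
  )
  list(
    alphabet_version = db$alphabet_version,
    n_layers = db$n_layers,
    n_records = n_records,
    n_substrate_keys = length(db$substrate),
    n_center_keys = length(db$center),
    substrate_occurrences = sum(vapply(db$substrate, `[[`, 1L, "count")),
    center_occurrences = sum(vapply(db$center, `[[`, 1L, "count")),
    content_hash = digest::digest(paste(lines, collapse = "\n"),
                                  algo = "sha256", serialize = FALSE)
  )
}

#' @export
print.som_db <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "<som_db: %d substrate keys (%d occurrences), ",
    "%d center keys (%d occurrences), %d layers>\n"),
    m$n_substrate_keys, m$substrate_occurrences,
    m$n_center_keys, m$center_occurrences, x$n_layers))
  invisible(x)
}

#' Query the database pair with one atom fingerprint
#'
#' Returns every substrate and center entry similar to `fp` under
#' [is_similar()].  The prefix index is used when the exact-match depth
#' covers the indexed layers; results are identical to a full linear scan.
#'
#' @param db a `som_db`.
#' @param fp a `fingerprint` (same alphabet and layer count as the
#'   database).
#' @param params [similarity_params()].
#' @return list with `m_hits` / `n_hits` (lists of entries), and the
#'   occurrence-weighted totals `m` and `n` (`n <= m` by the containment
#'   invariant).
#' @export
db_query <- function(db, fp, params = similarity_params()) {
  if (!identical(attr(fp, "alphabet_version"), db$alphabet_version)) {
    stop("fingerprint alphabet version does not match the database")
  }
  if (nrow(fp) != db$n_layers) {
    stop("fingerprint has ", nrow(fp), " layers; database uses ", db$n_layers)
  }
  use_index <- params$exact_depth >= .db_prefix_layers
  pick <- function(side, index) {
    if (use_index) {
      p <- fp_key(fp, layers = .db_prefix_layers)
      keys <- index[[p]]
      if (is.null(keys)) return(list())
      side[keys]
    } else {
      side
    }
  }
  scan <- function(entries) {
    hits <- list()
    for (e in entries) {
      if (is_similar(fp, e$fp, params)) hits[[length(hits) + 1L]] <- e
    }
    hits
  }
  m_hits <- scan(pick(db$substrate, db$prefix_index$substrate))
  n_hits <- scan(pick(db$center, db$prefix_index$center))
  list(
    m_hits = m_hits,
    n_hits = n_hits,
    m = sum(vapply(m_hits, `[[`, 1L, "count")),
    n = sum(vapply(n_hits, `[[`, 1L, "count"))
  )
}

#' Save a fingerprint database pair to a directory
#'
#' Writes `substrate.jsonl`, `centers.jsonl` and `manifest.json`.
#'
#' @param db a `som_db`.
#' @param path directory (created if missing).
#' @return invisibly, `path`.
#' @export
db_save <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  sub_lines <- vapply(db$substrate, function(e)
    jsonlite::toJSON(list(key = e$key, count = e$count), auto_unbox = TRUE),
    "")
  ctr_lines <- vapply(db$center, function(e)
    jsonlite::toJSON(list(key = e$key, count = e$count,
                          patterns = as.list(e$patterns)),
                     auto_unbox = TRUE), "")
  writeLines(sub_lines, file.path(path, "substrate.jsonl"))
  writeLines(ctr_lines, file.path(path, "centers.jsonl"))
  if (!is.null(db$patterns)) {
    write_patterns(db$patterns, file.path(path, "patterns.tsv"))
  }
  jsonlite::write_json(db$manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a fingerprint database pair from a directory
#'
#' Recomputes the content hash and fails with a corruption error when it
#' does not match the manifest.
#'
#' @param path directory written by [db_save()].
#' @return a `som_db` whose queries are identical to the saved one's.
#' @export
db_load <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(man_path)
  n_layers <- as.integer(manifest$n_layers)
  read_jsonl <- function(f) {
    p <- file.path(path, f)
    if (!file.exists(p)) stop("database file missing: ", p)
    lines <- readLines(p, warn = FALSE)
    lines <- lines[nzchar(lines)]
    lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l),
               error = function(e) stop("corrupt database line in ", f))
    })
  }
  substrate <- list()
  for (e in read_jsonl("substrate.jsonl")) {
    if (is.null(e$key) || is.null(e$count)) {
      stop("corrupt substrate entry in ", path)
    }
    substrate[[e$key]] <- list(key = e$key, count = as.integer(e$count),
                               fp = fp_from_key(e$key, n_layers))
  }
  center <- list()
  for (e in read_jsonl("centers.jsonl")) {
    if (is.null(e$key) || is.null(e$count)) {
      stop("corrupt center entry in ", path)
    }
    pats <- unlist(e$patterns)
    center[[e$key]] <- list(
      key = e$key, count = as.integer(e$count),
      patterns = stats::setNames(as.integer(pats), names(pats)),
      fp = fp_from_key(e$key, n_layers))
  }
  patterns <- NULL
  pat_path <- file.path(path, "patterns.tsv")
  if (file.exists(pat_path)) patterns <- read_patterns(pat_path)
  sort_by_name <- function(x) {
    if (!length(x)) return(stats::setNames(list(), character(0)))
    x[order(names(x))]
  }
  db <- structure(list(
    substrate = sort_by_name(substrate),
    center = sort_by_name(center),
    prefix_index = build_prefix_index(sort(names(substrate)),
                                      sort(names(center)), n_layers),
    alphabet_version = manifest$alphabet_version,
    n_layers = n_layers,
    patterns = patterns,
    manifest = NULL
  ), class = "som_db")
  db$manifest <- db_manifest(db, n_records = manifest$n_records)
  if (!identical(db$manifest$content_hash, manifest$content_hash)) {
    stop("database corruption: content hash mismatch under ", path)
  }
  db
}
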