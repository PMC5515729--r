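# Six-layer topological atom-environment count fingerprints.
#
# For a root atom, layer j (j = 0..5) counts the heavy atoms of each
# alphabet type at shortest-path distance exactly j in the bond graph.
# Layers beyond the molecule's radius carry a single PAD count, so every
# row has at least one nonzero entry and the Soergel metric is always
# defined.

#' Number of fingerprint layers used by default
#' @keywords internal
.n_layers_default <- 6L

#' Compute the layered count fingerprint of one atom
#'
#' @param mol a `molgraph`.
#' @param atom_index 1-based heavy-atom index of the root atom.
#' @param n_layers number of layers (default 6).
#' @return an object of class `fingerprint`: an integer matrix with
#'   `n_layers` rows (layers 0..n_layers-1) and one column per alphabet
#'   type, with attributes `root_atom`, `molecule_id` and `alphabet_version`.
#' @export
#' @examples
#' mol <- parse_smiles("CO")[[1]]
#' atom_fingerprint(mol, 1)
atom_fingerprint <- function(mol, atom_index, n_layers = .n_layers_default) {
  stopifnot(inherits(mol, "molgraph"))
  if (atom_index < 1 || atom_index > mol$n) {
    stop("atom_index out of range: ", atom_index)
  }
  molecule_fingerprints(mol, n_layers)[[atom_index]]
}

#' Compute fingerprints for every heavy atom of a molecule
#'
#' @param mol a `molgraph`.
#' @param n_layers number of layers (default 6).
#' @return a list of `fingerprint` matrices, one per heavy atom in atom
#'   order (empty list for an empty molecule).
#' @export
molecule_fingerprints <- function(mol, n_layers = .n_layers_default) {
  stopifnot(inherits(mol, "molgraph"))
  if (mol$n == 0) return(list())
  ab <- atom_type_alphabet()
  types <- atom_types(mol)
  col <- match(types, ab$types)
  d <- mol_distances(mol)
  pad_col <- match(ab$pad, ab$types)
  lapply(seq_len(mol$n), function(root) {
    m <- matrix(0L, nrow = n_layers, ncol = length(ab$types),
                dimnames = list(paste0("L", seq_len(n_layers) - 1), ab$types))
    dr <- d[root, ]
    for (j in seq_len(n_layers) - 1L) {
      at <- which(is.finite(dr) & dr == j)
      if (length(at)) {
        tab <- tabulate(col[at], nbins = length(ab$types))
        m[j + 1L, ] <- as.integer(tab)
      } else {
        m[j + 1L, pad_col] <- 1L
      }
    }
    structure(m, class = "fingerprint", root_atom = root,
              molecule_id = mol$id, alphabet_version = ab$version)
  })
}

#' @export
print.fingerprint <- function(x, ...) {
  nz <- which(x != 0, arr.ind = TRUE)
  cat(sprintf("<fingerprint root=%s mol=%s>\n",
              attr(x, "root_atom"), attr(x, "molecule_id")))
  for (j in sort(unique(nz[, 1]))) {
    k <- nz[nz[, 1] == j, 2]
    cat(sprintf("  L%d: %s\n", j - 1,
                paste0(colnames(x)[k], "=", x[j, k], collapse = " ")))
  }
  invisible(x)
}

#' Serialize a fingerprint to its database key
#'
#' The key lists, per layer, the nonzero type counts in alphabet order:
#' `type=count;...` per layer, layers joined with `|`.  Bit-exact across
#' runs and platforms.
#'
#' @param fp a `fingerprint` matrix.
#' @param layers optionally restrict to the first `layers` rows (used for
#'   the exact-match prefix bucket).
#' @return a single string.
#' @export
fp_key <- function(fp, layers = nrow(fp)) {
  rows <- vapply(seq_len(layers), function(j) {
    k <- which(fp[j, ] != 0L)
    paste0(colnames(fp)[k], "=", fp[j, k], collapse = ";")
  }, "")
  paste(rows, collapse = "|")
}

#' Reconstruct a fingerprint matrix from its key
#'
#' @param key a string produced by [fp_key()].
#' @param n_layers number of layers encoded in the key.
#' @return a `fingerprint` matrix (root/molecule attributes unset).
#' @export
fp_from_key <- function(key, n_layers = .n_layers_default) {
  ab <- atom_type_alphabet()
  m <- matrix(0L, nrow = n_layers, ncol = length(ab$types),
              dimnames = list(paste0("L", seq_len(n_layers) - 1), ab$types))
  rows <- strsplit(key, "|", fixed = TRUE)[[1]]
  if (length(rows) != n_layers) {
    stop("fingerprint key has ", length(rows), " layers, expected ", n_layers)
  }
  for (j in seq_along(rows)) {
    if (!nzchar(rows[j])) next
    kv <- strsplit(strsplit(rows[j], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (p in kv) {
      ci <- match(p[1], ab$types)
      if (is.na(ci)) stop("unknown atom type in key: ", p[1])
      m[j, ci] <- as.integer(p[2])
    }
  }
  structure(m, class = "fingerprint", root_atom = NA_integer_,
            molecule_id = NA_character_, alphabet_version = ab$version)
}

# Environment-equivalence classes of atoms: two atoms are equivalent when
# their full-depth layer fingerprints (layers up to the graph diameter)
# are identical.  Used for symmetry-aware SOM credit and metabolite dedup.
atom_equiv_classes <- function(mol) {
  if (mol$n == 0) return(integer(0))
  d <- mol_distances(mol)
  depth <- max(1, max(d[is.finite(d)]) + 1)
  fps <- molecule_fingerprints(mol, n_layers = depth)
  keys <- vapply(fps, fp_key, "")
  match(keys, unique(keys))
}
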