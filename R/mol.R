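# Molecule graphs.
#
# Structures are handled as heavy-atom graphs with SYBYL/Tripos atom types,
# aromatic flags, hydrogen counts and formal charges.  Parsing, atom typing,
# aromaticity perception and canonicalization are delegated to OpenBabel
# (via ChemmineOB); the graph itself is a plain R list so that the
# fingerprint, SMARTS and MCS machinery can walk it directly.

#' Convert between chemical formats via OpenBabel
#'
#' Thin wrapper around [ChemmineOB::convertFormat()] that suppresses
#' OpenBabel's console chatter and returns `""` for unparseable input.
#'
#' @param from,to format codes understood by OpenBabel (e.g. `"SMI"`,
#'   `"CAN"`, `"MOL2"`, `"SDF"`).
#' @param source input text.
#' @param add_h add explicit hydrogens before writing.
#' @return the converted text (possibly `""`).
#' @keywords internal
ob_convert <- function(from, to, source, add_h = FALSE) {
  opts <- if (add_h) data.frame(names = "h", args = "") else
    data.frame(names = character(0), args = character(0))
  out <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineOB::convertFormat(from, to, source, options = opts)
    )),
    error = function(e) ""
  )
  if (length(out) == 0) "" else out
}

#' Canonical SMILES
#'
#' Canonicalizes one or more SMILES strings with OpenBabel.  Unparseable
#' entries yield `NA`.
#'
#' @param smiles character vector of SMILES.
#' @return character vector of the same length; `NA` where parsing failed.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "c1ccccc1O"))
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  keys <- paste0("q", seq_along(smiles))
  src <- paste0(smiles, "\t", keys, collapse = "\n")
  out <- ob_convert("SMI", "CAN", src)
  res <- rep(NA_character_, length(smiles))
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) {
      i <- match(trimws(p[2]), keys)
      if (!is.na(i)) res[i] <- p[1]
    }
  }
  res
}

# Split concatenated MOL2 text into per-molecule blocks keyed by title.
split_mol2_blocks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  blocks <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    blk <- lines[from:to]
    title <- trimws(blk[2])
    blocks[[title]] <- blk
  }
  blocks
}

# Parse one MOL2 block (lines) into atom/bond tables.
parse_mol2_block <- function(lines) {
  sec_atom <- grep("^@<TRIPOS>ATOM", lines)
  sec_bond <- grep("^@<TRIPOS>BOND", lines)
  sec_all <- grep("^@<TRIPOS>", lines)
  end_of <- function(start) {
    nxt <- sec_all[sec_all > start]
    if (length(nxt)) nxt[1] - 1 else length(lines)
  }
  atoms <- NULL
  if (length(sec_atom)) {
    rng <- (sec_atom[1] + 1):end_of(sec_atom[1])
    rows <- lines[rng]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows)) {
      f <- strsplit(trimws(rows), "[[:space:]]+")
      atoms <- data.frame(
        name = vapply(f, `[`, "", 2),
        sybyl = vapply(f, `[`, "", 6),
        stringsAsFactors = FALSE
      )
    }
  }
  bonds <- NULL
  if (length(sec_bond)) {
    rng <- (sec_bond[1] + 1):end_of(sec_bond[1])
    rows <- lines[rng]
    rows <- rows[nzchar(trimws(rows))]
    if (length(rows)) {
      f <- strsplit(trimws(rows), "[[:space:]]+")
      bonds <- data.frame(
        a = as.integer(vapply(f, `[`, "", 2)),
        b = as.integer(vapply(f, `[`, "", 3)),
        order = vapply(f, `[`, "", 4),
        stringsAsFactors = FALSE
      )
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Element symbol from a SYBYL type ("C.ar" -> "C", "Cl" -> "Cl").
sybyl_element <- function(sybyl) {
  sub("\\..*$", "", sybyl)
}

# Formal charges per heavy atom, from an SDF conversion of the same SMILES
# (MOL2 carries only partial charges).  Returns an integer vector or NULL.
sdf_formal_charges <- function(sdf_record, n_heavy) {
  charges <- integer(n_heavy)
  chg <- grep("^M  CHG", sdf_record, value = TRUE)
  for (line in chg) {
    f <- strsplit(trimws(sub("^M  CHG", "", line)), "[[:space:]]+")[[1]]
    f <- as.integer(f)
    k <- f[1]
    for (j in seq_len(k)) {
      idx <- f[2 * j]
      val <- f[2 * j + 1]
      if (idx >= 1 && idx <= n_heavy) charges[idx] <- val
    }
  }
  charges
}

#' Build a molecule graph
#'
#' Low-level constructor for the heavy-atom graph representation used
#' throughout the package.  Atom indices are 0-based in all user-facing
#' interfaces; internally rows of `atoms` are 1-based.
#'
#' @param elem character vector of element symbols.
#' @param sybyl character vector of SYBYL atom types (same length).
#' @param arom logical vector, aromatic atom flags.
#' @param hcount integer vector of attached hydrogens.
#' @param charge integer vector of formal charges.
#' @param bonds data frame with columns `a`, `b` (1-based atom indices) and
#'   `order` (one of `"1"`, `"2"`, `"3"`, `"ar"`, `"am"`).
#' @param id molecule identifier.
#' @param smiles canonical SMILES, if known.
#' @return an object of class `molgraph`.
#' @keywords internal
new_molgraph <- function(elem, sybyl, arom, hcount, charge, bonds, id = NA_character_,
                         smiles = NA_character_) {
  n <- length(elem)
  adj <- vector("list", n)
  border <- vector("list", n)
  if (n > 0 && !is.null(bonds) && nrow(bonds) > 0) {
    # amide "am" bonds are single bonds for graph purposes
    ord <- bonds$order
    ord[ord == "am"] <- "1"
    ord[ord %in% c("un", "du", "nc")] <- "1"
    bonds$order <- ord
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a[k]; b <- bonds$b[k]; o <- bonds$order[k]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
      border[[a]] <- c(border[[a]], o)
      border[[b]] <- c(border[[b]], o)
    }
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(
    n = n, elem = elem, sybyl = sybyl, arom = arom,
    hcount = as.integer(hcount), charge = as.integer(charge),
    bonds = bonds, adj = adj, border = border,
    id = id, smiles = smiles
  ), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d heavy atoms, %d bonds>  %s\n",
              if (is.na(x$id)) "" else x$id, x$n, nrow(x$bonds),
              if (is.na(x$smiles)) "" else x$smiles))
  invisible(x)
}

# Bond order between atoms i and j (1-based), or NA if not bonded.
bond_order_between <- function(mol, i, j) {
  k <- match(j, mol$adj[[i]])
  if (is.na(k)) NA_character_ else mol$border[[i]][k]
}

# All-pairs topological (shortest path) distances over the heavy-atom graph.
# Cached on first use.
mol_distances <- function(mol) {
  if (!is.null(mol$dist)) return(mol$dist)
  if (mol$n == 0) return(matrix(numeric(0), 0, 0))
  g <- igraph::make_empty_graph(n = mol$n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$a, mol$bonds$b))
  }
  igraph::distances(g)
}

# Attach the cached distance matrix (returns updated molecule).
with_distances <- function(mol) {
  if (is.null(mol$dist)) mol$dist <- mol_distances(mol)
  mol
}

#' Parse SMILES into molecule graphs
#'
#' Each SMILES is canonicalized first (unless `canonicalize = FALSE`), so
#' atom indices refer to heavy atoms in canonical order — the order used in
#' all of the package's file formats.  Hydrogen counts come from explicit
#' hydrogen addition during parsing; hydrogens themselves are not vertices.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional molecule identifiers (defaults to `mol1`, `mol2`, ...).
#' @param canonicalize canonicalize before parsing (recommended; keeps file
#'   atom indices stable).
#' @return a list of `molgraph` objects; unparseable SMILES yield `NULL`
#'   entries (with a warning).
#' @export
#' @examples
#' mol <- parse_smiles("COc1ccccc1")[[1]]
#' mol$sybyl
parse_smiles <- function(smiles, ids = NULL, canonicalize = TRUE) {
  if (length(smiles) == 0) return(list())
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  work <- smiles
  if (canonicalize) {
    can <- canonical_smiles(smiles)
  } else {
    can <- smiles
  }
  res <- vector("list", length(smiles))
  names(res) <- ids
  ok <- which(!is.na(can) & nzchar(can))
  if (!length(ok)) {
    if (length(smiles)) warning("no parseable SMILES in input")
    return(res)
  }
  keys <- paste0("q", ok)
  src <- paste0(can[ok], "\t", keys, collapse = "\n")
  mol2 <- ob_convert("SMI", "MOL2", src, add_h = TRUE)
  sdf <- ob_convert("SMI", "SDF", src)
  blocks <- if (nzchar(mol2)) split_mol2_blocks(mol2) else list()
  sdf_recs <- list()
  if (nzchar(sdf)) {
    recs <- strsplit(sdf, "\\${4}\n?")[[1]]
    for (r in recs) {
      rl <- strsplit(r, "\n", fixed = TRUE)[[1]]
      rl <- rl[cumsum(nzchar(rl)) > 0]   # drop leading blanks
      if (length(rl) >= 1) {
        title <- trimws(rl[1])
        if (nzchar(title)) sdf_recs[[title]] <- rl
      }
    }
  }
  for (i in seq_along(ok)) {
    key <- keys[i]
    blk <- blocks[[key]]
    if (is.null(blk)) next
    parsed <- parse_mol2_block(blk)
    at <- parsed$atoms
    if (is.null(at) || nrow(at) == 0) next
    heavy <- which(at$sybyl != "H")
    nh <- length(heavy)
    if (nh == 0) next
    # hydrogens are appended after heavy atoms by OpenBabel; count them
    hcount <- integer(nh)
    remap <- match(seq_len(nrow(at)), heavy)   # old index -> heavy index
    bonds <- parsed$bonds
    keep <- logical(0)
    if (!is.null(bonds) && nrow(bonds) > 0) {
      for (k in seq_len(nrow(bonds))) {
        a <- bonds$a[k]; b <- bonds$b[k]
        ah <- !is.na(remap[a]); bh <- !is.na(remap[b])
        if (ah && !bh) hcount[remap[a]] <- hcount[remap[a]] + 1L
        if (bh && !ah) hcount[remap[b]] <- hcount[remap[b]] + 1L
        keep <- c(keep, ah && bh)
      }
      bonds <- bonds[keep, , drop = FALSE]
      bonds$a <- remap[bonds$a]
      bonds$b <- remap[bonds$b]
    }
    sybyl <- at$sybyl[heavy]
    elem <- sybyl_element(sybyl)
    charge <- integer(nh)
    srec <- sdf_recs[[key]]
    if (!is.null(srec)) charge <- sdf_formal_charges(srec, nh)
    # OpenBabel writes delocalized carboxylate/nitro-style groups with "ar"
    # bonds to O.co2 oxygens; localize them (one double bond to an uncharged
    # oxygen, single bonds to the rest) so they are not treated as aromatic.
    if (!is.null(bonds) && nrow(bonds) > 0) {
      oco2 <- which(sybyl == "O.co2")
      if (length(oco2)) {
        centers <- unique(unlist(lapply(oco2, function(o) {
          k <- which((bonds$a == o | bonds$b == o) & bonds$order == "ar")
          setdiff(c(bonds$a[k], bonds$b[k]), o)
        })))
        for (ctr in centers) {
          k <- which(((bonds$a == ctr & bonds$b %in% oco2) |
                      (bonds$b == ctr & bonds$a %in% oco2)) &
                     bonds$order == "ar")
          if (!length(k)) next
          oxy <- ifelse(bonds$a[k] == ctr, bonds$b[k], bonds$a[k])
          dbl <- k[order(charge[oxy] != 0)][1]   # prefer uncharged O for "="
          bonds$order[k] <- "1"
          bonds$order[dbl] <- "2"
        }
      }
    }
    arom <- grepl("\\.ar$", sybyl) & elem != "O"
    # atoms in aromatic bonds are aromatic even if typed otherwise (e.g. N.am)
    if (!is.null(bonds) && nrow(bonds) > 0) {
      arom_b <- bonds$order == "ar"
      arom[unique(c(bonds$a[arom_b], bonds$b[arom_b]))] <- TRUE
    }
    mol <- new_molgraph(elem, sybyl, arom, hcount, charge, bonds,
                        id = ids[ok[i]], smiles = can[ok[i]])
    res[[ok[i]]] <- with_distances(mol)
  }
  nbad <- sum(vapply(res, is.null, TRUE))
  if (nbad > 0) warning(sprintf("%d SMILES could not be parsed", nbad))
  res
}

# SMILES default ("organic subset") valences used when deciding whether a
# written atom needs brackets.
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1)

# numeric bond order for valence bookkeeping
bond_order_num <- function(o) {
  switch(o, "1" = 1, "2" = 2, "3" = 3, "ar" = 1.5, 1)
}

#' Write a molecule graph as SMILES
#'
#' Emits SMILES from the internal graph representation (used for generated
#' metabolite structures).  The output is intended to be re-parsed and
#' canonicalized by OpenBabel; [sanitize_smiles()] does exactly that.
#'
#' @param mol a `molgraph`.
#' @param atoms optional 1-based atom subset (a connected component); default
#'   all atoms.
#' @return a SMILES string (possibly dot-disconnected).
#' @keywords internal
write_smiles <- function(mol, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(mol$n)
  if (!length(atoms)) return("")
  atoms <- sort(unique(atoms))

  atom_token <- function(i) {
    el <- mol$elem[i]
    ar <- isTRUE(mol$arom[i])
    sym <- if (ar && el %in% c("B", "C", "N", "O", "P", "S", "Se", "As")) {
      tolower(el)
    } else el
    ch <- mol$charge[i]
    h <- mol$hcount[i]
    need_bracket <- FALSE
    if (!(el %in% names(.default_valence))) need_bracket <- TRUE
    if (ch != 0) need_bracket <- TRUE
    if (ar && el != "C" && h > 0) need_bracket <- TRUE  # e.g. [nH]
    if (!need_bracket && el %in% names(.default_valence) && !ar) {
      # bracket if hydrogen count differs from the SMILES implicit default
      bsum <- 0
      for (k in seq_along(mol$adj[[i]])) {
        bsum <- bsum + bond_order_num(mol$border[[i]][k])
      }
      dv <- .default_valence[[el]]
      if (el %in% c("S", "P")) {
        # hypervalent S/P: implicit default steps up
        while (dv < bsum && dv + 2 <= 6) dv <- dv + 2
      }
      impl <- max(0, round(dv - bsum))
      if (impl != h) need_bracket <- TRUE
    }
    if (!need_bracket) return(sym)
    chs <- if (ch == 0) "" else if (ch == 1) "+" else if (ch == -1) "-" else
      sprintf("%+d", ch)
    hs <- if (h == 0) "" else if (h == 1) "H" else paste0("H", h)
    paste0("[", sym, hs, chs, "]")
  }

  bond_token <- function(i, j, o) {
    if (o == "2") return("=")
    if (o == "3") return("#")
    if (o == "ar") return("")            # aromatic default
    if (isTRUE(mol$arom[i]) && isTRUE(mol$arom[j]) && o == "1") return("-")
    ""
  }

  in_set <- rep(FALSE, mol$n)
  in_set[atoms] <- TRUE
  `%||%` <- function(a, b) if (is.null(a)) b else a
  ring_label <- function(no) if (no <= 9) as.character(no) else paste0("%", no)

  # Pass 1: DFS to classify edges.  Non-tree (back) edges become ring
  # closures: the digit is emitted at the atom that discovers the edge (the
  # descendant) and the matching "open" digit at the ancestor.
  pre_visited <- rep(FALSE, mol$n)
  back_edges <- list()       # key -> c(discoverer, ancestor)
  pre_dfs <- function(i, parent) {
    pre_visited[i] <<- TRUE
    nbrs <- mol$adj[[i]]
    for (j in nbrs) {
      if (!in_set[j] || identical(j, parent)) next
      if (pre_visited[j]) {
        key <- paste(min(i, j), max(i, j))
        if (is.null(back_edges[[key]])) back_edges[[key]] <<- c(i, j)
      } else {
        pre_dfs(j, i)
      }
    }
  }
  roots <- integer(0)
  for (a in atoms) {
    if (!pre_visited[a]) {
      pre_dfs(a, NA_integer_)
      roots <- c(roots, a)
    }
  }
  ring_no <- 0L
  ring_num <- list()                       # key -> digit
  ring_open_labels <- vector("list", mol$n)
  for (key in names(back_edges)) {
    ring_no <- ring_no + 1L
    ring_num[[key]] <- ring_no
    anc <- back_edges[[key]][2]
    ring_open_labels[[anc]] <- paste0(ring_open_labels[[anc]] %||% "",
                                      ring_label(ring_no))
  }

  # Pass 2: emit, mirroring the same traversal order so edge classification
  # agrees with pass 1.
  visited <- rep(FALSE, mol$n)
  emit <- function(i, parent) {
    visited[i] <<- TRUE
    nbrs <- mol$adj[[i]]
    ords <- mol$border[[i]]
    closures <- ""
    segs <- character(0)
    for (k in seq_along(nbrs)) {
      j <- nbrs[k]
      if (!in_set[j] || identical(j, parent)) next
      if (visited[j]) {
        key <- paste(min(i, j), max(i, j))
        be <- back_edges[[key]]
        if (!is.null(be) && be[1] == i) {
          closures <- paste0(closures, bond_token(i, j, ords[k]),
                             ring_label(ring_num[[key]]))
        }
      } else {
        segs <- c(segs, paste0(bond_token(i, j, ords[k]), emit(j, i)))
      }
    }
    part <- paste0(atom_token(i), ring_open_labels[[i]] %||% "", closures)
    if (length(segs) > 1) {
      part <- paste0(part,
                     paste0("(", segs[-length(segs)], ")", collapse = ""),
                     segs[length(segs)])
    } else if (length(segs) == 1) {
      part <- paste0(part, segs[1])
    }
    part
  }
  comps <- character(0)
  for (a in roots) {
    if (!visited[a]) comps <- c(comps, emit(a, NA_integer_))
  }
  paste(comps, collapse = ".")
}

#' Sanitize a SMILES string
#'
#' Round-trips a SMILES through OpenBabel canonicalization; returns the
#' canonical SMILES on success and `NA` when the structure does not
#' sanitize (unparseable, impossible valence, broken aromaticity).
#'
#' @param smiles a SMILES string.
#' @return canonical SMILES or `NA_character_`.
#' @export
sanitize_smiles <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(NA_character_)
  canonical_smiles(smiles)[1]
}

#' Read molecules from a SMILES or SDF file
#'
#' @param path a `.smi`/`.smiles` file (SMILES, optional whitespace-separated
#'   id per line, `#` comments) or an `.sdf` file (V2000).
#' @return list of `molgraph` objects named by molecule id.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("sdf", "mol")) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    smi <- ob_convert("SDF", "CAN", txt)
    if (!nzchar(smi)) stop("no parseable molecules in SDF: ", path)
    lines <- strsplit(smi, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) >= 2 && nzchar(trimws(p[2]))) trimws(p[2])
      else paste0("mol", i)
    }, "")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) stop("no molecules in file: ", path)
    parts <- strsplit(lines, "[[:space:]]+")
    smiles <- vapply(parts, `[`, "", 1)
    ids <- vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) >= 2) p[2] else paste0("mol", i)
    }, "")
  }
  parse_smiles(smiles, ids = ids)
}
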