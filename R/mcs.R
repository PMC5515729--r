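# Maximum common substructure and MCS-based SOM extraction.
#
# The MCS flavor is connected, element-exact, aromaticity-exact and
# bond-order-exact: oxidation-state changes must break the mapping.  Sizes
# here are curated metabolic reactions (tens of heavy atoms), so a plain
# backtracking search over connected common subgraphs is adequate.

# Compatibility of atoms (a in mol1, b in mol2) for the MCS.
.mcs_atom_ok <- function(m1, a, m2, b) {
  m1$elem[a] == m2$elem[b] && isTRUE(m1$arom[a]) == isTRUE(m2$arom[b])
}

#' Maximum common connected substructure of two molecules
#'
#' Backtracking search for the largest connected common subgraph under
#' element-, aromaticity- and bond-order-exact matching.  Ties return the
#' first maximum found (deterministic for fixed input order).
#'
#' @param mol1,mol2 `molgraph` objects.
#' @return a list with `map1` (atoms of `mol1`, 1-based), `map2` (matched
#'   atoms of `mol2`, aligned with `map1`) and `size`; `size` 0 when the
#'   molecules share no atom.
#' @export
mcs_common <- function(mol1, mol2) {
  best <- list(map1 = integer(0), map2 = integer(0), size = 0L)
  if (mol1$n == 0 || mol2$n == 0) return(best)

  n1 <- mol1$n
  upper <- min(n1, mol2$n)

  # Branch-and-bound over connected extensions.  At each step the first
  # frontier atom is either mapped to some compatible mol2 atom, or
  # excluded from the current subtree — complete and free of
  # permutation-order duplicates.  The bound counts mol1 atoms still
  # reachable from the frontier through non-excluded atoms.
  grow <- function(map1, map2, frontier, excluded) {
    if (length(map1) > best$size) {
      best <<- list(map1 = map1, map2 = map2, size = length(map1))
    }
    if (best$size == upper) return()
    frontier <- frontier[!frontier %in% excluded]
    if (!length(frontier)) return()
    # reachability bound
    seen <- rep(FALSE, n1)
    seen[map1] <- TRUE
    seen[excluded] <- TRUE
    stack <- frontier
    reach <- 0L
    while (length(stack)) {
      a <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[a]) next
      seen[a] <- TRUE
      reach <- reach + 1L
      stack <- c(stack, mol1$adj[[a]])
    }
    if (length(map1) + reach <= best$size) return()

    a <- frontier[1]
    nb1 <- mol1$adj[[a]]
    anchored <- which(nb1 %in% map1)
    if (length(anchored)) {
      first_nb <- nb1[anchored[1]]
      b_cands <- mol2$adj[[map2[match(first_nb, map1)]]]
      for (b in b_cands) {
        if (b %in% map2) next
        if (!.mcs_atom_ok(mol1, a, mol2, b)) next
        ok <- TRUE
        for (k in anchored) {
          x1 <- nb1[k]
          o1 <- mol1$border[[a]][k]
          x2 <- map2[match(x1, map1)]
          o2 <- bond_order_between(mol2, b, x2)
          if (is.na(o2) || o1 != o2) { ok <- FALSE; break }
        }
        if (!ok) next
        nm1 <- c(map1, a)
        nf <- unique(c(frontier[-1], setdiff(mol1$adj[[a]], nm1)))
        grow(nm1, c(map2, b), nf[!nf %in% nm1], excluded)
      }
    }
    # exclude branch
    grow(map1, map2, frontier[-1], c(excluded, a))
  }

  # seed a is the minimal mol1 atom of the subgraph, so smaller atoms are
  # excluded — each connected subgraph is enumerated from one seed only
  for (a in seq_len(n1)) {
    if (best$size == upper) break
    for (b in seq_len(mol2$n)) {
      if (best$size == upper) break
      if (!.mcs_atom_ok(mol1, a, mol2, b)) next
      grow(a, b, setdiff(mol1$adj[[a]], a),
           if (a > 1) seq_len(a - 1L) else integer(0))
    }
  }
  best
}

#' SOM atoms of a substrate by MCS diff against a product
#'
#' Substrate atoms outside the maximum common substructure, plus MCS atoms
#' whose local environment differs between the two molecules (heavy-atom
#' degree, hydrogen count, or the multiset of incident bond orders).  When
#' the raw set contains an O/N/S heteroatom adjacent to a removed alkyl
#' carbon (dealkylation), the set reduces to the heteroatom(s).
#'
#' @param substrate,product `molgraph` objects.
#' @return integer vector of 1-based substrate atom indices.
#' @export
#' @examples
#' s <- parse_smiles("COc1ccccc1")[[1]]  # anisole
#' p <- parse_smiles("Oc1ccccc1")[[1]]   # phenol
#' soms_by_mcs(s, p)                     # the ether oxygen
soms_by_mcs <- function(substrate, product) {
  mcs <- mcs_common(substrate, product)
  if (mcs$size == 0) {
    stop("ambiguous reaction center: substrate and product share no ",
         "common substructure")
  }
  uncovered <- setdiff(seq_len(substrate$n), mcs$map1)
  changed <- integer(0)
  env_sig <- function(mol, i) {
    paste(length(mol$adj[[i]]), mol$hcount[i], mol$charge[i],
          paste(sort(mol$border[[i]]), collapse = ","), sep = "|")
  }
  for (j in seq_along(mcs$map1)) {
    a <- mcs$map1[j]; b <- mcs$map2[j]
    if (!identical(env_sig(substrate, a), env_sig(product, b))) {
      changed <- c(changed, a)
    }
  }
  raw <- sort(unique(c(uncovered, changed)))
  if (!length(raw)) {
    stop("ambiguous reaction center: substrate and product are identical ",
         "under the common-substructure diff")
  }
  # heteroatom convention for dealkylations: the O/N/S atom is the SOM
  het <- raw[substrate$elem[raw] %in% c("O", "N", "S")]
  if (length(het)) {
    for (h in het) {
      lost_c <- intersect(substrate$adj[[h]],
                          uncovered[substrate$elem[uncovered] == "C"])
      if (length(lost_c)) {
        drop <- unlist(lapply(lost_c, function(c0) {
          c(c0, reachable_avoiding(substrate, c0, h))
        }))
        raw <- setdiff(raw, setdiff(drop, h))
      }
    }
  }
  sort(unique(raw))
}

# Atoms reachable from `start` without passing through `block`.
reachable_avoiding <- function(mol, start, block) {
  seen <- rep(FALSE, mol$n)
  seen[block] <- TRUE
  stack <- start
  out <- integer(0)
  while (length(stack)) {
    a <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[a]) next
    seen[a] <- TRUE
    out <- c(out, a)
    stack <- c(stack, mol$adj[[a]][!seen[mol$adj[[a]]]])
  }
  setdiff(out, start)
}
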