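# Reaction SMARTS engine.
#
# A purpose-built matcher and transformation engine for the SMARTS subset
# used by metabolic reaction patterns: element primitives (aliphatic /
# aromatic / wildcard), H-count, connectivity (X), formal charge, atom
# maps, bond primitives (- = # : ~ and the single-or-aromatic default),
# branches and ring closures.  Application semantics follow the usual
# reaction-transform conventions: mapped atoms persist (bonds re-wired to
# the product template), unmapped reactant atoms are deleted together with
# fragments only reachable through them, unmapped product atoms are
# created, and hydrogen counts are re-derived from valence.

.two_letter_elems <- c("Cl", "Br", "Si", "Se", "As", "Sn", "Ge", "Gd",
                       "Pt", "Co", "Mn", "Zn", "Na", "Li", "Mg", "Al",
                       "Ca", "Fe", "Cu")

# ---- parsing ---------------------------------------------------------------

# Parse the inside of a bracket atom "[...]" (without the brackets).
parse_bracket_atom <- function(s, where) {
  atom <- list(elem = NA_character_, arom = NA, hcount = NA_integer_,
               degree = NA_integer_, charge = NA_integer_, map = NA_integer_)
  i <- 1L
  n <- nchar(s)
  getnum <- function() {
    j <- i
    while (j <= n && grepl("[0-9]", substr(s, j, j))) j <- j + 1L
    if (j == i) return(NA_integer_)
    v <- as.integer(substr(s, i, j - 1))
    i <<- j
    v
  }
  first <- TRUE
  while (i <= n) {
    ch <- substr(s, i, i)
    two <- if (i < n) substr(s, i, i + 1) else ""
    if (first && two %in% .two_letter_elems) {
      atom$elem <- two; atom$arom <- FALSE; i <- i + 2L; first <- FALSE
    } else if (first && ch == "#") {
      i <- i + 1L
      z <- getnum()
      if (is.na(z)) stop("bad atomic number in SMARTS: ", where)
      sym <- c("6" = "C", "7" = "N", "8" = "O", "16" = "S", "15" = "P")[
        as.character(z)]
      if (is.na(sym)) stop("unsupported atomic number #", z, " in ", where)
      atom$elem <- sym; atom$arom <- NA; first <- FALSE
    } else if (first && ch %in% c("C", "N", "O", "S", "P", "B", "F", "I")) {
      atom$elem <- ch; atom$arom <- FALSE; i <- i + 1L; first <- FALSE
    } else if (first && ch %in% c("c", "n", "o", "s", "p", "b")) {
      atom$elem <- toupper(ch); atom$arom <- TRUE; i <- i + 1L; first <- FALSE
    } else if (first && ch == "*") {
      atom$elem <- "*"; atom$arom <- NA; i <- i + 1L; first <- FALSE
    } else if (!first && ch == "H") {
      i <- i + 1L
      v <- getnum()
      atom$hcount <- if (is.na(v)) 1L else v
    } else if (!first && ch == "X") {
      i <- i + 1L
      v <- getnum()
      if (is.na(v)) stop("X requires a digit in ", where)
      atom$degree <- v
    } else if (!first && ch == "+") {
      i <- i + 1L
      v <- getnum()
      atom$charge <- if (is.na(v)) 1L else v
    } else if (!first && ch == "-") {
      i <- i + 1L
      v <- getnum()
      atom$charge <- if (is.na(v)) -1L else -v
    } else if (!first && ch == ":") {
      i <- i + 1L
      v <- getnum()
      if (is.na(v)) stop("atom map requires a number in ", where)
      atom$map <- v
    } else {
      stop(sprintf("unsupported SMARTS primitive '%s' in '%s'", ch, where))
    }
  }
  if (is.na(atom$elem)) stop("bracket atom without element in ", where)
  atom
}

# Parse one connected SMARTS component into a pattern graph:
# list(atoms = list of atom specs, bonds = data.frame(a, b, order)).
parse_smarts_component <- function(s) {
  atoms <- list()
  bonds <- data.frame(a = integer(0), b = integer(0), order = character(0),
                      stringsAsFactors = FALSE)
  stack <- integer(0)
  prev <- NA_integer_
  pending <- NA_character_
  rings <- list()   # digit -> list(atom, order)
  i <- 1L
  n <- nchar(s)
  add_atom <- function(atom) {
    atoms[[length(atoms) + 1L]] <<- atom
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[nrow(bonds) + 1L, ] <<- list(prev, idx, pending)
    }
    prev <<- idx
    pending <<- NA_character_
    idx
  }
  add_ring <- function(d) {
    key <- as.character(d)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, order = pending)
    } else {
      o <- rings[[key]]$order
      if (is.na(o)) o <- pending
      bonds[nrow(bonds) + 1L, ] <<- list(rings[[key]]$atom, prev, o)
      rings[[key]] <<- NULL
    }
    pending <<- NA_character_
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    two <- if (i < n) substr(s, i, i + 1) else ""
    if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket in SMARTS: ", s)
      add_atom(parse_bracket_atom(substr(s, i + 1, i + j - 2), s))
      i <- i + j
    } else if (two %in% c("Cl", "Br")) {
      add_atom(list(elem = two, arom = FALSE, hcount = NA_integer_,
                    degree = NA_integer_, charge = NA_integer_,
                    map = NA_integer_))
      i <- i + 2L
    } else if (ch %in% c("C", "N", "O", "S", "P", "B", "F", "I")) {
      add_atom(list(elem = ch, arom = FALSE, hcount = NA_integer_,
                    degree = NA_integer_, charge = NA_integer_,
                    map = NA_integer_))
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s", "p", "b")) {
      add_atom(list(elem = toupper(ch), arom = TRUE, hcount = NA_integer_,
                    degree = NA_integer_, charge = NA_integer_,
                    map = NA_integer_))
      i <- i + 1L
    } else if (ch == "*") {
      add_atom(list(elem = "*", arom = NA, hcount = NA_integer_,
                    degree = NA_integer_, charge = NA_integer_,
                    map = NA_integer_))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS: ", s)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      add_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      add_ring(substr(s, i + 1, i + 2))
      i <- i + 3L
    } else {
      stop(sprintf("unsupported SMARTS character '%s' in '%s'", ch, s))
    }
  }
  if (length(rings)) stop("unclosed ring bond in SMARTS: ", s)
  if (!length(atoms)) stop("empty SMARTS component: ", s)
  list(atoms = atoms, bonds = bonds)
}

# Adjacency lists for a pattern graph.
pattern_adjacency <- function(pat) {
  n <- length(pat$atoms)
  adj <- replicate(n, integer(0), simplify = FALSE)
  bord <- replicate(n, character(0), simplify = FALSE)
  if (nrow(pat$bonds)) {
    for (k in seq_len(nrow(pat$bonds))) {
      a <- pat$bonds$a[k]; b <- pat$bonds$b[k]; o <- pat$bonds$order[k]
      adj[[a]] <- c(adj[[a]], b); bord[[a]] <- c(bord[[a]], o)
      adj[[b]] <- c(adj[[b]], a); bord[[b]] <- c(bord[[b]], o)
    }
  }
  pat$adj <- adj
  pat$bord <- bord
  pat
}

#' Parse a reaction SMARTS string
#'
#' `reactants >> products`, each side possibly dot-separated into
#' components.  The reactant side must be a single connected component.
#'
#' @param smarts the reaction SMARTS text.
#' @return an object of class `reaction_smarts` with elements `reactant`
#'   (pattern graph), `products` (list of pattern graphs), `rmap` / `pmap`
#'   (map number -> atom position lookups) and `smarts`.
#' @export
#' @examples
#' rx <- parse_reaction_smarts("[O:1][CH3]>>[O:1]")
parse_reaction_smarts <- function(smarts) {
  sides <- strsplit(smarts, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2 || !nzchar(trimws(sides[1])) ||
      !nzchar(trimws(sides[2]))) {
    stop("reaction SMARTS must have the form 'reactants>>products': ", smarts)
  }
  rparts <- strsplit(trimws(sides[1]), ".", fixed = TRUE)[[1]]
  pparts <- strsplit(trimws(sides[2]), ".", fixed = TRUE)[[1]]
  rcomp <- lapply(rparts, parse_smarts_component)
  if (length(rcomp) != 1) {
    stop("multi-component reactant patterns are not supported: ", smarts)
  }
  reactant <- pattern_adjacency(rcomp[[1]])
  products <- lapply(lapply(pparts, parse_smarts_component),
                     pattern_adjacency)
  maps_of <- function(pat) {
    m <- vapply(pat$atoms, function(a) a$map, 1L)
    stats::setNames(which(!is.na(m)), m[!is.na(m)])
  }
  rmap <- maps_of(reactant)
  pmap_list <- lapply(products, maps_of)
  all_p <- unlist(lapply(pmap_list, names))
  if (!length(rmap) || !length(all_p)) {
    stop("reaction SMARTS needs at least one mapped atom per side: ", smarts)
  }
  if (anyDuplicated(names(rmap)) || anyDuplicated(all_p)) {
    stop("duplicate atom map number in: ", smarts)
  }
  structure(list(reactant = reactant, products = products,
                 rmap = rmap, pmaps = pmap_list, smarts = smarts),
            class = "reaction_smarts")
}

#' @export
print.reaction_smarts <- function(x, ...) {
  cat(sprintf("<reaction_smarts %s: %d reactant atoms, %d product component(s)>\n",
              x$smarts, length(x$reactant$atoms), length(x$products)))
  invisible(x)
}

# ---- matching --------------------------------------------------------------

# Does molecule atom i satisfy pattern atom spec p?
atom_matches <- function(mol, i, p) {
  if (p$elem != "*") {
    if (mol$elem[i] != p$elem) return(FALSE)
    if (!is.na(p$arom) && isTRUE(mol$arom[i]) != p$arom) return(FALSE)
  }
  if (!is.na(p$hcount) && mol$hcount[i] != p$hcount) return(FALSE)
  # X counts total connections, hydrogens included (SMARTS convention)
  if (!is.na(p$degree) &&
      length(mol$adj[[i]]) + mol$hcount[i] != p$degree) return(FALSE)
  if (!is.na(p$charge) && mol$charge[i] != p$charge) return(FALSE)
  TRUE
}

# Does molecule bond order `mo` satisfy pattern bond primitive `po`?
bond_matches <- function(mo, po) {
  if (is.na(po)) return(mo %in% c("1", "ar"))   # single-or-aromatic default
  switch(po,
         "-" = mo == "1",
         "=" = mo == "2",
         "#" = mo == "3",
         ":" = mo == "ar",
         "~" = TRUE,
         FALSE)
}

#' Match a SMARTS pattern graph against a molecule
#'
#' Backtracking subgraph matcher.  Mappings are injective on atoms; bonds of
#' the pattern must be present in the molecule with a compatible order
#' (non-pattern molecule bonds between matched atoms are allowed, as usual
#' for substructure — not induced-subgraph — matching).
#'
#' @param mol a `molgraph`.
#' @param pat a pattern graph from [parse_smarts_component()] (with
#'   adjacency, as stored in a `reaction_smarts`).
#' @param anchor optional `c(pattern_atom, mol_atom)` pair that must be part
#'   of every returned match.
#' @param max_matches stop after this many matches.
#' @return list of integer vectors mapping pattern atom positions to
#'   molecule atom indices (1-based); empty list when there is no match.
#' @keywords internal
match_smarts <- function(mol, pat, anchor = NULL, max_matches = 256L) {
  np <- length(pat$atoms)
  if (mol$n == 0 || np == 0) return(list())
  if (is.null(pat$adj)) pat <- pattern_adjacency(pat)

  # visit order: DFS over the pattern graph starting from the anchor atom
  # (or atom 1), so each new atom is adjacent to an already-placed one
  start <- if (!is.null(anchor)) anchor[1] else 1L
  order <- integer(0)
  seen <- rep(FALSE, np)
  stack <- start
  while (length(stack)) {
    a <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (seen[a]) next
    seen[a] <- TRUE
    order <- c(order, a)
    stack <- c(stack, rev(pat$adj[[a]]))
  }
  if (any(!seen)) stop("disconnected SMARTS pattern component")

  pos <- match(seq_len(np), order)     # pattern atom -> position in order
  matches <- list()
  assign <- rep(NA_integer_, np)
  used <- rep(FALSE, mol$n)

  place <- function(step) {
    if (length(matches) >= max_matches) return()
    if (step > np) {
      matches[[length(matches) + 1L]] <<- assign
      return()
    }
    pa <- order[step]
    spec <- pat$atoms[[pa]]
    # candidates: anchored, or neighbors of an already-placed pattern atom
    placed_nbrs <- pat$adj[[pa]][!is.na(assign[pat$adj[[pa]]])]
    cands <- if (!is.null(anchor) && pa == anchor[1]) {
      anchor[2]
    } else if (length(placed_nbrs)) {
      mol$adj[[assign[placed_nbrs[1]]]]
    } else {
      seq_len(mol$n)
    }
    for (cm in cands) {
      if (used[cm]) next
      if (!atom_matches(mol, cm, spec)) next
      ok <- TRUE
      for (k in seq_along(pat$adj[[pa]])) {
        pb <- pat$adj[[pa]][k]
        if (is.na(assign[pb])) next
        mo <- bond_order_between(mol, cm, assign[pb])
        if (is.na(mo) || !bond_matches(mo, pat$bord[[pa]][k])) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      assign[pa] <<- cm
      used[cm] <<- TRUE
      place(step + 1L)
      assign[pa] <<- NA_integer_
      used[cm] <<- FALSE
    }
  }
  place(1L)
  unique(matches)
}

# ---- application -----------------------------------------------------------

# Resolve the default bond order for a product-template bond.
product_bond_order <- function(po, arom_a, arom_b) {
  if (!is.na(po)) {
    return(switch(po, "-" = "1", "=" = "2", "#" = "3", ":" = "ar", "~" = "1"))
  }
  if (isTRUE(arom_a) && isTRUE(arom_b)) "ar" else "1"
}

#' Apply a reaction SMARTS transformation to a molecule
#'
#' Enumerates matches of the reactant pattern (optionally anchored so that
#' a designated mapped atom lands on a given molecule atom) and builds the
#' product structure(s) for each match.  Products that fail sanitization
#' are dropped.
#'
#' @param mol a `molgraph`.
#' @param rxn a [parse_reaction_smarts()] object (or a reaction SMARTS
#'   string).
#' @param anchor_atom optional 1-based molecule atom that the
#'   `anchor_map`-numbered pattern atom must match.
#' @param anchor_map map number anchored to `anchor_atom` (default: the
#'   lowest map number on the reactant side).
#' @return list of match results, each a list with `mapping` (pattern ->
#'   molecule atoms) and `products` (character vector of canonical product
#'   SMILES, one per product template component; unsanitizable components
#'   are dropped — an empty vector means the match produced nothing valid).
#' @export
#' @examples
#' mol <- parse_smiles("COc1ccccc1")[[1]]
#' res <- apply_reaction(mol, "[O:1][CH3]>>[O:1]")
#' res[[1]]$products   # "Oc1ccccc1"
apply_reaction <- function(mol, rxn, anchor_atom = NULL, anchor_map = NULL) {
  if (is.character(rxn)) rxn <- parse_reaction_smarts(rxn)
  stopifnot(inherits(rxn, "reaction_smarts"))
  anchor <- NULL
  if (!is.null(anchor_atom)) {
    if (is.null(anchor_map)) {
      anchor_map <- min(as.integer(names(rxn$rmap)))
    }
    pa <- rxn$rmap[as.character(anchor_map)]
    if (is.na(pa)) stop("anchor map ", anchor_map, " not on reactant side")
    anchor <- c(unname(pa), anchor_atom)
  }
  ms <- match_smarts(mol, rxn$reactant, anchor = anchor)
  lapply(ms, function(m) {
    list(mapping = m, products = build_products(mol, rxn, m))
  })
}

# Construct product SMILES for one reactant match.
build_products <- function(mol, rxn, mapping) {
  rpat <- rxn$reactant
  np <- length(rpat$atoms)
  rmapnum <- vapply(rpat$atoms, function(a) a$map, 1L)
  mapped_idx <- which(!is.na(rmapnum))
  unmapped_idx <- which(is.na(rmapnum))
  deleted <- mapping[unmapped_idx]

  # working copy of the molecule as editable vectors
  elem <- mol$elem; arom <- mol$arom; hcount <- mol$hcount
  charge <- mol$charge; sybyl <- mol$sybyl
  bonds <- mol$bonds
  touched <- rep(FALSE, mol$n)

  # 1. remove bonds that the reactant template spans between mapped atoms
  if (nrow(rpat$bonds)) {
    drop <- logical(nrow(bonds))
    for (k in seq_len(nrow(rpat$bonds))) {
      pa <- rpat$bonds$a[k]; pb <- rpat$bonds$b[k]
      if (is.na(rmapnum[pa]) || is.na(rmapnum[pb])) next
      a <- mapping[pa]; b <- mapping[pb]
      hit <- (bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a)
      drop <- drop | hit
      touched[c(a, b)] <- TRUE
    }
    bonds <- bonds[!drop, , drop = FALSE]
  }

  # 2. create product-template atoms / re-wire mapped atoms
  new_atoms <- list()    # appended after mol$n
  comp_of_new <- integer(0)
  atom_of_map <- stats::setNames(mapping[mapped_idx], rmapnum[mapped_idx])
  prod_atom_id <- list()  # per product component: template position -> atom id
  h_explicit_old <- rep(FALSE, mol$n)   # product template fixed the H count
  next_id <- mol$n

  for (ci in seq_along(rxn$products)) {
    ppat <- rxn$products[[ci]]
    ids <- integer(length(ppat$atoms))
    for (ai in seq_along(ppat$atoms)) {
      spec <- ppat$atoms[[ai]]
      if (!is.na(spec$map)) {
        a <- atom_of_map[as.character(spec$map)]
        if (is.na(a)) stop("product map ", spec$map, " missing on reactant side")
        ids[ai] <- a
        if (spec$elem != "*") {
          elem[a] <- spec$elem
          if (!is.na(spec$arom)) arom[a] <- spec$arom
        }
        if (!is.na(spec$charge)) charge[a] <- spec$charge
        if (!is.na(spec$hcount)) {
          hcount[a] <- spec$hcount
          h_explicit_old[a] <- TRUE
        }
        touched[a] <- TRUE
      } else {
        next_id <- next_id + 1L
        ids[ai] <- next_id
        new_atoms[[length(new_atoms) + 1L]] <- spec
        comp_of_new <- c(comp_of_new, ci)
      }
    }
    prod_atom_id[[ci]] <- ids
  }

  n_all <- next_id
  elem <- c(elem, vapply(new_atoms, function(a) a$elem, ""))
  arom <- c(arom, vapply(new_atoms, function(a) isTRUE(a$arom), TRUE))
  hcount <- c(hcount, vapply(new_atoms, function(a)
    if (is.na(a$hcount)) NA_integer_ else a$hcount, 1L))
  charge <- c(charge, vapply(new_atoms, function(a)
    if (is.na(a$charge)) 0L else a$charge, 1L))

  # 3. add product-template bonds
  for (ci in seq_along(rxn$products)) {
    ppat <- rxn$products[[ci]]
    ids <- prod_atom_id[[ci]]
    if (nrow(ppat$bonds)) {
      for (k in seq_len(nrow(ppat$bonds))) {
        pa <- ppat$bonds$a[k]; pb <- ppat$bonds$b[k]
        a <- ids[pa]; b <- ids[pb]
        o <- product_bond_order(ppat$bonds$order[k],
                                arom[a], arom[b])
        # replace any surviving bond between a and b
        hit <- (bonds$a == a & bonds$b == b) | (bonds$a == b & bonds$b == a)
        bonds <- bonds[!hit, , drop = FALSE]
        bonds[nrow(bonds) + 1L, ] <- list(a, b, o)
        if (a <= mol$n) touched[a] <- TRUE
        if (b <= mol$n) touched[b] <- TRUE
      }
    }
  }

  # 4. delete atoms matched by unmapped reactant atoms
  keep <- setdiff(seq_len(n_all), deleted)
  bonds <- bonds[!(bonds$a %in% deleted) & !(bonds$b %in% deleted), ,
                 drop = FALSE]
  # neighbors of deleted atoms lose a bond
  touched[intersect(seq_len(mol$n), unique(unlist(
    lapply(deleted, function(d) mol$adj[[d]]))))] <- TRUE

  remap <- match(seq_len(n_all), keep)
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]
  elem <- elem[keep]; arom <- arom[keep]; hcount <- hcount[keep]
  charge <- charge[keep]
  touched_all <- c(touched, rep(TRUE, length(new_atoms)))[keep]
  h_explicit <- c(h_explicit_old, vapply(new_atoms, function(a)
    !is.na(a$hcount), TRUE))[keep]
  sybyl_all <- c(sybyl, rep("", length(new_atoms)))[keep]
  h_missing <- is.na(hcount)

  out <- new_molgraph(elem, sybyl_all, arom,
                      ifelse(h_missing, 0L, hcount), charge, bonds)

  # 5. re-derive hydrogen counts where bonding changed, unless the product
  # template pinned the count explicitly
  for (i in which((touched_all & !h_explicit) | h_missing)) {
    el <- out$elem[i]
    dv <- .default_valence[el]
    if (is.na(dv)) next
    bsum <- 0
    for (k in seq_along(out$adj[[i]])) {
      bsum <- bsum + bond_order_num(out$border[[i]][k])
    }
    veff <- dv + out$charge[i]
    if (el %in% c("S", "P")) {
      while (veff < bsum && veff + 2 <= 6) veff <- veff + 2
    }
    out$hcount[i] <- max(0L, as.integer(round(veff - bsum)))
  }

  # valence gate: OpenBabel tolerates impossible valences in bracketed
  # SMILES, so over-valent atoms must be rejected here
  if (!valid_valences(out)) return(character(0))

  # 6. split into product molecules: the edited graph's components are
  # grouped by the product template component whose atoms they contain;
  # leftover fragments (only attached via deleted atoms) are dropped
  if (out$n == 0) return(character(0))
  g <- igraph::make_empty_graph(n = out$n, directed = FALSE)
  if (nrow(out$bonds)) {
    g <- igraph::add_edges(g, rbind(out$bonds$a, out$bonds$b))
  }
  comp <- igraph::components(g)$membership
  products <- character(0)
  for (ci in seq_along(rxn$products)) {
    ids <- remap[prod_atom_id[[ci]]]
    ids <- ids[!is.na(ids)]
    if (!length(ids)) next
    members <- which(comp %in% unique(comp[ids]))
    smi <- write_smiles(out, members)
    can <- sanitize_smiles(smi)
    if (!is.na(can)) products <- c(products, can)
  }
  unique(products)
}

# Upper-bound valence check (aromatic bonds counted as single, so this is
# a necessary condition only; it exists to catch over-valent edit results).
.max_valence <- c(B = 3, C = 4, N = 3, O = 2, S = 6, P = 5, Si = 4,
                  F = 1, Cl = 1, Br = 1, I = 1, Se = 6)

valid_valences <- function(mol) {
  for (i in seq_len(mol$n)) {
    mx <- .max_valence[mol$elem[i]]
    if (is.na(mx)) next
    if (mol$elem[i] %in% c("N", "O")) mx <- mx + max(0L, mol$charge[i])
    bsum <- 0
    for (k in seq_along(mol$adj[[i]])) {
      o <- mol$border[[i]][k]
      bsum <- bsum + if (o == "ar") 1 else bond_order_num(o)
    }
    if (bsum + mol$hcount[i] > mx) return(FALSE)
  }
  TRUE
}

# ---- changed-atom analysis (for SOM extraction from patterns) -------------

# Signature of a mapped atom's environment within one side of a reaction
# template: element/arom/charge plus the multiset of (neighbor identity,
# bond order) pairs, with mapped neighbors identified by map number and
# unmapped neighbors by their element.
template_atom_signature <- function(pat, ai) {
  spec <- pat$atoms[[ai]]
  nb <- character(0)
  for (k in seq_along(pat$adj[[ai]])) {
    j <- pat$adj[[ai]][k]
    o <- pat$bord[[ai]][k]
    if (is.na(o)) o <- "d"
    jid <- if (!is.na(pat$atoms[[j]]$map)) {
      paste0("m", pat$atoms[[j]]$map)
    } else {
      paste0("x", pat$atoms[[j]]$elem)
    }
    nb <- c(nb, paste0(jid, "/", o))
  }
  paste(spec$elem,
        if (is.na(spec$arom)) "?" else spec$arom,
        if (is.na(spec$charge)) "?" else spec$charge,
        paste(sort(nb), collapse = ","),
        sep = "|")
}

#' Mapped atoms changed by a reaction template
#'
#' A mapped atom counts as changed when its in-template environment
#' (element, aromaticity, charge, bonds to mapped neighbors by map number
#' and to unmapped neighbors by element) differs between the reactant and
#' product sides, or when it is absent from the product side.
#'
#' @param rxn a `reaction_smarts`.
#' @return integer vector of changed map numbers (sorted).
#' @export
changed_map_atoms <- function(rxn) {
  stopifnot(inherits(rxn, "reaction_smarts"))
  changed <- integer(0)
  for (mn in names(rxn$rmap)) {
    rsig <- template_atom_signature(rxn$reactant, rxn$rmap[[mn]])
    psig <- NULL
    for (ci in seq_along(rxn$products)) {
      pm <- rxn$pmaps[[ci]]
      if (mn %in% names(pm)) {
        psig <- template_atom_signature(rxn$products[[ci]], pm[[mn]])
        break
      }
    }
    if (is.null(psig) || !identical(rsig, psig)) {
      changed <- c(changed, as.integer(mn))
    }
  }
  sort(changed)
}

# Map numbers on the reactant side, in order of appearance in the SMARTS
# text (used for the default reaction-center choice).
reactant_maps_in_order <- function(rxn) {
  m <- vapply(rxn$reactant$atoms, function(a) a$map, 1L)
  m[!is.na(m)]
}

#' The designated reaction-center map number of a pattern
#'
#' The first (in SMARTS text order) mapped reactant atom that
#' [changed_map_atoms()] reports as changed; if none changed, the first
#' mapped atom.  Pattern records may override this with an explicit
#' `center_map`.
#'
#' @param rxn a `reaction_smarts`.
#' @return a map number (integer).
#' @export
default_center_map <- function(rxn) {
  ord <- reactant_maps_in_order(rxn)
  ch <- changed_map_atoms(rxn)
  hit <- ord[ord %in% ch]
  if (length(hit)) hit[1] else ord[1]
}
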