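# Independent oracle implementations, deliberately naive and separate from
# the package's code paths.

# Naive BFS layer counts: returns a list of named count tables per layer
# for one root atom, computed by breadth-first search over the bond graph.
naive_layer_counts <- function(mol, root, n_layers = 6) {
  dist <- rep(NA_integer_, mol$n)
  dist[root] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (a in frontier) {
      for (b in mol$adj[[a]]) {
        if (is.na(dist[b])) {
          dist[b] <- d
          nxt <- c(nxt, b)
        }
      }
    }
    frontier <- unique(nxt)
  }
  types <- vapply(seq_len(mol$n), function(i) assign_atom_type(mol, i), "")
  lapply(seq_len(n_layers) - 1L, function(j) {
    at <- which(!is.na(dist) & dist == j)
    if (!length(at)) return(c(PAD = 1L))
    tab <- table(types[at])
    stats::setNames(as.integer(tab), names(tab))
  })
}

# Term-by-term naive reimplementation of the similarity decision.
naive_is_similar <- function(fa, fb, exact_depth, threshold) {
  n <- nrow(fa)
  for (j in seq_len(min(exact_depth, n))) {
    if (any(fa[j, ] != fb[j, ])) return(FALSE)
  }
  total <- 0
  for (j in seq_len(n)) {
    lambda <- j
    w <- (2 / n) * (lambda / exp(lambda - 1) + (n - 1) / (2 * lambda))
    num <- sum(fa[j, ] * fb[j, ])
    den <- sum(fa[j, ]^2 + fb[j, ]^2 - fa[j, ] * fb[j, ])
    soe <- if (den == 0) 0 else 1 - num / den
    ham <- sum(abs(fa[j, ] - fb[j, ]))
    total <- total + w * soe * ham
  }
  total <= threshold
}

# Exhaustive pair-counting (Mann-Whitney) AUC oracle.
pair_count_auc <- function(scores, labels) {
  pos <- which(labels)
  neg <- which(!labels)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  tot / (length(pos) * length(neg))
}

# Brute-force linear database scan with direct evaluation of the metric
# formulas (no prefix index, no package similarity helpers).
naive_db_scan <- function(db, fp, exact_depth, threshold) {
  count_side <- function(side) {
    tot <- 0L
    for (e in side) {
      if (naive_is_similar(unclass(fp), unclass(e$fp), exact_depth,
                           threshold)) {
        tot <- tot + e$count
      }
    }
    tot
  }
  list(m = count_side(db$substrate), n = count_side(db$center))
}

# Relabel a molgraph under a permutation of its atoms (perm[i] = new index
# of old atom i); used for invariance checks.
permute_molgraph <- function(mol, perm) {
  inv <- integer(mol$n)
  inv[perm] <- seq_len(mol$n)
  bonds <- mol$bonds
  bonds$a <- perm[bonds$a]
  bonds$b <- perm[bonds$b]
  metsite:::new_molgraph(
    elem = mol$elem[inv], sybyl = mol$sybyl[inv],
    arom = mol$arom[inv], hcount = mol$hcount[inv],
    charge = mol$charge[inv], bonds = bonds,
    id = mol$id, smiles = mol$smiles)
}
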