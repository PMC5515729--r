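---
title: "Predicting sites of metabolism with reaction-derived fingerprint databases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting sites of metabolism with reaction-derived fingerprint databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsite)
```

## The model

`metsite` treats metabolism prediction as a retrieval problem over atom
environments. The unit of evidence is one heavy atom of one curated
metabolic reaction. Two databases are built from a reaction corpus:

* the **substrate database** — the layered count fingerprint of *every*
  heavy atom of every substrate, with occurrence counts;
* the **reaction-center database** — the fingerprints of the annotated
  site-of-metabolism (SOM) atoms only, each key carrying the multiset of
  reaction-SMARTS pattern ids observed there.

For a query atom, the number of similar fingerprints in the first
database (`m`) estimates how often this environment has been seen at all;
in the second (`n`), how often it reacted. The raw evidence is then
*corrected*: every center hit proposes the reaction-SMARTS patterns
stored with it, and a hit only stands if at least one of its patterns can
actually be applied with its designated center atom anchored at the query
atom, producing a product that passes valence and sanitization checks.
Hits failing this are counted as `x` and removed from both numerator and
denominator:

$$r_i = \frac{n - x}{m - x}, \qquad p_i = \frac{r_i}{\max_i r_i}.$$

The same applicability check yields the metabolite structures, so site
scoring and structure generation cannot disagree: a site only keeps
reactive credit for transformations that produce a concrete, valid
product. This coupling is what suppresses false-positive metabolites
relative to purely fingerprint-statistical scoring.

### Fingerprints

Each atom's fingerprint is a 6 × 44 count matrix: layer $j$ (rows,
$j = 0..5$) counts the heavy atoms of each type at bond-graph
shortest-path distance exactly $j$ from the root. Hydrogens are never
counted. The column alphabet is 33 base SYBYL/Tripos mol2 atom types, 10
extra elements seen in metabolic corpora (As, Pt, Co, Mn, Zn, Se, Ge, Sn,
Gd, B), and one reserved `PAD` pseudo-type. A layer beyond the molecule's
radius holds a single `PAD` count; this keeps every row nonzero, so the
Soergel metric is always well defined and "missing layer" mismatches
participate in the exact-match filter like any other count difference.
Because the canonical mol2 type list is longer than 33, the base set here
is the 33 heavy-atom chemistry types (5 carbon, 7 nitrogen, 3 oxygen, 4
sulfur types, P.3, the four halogens, Si and eight common metals); the
order is fixed and versioned (`tripos33+10+pad/1`) and serialized keys
embed it. Atom typing and aromaticity perception are delegated to
OpenBabel's mol2 writer; one delocalization artifact (carboxylate-style
groups emitted with "aromatic" bonds to `O.co2` oxygens) is re-localized
during parsing.

### Similarity

Similarity of two fingerprints combines an exact-match prefix with a
weighted score. The prefix requires the first `exact_depth` layers
(default 3 — the root layer counts as the first) to be identical; this
guarantees a small identical core environment and makes retrieval
indexable. The score is

$$d_\mathrm{total} = \sum_{j=0}^{5} \Delta\lambda_{j+1}\, d_j\, d_{\mathrm{Ham},j},
\qquad
\Delta\lambda = \frac{2}{\lambda_\mathrm{total}}\left[\frac{\lambda}{e^{\lambda-1}}
+ \frac{\lambda_\mathrm{total}-1}{2\lambda}\right]$$

with $d_j$ the Soergel distance (complement of the count Tanimoto) and
$d_{\mathrm{Ham},j}$ the Hamming distance of layer $j$, both summed over
the full 44-column width (the extra elements and `PAD` are declared parts
of the fingerprint and must be comparable). The level index is
$\lambda = j + 1$, the only mapping under which the weight formula
($\lambda \ge 1$) covers the root layer; weights then decrease strictly
from $7/6$ at the root to $\approx 0.152$ at layer 6, so inner layers
dominate. Two fingerprints are similar when the prefix matches **and**
$d_\mathrm{total} \le 3.5$, the threshold taken as a fixed constant of
the method (the calibration that produced it is not reproduced here).
The comparison is inclusive exactly as stated.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `exact_depth` | 3 layers | identical-prefix requirement; deeper values retrieve little or nothing, shallower ones admit noise (see the depth sweep) |
| `threshold` | 3.5 (score units) | inclusive similarity cutoff on $d_\mathrm{total}$ |
| `n_layers` | 6 | fingerprint radius in bonds |
| `top_k` | 3 sites | how many ranked sites generate metabolites |

Likelihood categories bin $p$ as very unlikely $[0, 0.15)$, unlikely
$[0.15, 0.33)$, likely $[0.33, 0.66)$, very likely $[0.66, 1]$. The top
bin is closed at 1: max-normalization forces the best site to exactly
1.00, so an open bin would leave the best site of every molecule
uncategorized — the printed bins are treated as a typographical artifact
there.

### Degenerate cases and tie-breaks

* $m = 0$ (environment never seen) and $m = x$ (all evidence corrected
  away) both give $r = 0$: no usable evidence means no predicted
  reactivity. Such sites never generate metabolites.
* If every $r_i = 0$, all $p_i = 0$ (no normalization by zero).
* Ranks order by $p$ descending with lower atom index breaking ties;
  since graph-equivalent atoms have identical fingerprints and hence
  identical $p$, symmetric sites always rank adjacently.
* Metabolites deduplicate by (canonical product SMILES, site equivalence
  class), summing the support of distinct generating patterns; ordering
  is site rank, then support descending, then SMILES.
* A center hit whose key carries several patterns counts toward `x` only
  when *none* of them applies — one generatable product proves the pair
  similar.

## SOM annotation

Training reactions rarely state their SOM explicitly, so it is derived:

1. **provided** — explicit atom indices in the record win;
2. **pattern** — if the record names a reaction-SMARTS pattern, the
   pattern's reactant side is matched and the designated center map atom
   marks the SOM (each pattern carries a `center_map`; the default is the
   first mapped atom whose in-template environment changes between the
   two sides);
3. **mcs-diff** — otherwise a connected, element- and bond-order-exact
   maximum common substructure of substrate and product is computed;
   substrate atoms outside it, plus mapped atoms whose degree/H/bond
   environment differs, form the raw diff. For dealkylations the
   heteroatom convention applies: when the diff pairs an O/N/S atom with
   a leaving alkyl fragment, the heteroatom alone is the SOM.

The bond-order-exact MCS flavor is deliberate: oxidations must break the
mapping at the changed atom, otherwise the diff misses them. Records
failing all three routes (e.g. identity reactions) are curated out as
ambiguous-center records.

## The reaction-SMARTS engine

Pattern matching and product generation run on a purpose-built engine for
the SMARTS subset that metabolic patterns use: element primitives
(aliphatic/aromatic/wildcard), `H`/`X`/charge constraints (`X` counts
hydrogens, per SMARTS convention), atom maps, bond primitives, branches
and ring closures. Application follows the usual transform semantics:
mapped atoms persist with bonds rewritten to the product template,
unmapped reactant atoms are deleted (with fragments reachable only
through them), unmapped product atoms are created, and hydrogen counts
are re-derived from standard valences unless the template pins them.
Products are validated twice: an explicit valence ceiling (OpenBabel will
happily round-trip a pentavalent carbon written in brackets, so this
check cannot be delegated) and canonicalization round-trip. Failing
components are dropped; a match with no valid product is "not
applicable".

## The synthetic dataset generator

The generator emulates the one statistical property the method actually
exploits: **recurring reaction-center environments**. Each of eight
reaction classes (O-, N-, S-demethylation, phenol O-glucuronidation,
cyclization, ring opening, ring contraction, ring expansion) has a
template substrate decorated with inert substituents from a fixed
vocabulary (seed-shuffled), so the center environment repeats across
records while the periphery varies — the redundancy a real corpus shows
for common biotransformations. Products are computed by applying the
class pattern at its center, which makes every record self-consistent by
construction and gives exact ground-truth SOMs. One in five records per
class is held out; inert decoys (halobenzenes, alkanes, ethers) provide
atoms with substrate-only evidence. Aromatic hydroxylation is available
as a ninth class but is not generated by default: every aromatic CH is a
center there, which makes its ground truth nearly informationless for
ranking evaluation (the pattern itself remains in the library and in the
applicability machinery).

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: realistic class frequency imbalance,
multi-step metabolism, stereochemistry, charged substrates,
regioselectivity between competing centers of the same class, and the
sheer environment diversity of tens of thousands of literature reactions.
Parameter-recovery results on fixtures bound the implementation's
correctness, not the method's real-world accuracy.

## Evaluation protocol

Top-*k* accuracy is the fraction of molecules with a true SOM among the
*k* best-ranked sites, with symmetry-aware credit (an atom in the same
environment-equivalence class as a true SOM counts — without this,
symmetric atoms would split credit arbitrarily). Atom-level ROC AUC is
reported pooled over all atoms and as mean/median of per-molecule AUCs,
excluding molecules whose atoms are all one class. Metabolite
recall/precision/F1 are micro-averaged with canonical, stereo-stripped
SMILES identity, plus the pooled false-positive count. The analytic
random baseline for top-*k* is $1 - \binom{N-s}{k}/\binom{N}{k}$ per
molecule. The depth sweep re-runs prediction at exact-match depths 1–6;
at depth 6 many query atoms retrieve nothing (their score collapses to
0), which is the observable trade-off motivating the default of 3.

Problem sizes used by the shipped tests: the shared fixture set is 8
classes × 4 records; the parameter-recovery check runs 8 × 10 records
with a 20 % stratified holdout across ten generator seeds, which keeps
the full suite under a minute on one CPU while the holdout still contains
every class.

## Design decisions taken where the design was open

* **Occurrence-weighted counts.** `m` and `n` count atom occurrences
  (multiset), not distinct fingerprint keys — the hit-count semantics of
  the fingerprint-data-mining lineage this method belongs to.
* **Reaction identity for deduplication** is canonical reaction SMILES:
  each side's components canonicalized, sorted, dot-joined.
* **Multi-substrate records**: the largest reactant is "the substrate";
  cofactors stay on the pattern side only.
* **Anchored applicability.** Patterns are applied with the center map
  atom pinned to the query atom, not anywhere on the molecule; an
  un-anchored check could validate a hit using a different site,
  defeating the site-specific correction.
* **0-based atom indices in files, 1-based in R.** Files follow the
  toolkit convention; the R API follows R. The boundary is exactly the
  readers/writers.
* **Fingerprint-key equivalence classes** stand in for graph
  automorphism orbits (identical full-depth layered environments). For
  drug-like graphs this matches orbit structure in practice; pathological
  regular graphs could over-merge, which we accept for robustness and
  determinism.

## Known limitations

* Formal-charge handling is limited to what OpenBabel canonicalization
  round-trips; molecules are treated as neutral heavy-atom graphs and
  fixture chemistry is neutral.
* No stereochemistry: reaction identity and metabolite identity are
  2D-topological.
* Single transformation step only, matching the single-step curation
  rule; no metabolite trees.
* The SMARTS engine implements the subset metabolic patterns need, not
  the full language (no recursive SMARTS, no logical operators within an
  atom).
* Prediction quality on novel atom environments is structurally limited:
  an environment absent from the databases scores 0 even if reactive,
  which can promote weakly supported sites of the same molecule.
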