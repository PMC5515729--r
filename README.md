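# metsite

Site-of-metabolism (SOM) and metabolite prediction for drug-like
molecules, from reaction-derived atom-environment fingerprints.

## The problem

Knowing *where* a candidate drug will be metabolized — and *what* the
metabolites look like — is decisive early in discovery: metabolism drives
clearance, toxicity and drug–drug interactions, but the experiments are
slow and expensive. `metsite` is a data-driven predictor for both
questions at once. It is aimed at medicinal and computational chemists who
have (or can curate) a table of metabolic reactions and want ranked SOMs
plus concrete metabolite structures for new molecules.

## The method

A metabolic reaction corpus is distilled into two databases of **six-layer
topological atom fingerprints** (Molprint2D style): for each heavy atom,
layer *j* counts the atoms of each SYBYL/Tripos type at bond-graph
distance exactly *j* (33 base mol2 types, 10 extra metabolic elements, and
a padding type for layers beyond the molecule's radius). One database
holds every substrate atom; the other holds the annotated reaction-center
atoms, each tagged with the reaction-SMARTS pattern of its
biotransformation. SOMs of training reactions are derived by a
maximum-common-substructure diff (with the heteroatom convention for
dealkylations) or, for complex rewrites, from the atom-mapped changes in
the pattern itself.

For a query molecule, each atom's fingerprint *F* is matched against both
databases. Two fingerprints are similar when their first three layers
match exactly and the weighted score

d_total = Σ_{j=0..5} Δλ_{j+1} · d_j · d_Ham,j ≤ 3.5,

where d_j is the Soergel (count-Tanimoto complement) distance of layer
*j*, d_Ham,j the Hamming (absolute count difference) distance, and
Δλ = (2/λ_total)·[λ/e^{λ−1} + (λ_total−1)/(2λ)] the layer weight
(λ_total = 6). With *m* similar substrate occurrences and *n* similar
center occurrences, a correction step tries to actually **apply** every
candidate reaction-SMARTS pattern anchored at the query atom; center hits
whose patterns all fail to generate a sanitizable product are counted as
*x* dissimilar occurrences. Each site's score is then the occurrence
ratio

r = (n − x) / (m − x),   p = r / max(r),

binned as very unlikely [0, 0.15), unlikely [0.15, 0.33), likely
[0.33, 0.66), very likely [0.66, 1]. The applicable patterns at
top-ranked sites directly yield the ranked metabolite structures — the
same applicability check that corrects the ranking also produces the
products, which is what keeps false-positive metabolites low.

## Worked example

The package ships a deterministic synthetic reaction generator (eight
reaction classes built by substituent decoration, with ground-truth SOMs)
so the whole pipeline runs without licensed reaction databases:

```r
library(metsite)
man <- generate_dataset(seed = 7, n_per_class = 10)
fit <- som_model(man$records[man$records$split == "train", ], man$patterns)
fit
#> Site-of-metabolism model
#>   reactions: 64   substrate atoms: 679   reaction centers: 72
#>   fingerprint: 6 layers, alphabet tripos33+10+pad/1
#>   similarity: exact depth 3, threshold 3.5

res <- predict(fit, c(anisole_Br = "COc1ccc(Br)cc1"))
head(res$sites[order(res$sites$rank), ], 4)
#>  molecule_id atom_index element  m n x r p      category rank
#>   anisole_Br          2       O  8 8 0 1 1   very likely    1
#>   anisole_Br          1       C  8 0 0 0 0 very unlikely    2
#>   anisole_Br          3       C  8 0 0 0 0 very unlikely    3
#>   anisole_Br          4       C 32 0 0 0 0 very unlikely    4

res$metabolites
#>  product_smiles site_atom pattern_id support rank
#>   Oc1ccc(cc1)Br         2 O_demethyl       8    1
```

Reading the output: the ether oxygen (atom 2) matched 8 substrate-atom
occurrences (`m`), all 8 of which are known O-demethylation centers
(`n`), none corrected away (`x`), so its occurrence ratio is 1 and its
normalized probability `p` is 1.00 — "very likely". Every other atom has
database support but no center hits. The single predicted metabolite is
the O-demethylated phenol, generated by applying the `O_demethyl` pattern
at that oxygen, with support 8 (occurrences of the generating centers).

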