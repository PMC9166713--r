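---
title: "Mining uncharacterized microbial lectins: methods and design"
author: "lectiscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining uncharacterized microbial lectins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lectiscope)
```

## The problem

Lectins are non-enzymatic carbohydrate-binding proteins. In the human
microbiome they are mostly uncharacterized: the proteins that carry a
carbohydrate-binding module (CBM) but no catalytic machinery are rarely
named, rarely assayed, and yet highly prevalent across individuals and body
sites. `lectiscope` implements, as reusable and tested components, the
computational workflow for discovering such candidate lectins from
domain-annotated protein sets, quantifying their prevalence and overlap
across metagenomic body-site catalogs, and extracting a conserved
glycan-binding motif from glycan microarray screens.

The pipeline has four stages, each usable on its own:

1. **Mining** (`classifyRecords`): keep proteins with at least one CBM
   domain, no catalytic domain, no description keyword indicating transport,
   cell structure or adhesion, and (by default) no curated/reviewed
   annotation.
2. **Clustering** (`greedyCluster`): collapse candidates into "unique"
   sequences by greedy centroid clustering at 90% global-alignment identity.
3. **Prevalence** (`buildPresenceMatrix` and friends): score each unique
   lectin against per-sample gene catalogs into a Boolean incidence matrix;
   derive per-site richness, per-person means, cross-site overlap and
   sample-based rarefaction.
4. **Array analysis** (`bindingProfile`, `mineMotifs`): trim and aggregate
   replicate RFUs, normalize to the top binder, call binders, and mine the
   connected sub-glycan best separating bound from unbound structures.

## Filtering rules and their parameters

A record's fate is decided by four rules evaluated in a fixed order —
`no_cbm`, `catalytic`, `keyword`, `reviewed` — so a record failing several
rules always reports the same (first) reason. The defaults are:

* **CBM list** (`FilterConfig(cbmDomains=)`): which domain identifiers count
  as carbohydrate-binding. The packaged default is a small table including
  the CBM6-CBM35-CBM36-like module (IPR033803) and the
  Bacteroidetes-associated carbohydrate-binding often-N-terminal domain
  (IPR024361); a real analysis should pass the full curated list.
* **Catalytic domains** are recognized *only* through the domain table's
  `category` column. We deliberately do not infer catalysis from free text or
  from the identifier string: an explicit category input is reproducible,
  a natural-language heuristic is not.
* **Keywords**: a 30-entry list (`defaultExclusionKeywords()`) covering
  transport, cell-structure and adhesion functions. Matching is
  case-insensitive against whole tokens of the description (split at
  non-alphanumerics): `Fim` fires on the token `fim` but not inside
  `fimbrillin`; the long forms (`Fimbriae`, `Fimbrial`, `FimH`) are their own
  entries. Whether matching should be case-sensitive, and whether it applies
  beyond the description field, is genuinely underdetermined; both stay
  configuration (`caseSensitive`), with the token rule as the default.

## Identity, clustering and the two thresholds

Identity comes from Needleman–Wunsch global alignment (BLOSUM62, affine gap
opening 11, extension 1 — BLASTP-like defaults, configurable) with a single
unambiguous denominator: **matches over all alignment columns, terminal gaps
included**. Under this definition identity 1 holds exactly for identical
sequences, and truncated homologs are penalized by their missing residues.

Two thresholds with different boundary semantics coexist on purpose:

* clustering joins a centroid at identity **≥ 0.90** (inclusive), matching
  the "clustered at 90% identity" convention;
* catalog/reference matching requires identity **> 0.90** (strict), matching
  the "> 90% identity" match rule.

Both are parameters; the boundary semantics are fixed and tested.

`matchToSet` additionally applies a query-coverage filter (default 0.8 of
query length, counting query residues aligned opposite a reference residue).
With global alignment this filter is almost always satisfied — identity
already penalizes length mismatch — and it mainly guards against short
reference fragments; it is kept explicit and logged because local-alignment
backends would need it.

Clustering is greedy and centroid-based: sequences sorted by (length
descending, accession ascending); the first founds a cluster; each next
sequence joins the best-identity centroid at or above threshold (ties to the
earliest-created centroid) or founds a new one. Input order, tie-breaks and
the alignment backend are fully specified, so repeated runs are
bit-identical. We do not reproduce heuristic k-mer prefilters of production
clustering tools; at package scale exact alignment to every centroid is
affordable and easier to reason about.

## Presence, prevalence and rarefaction

`buildPresenceMatrix` evaluates `matchToSet` for every (lectin, sample)
pair; a cell is `TRUE` if any gene of that sample matches. All downstream
statistics depend only on this Boolean matrix and the sample-to-site map.
Each sample is treated as one person; collapsing repeat visits per subject
is out of scope.

Rarefaction is **sample-based (incidence)**: for a site with $N$ samples and
lectin incidence counts $N_i$,
$$S(n) = \sum_{i} \left(1 - \frac{\binom{N-N_i}{n}}{\binom{N}{n}}\right),$$
the expected number of distinct lectins seen in a random $n$-sample subset.
We evaluate it analytically in log space (`lchoose`), with
$\binom{N-N_i}{n} = 0$ whenever $n > N - N_i$, rather than by resampling;
an optional seeded resampling mode supplies standard deviations. The suite
verifies $S(n)$ against exhaustive enumeration of all subsets for small $N$
and against `vegan::specaccum(method = "exact")`.

`topPrevalent` resolves the ambiguity of "top 10%" at small richness by
`ceiling(fraction × richness)` with ties broken by accession. Cross-site
overlap reports the fraction of lectins present in ≥ 2 sites, per-site
exclusive fractions, a pairwise table, and exact per-region counts for up to
6 sites.

## Glycan structures, arrays and motifs

Glycans are rooted trees: the reducing-end residue is the root, edges carry
the anomeric configuration (`a`/`b`/`?`) and both linkage carbons. The
condensed-notation parser reads strings like
`Galb1-3GlcNAcb1-2Mana1-3Man` and `Mana1-3(Mana1-6)Manb1-4GlcNAc`
(branches in parentheses attach to the residue on their right; a trailing
`-Sp<n>` spacer is stripped). Sulfation/phosphorylation decorations (e.g.
`Gal6S`) are kept on the node and must match exactly; unknown tokens are a
parse error, never silently dropped. The canonical serialization orders the
children of every node by (parent carbon, residue code, serialization), so
round-trips are identities and ties break deterministically.

Array processing follows the screen's convention: per glycan, drop exactly
one maximum and one minimum replicate (not all tied extremes — six
replicates become a mean of four) and average the rest. Negative
(background-subtracted) RFUs participate in trimming and are clipped to zero
only for normalization, which divides by the maximum so the top binder
scores exactly 1. The array itself defines no binder criterion, so the
binder call is an explicit parameter: normalized score ≥ 0.1 by default, a
conservative fraction-of-top rule on the same scale as the normalization.

Motif mining enumerates every connected sub-glycan of the binders up to
`maxSize` residues and scores each candidate by
`binder_coverage − nonbinder_frequency` — a transparent contrast statistic
chosen so an exhaustive oracle can check every number; we make no attempt to
reproduce any specific motif-discovery program's internal scoring.
Containment (`containsMotif`) is **unanchored** (the motif may sit anywhere
in the tree) and exact on residue codes, decorations, anomeric
configurations and both linkage carbons, with one permissive rule: an
unknown (`?`) anomeric on the data side matches anything, since array
structure annotations are often underspecified. Ranking is by (score desc,
size desc, canonical text asc) and only maximal motifs survive per score
tier: a motif is dropped when a strictly larger motif containing it scores
at least as well, which collapses the nested sub-chains of a conserved
determinant onto the determinant itself.

## The synthetic-data generators

Real inputs for this workflow are versioned database downloads; the package
instead ships seeded generators whose outputs carry full ground truth, and
the test suite treats those labels as the acceptance surface.

* `genProteinUniverse`: true lectins (CBM present, clean description,
  unreviewed) plus decoys violating **exactly one** rule each, apportioned
  across the four violation classes by largest remainder. Sequences are
  i.i.d. uniform over the 20-residue alphabet with domains planted inside
  the sequence bounds.
* `genSequenceFamilies`: a random ancestor per family; every member carries
  **exactly** `round(divergence × length)` substitutions at random positions
  (no indels). We fix the substitution count rather than drawing it per
  site: with i.i.d. per-site mutation at 5% the member-to-member identity
  distribution is centred exactly on the 0.90 clustering threshold, so
  family recovery would be a coin flip; with the fixed count any two members
  differ at no more than twice that count of positions, worst-case pairwise
  identity is exactly 0.90, and recovery at the inclusive threshold is
  deterministic. Between-family identity stays near the random-sequence
  baseline.
* `genCatalogs`: each site sample contains lectin $i$ with the site's
  inclusion probability (exact copies by default; optionally mutated at a
  stated rate) plus random background genes. Planted presence is the
  ground-truth matrix.
* `genGlycanArray`: binders are the planted motif grafted into random tree
  context (1–3 extra residues at random positions and linkages, so binders
  share no systematic extension beyond the motif); nonbinders are random
  trees rejected and regenerated until they do not contain the motif.
  Replicates are class mean + Gaussian noise, with tenfold outliers injected
  at a stated probability to exercise trimming.

Every generator seeds its own RNG stream and restores the caller's state, so
outputs are byte-identical given (config, seed) and adding draws never
perturbs earlier ones. What these generators do **not** emulate: realistic
protein evolution (no indels by default, no rate heterogeneity), real domain
length distributions, phylogenetic correlation between samples, glycan
biosynthesis constraints, or array-wide spatial effects. Green tests
therefore demonstrate the machinery is exact on data matching its stated
assumptions, not that real databases would yield any particular counts —
headline numbers from real analyses depend on database versions and are
explicitly out of scope.

## Numerical choices and degenerate inputs

* Rarefaction uses `lchoose` differences exponentiated per term; terms with
  $n > N - N_i$ are exactly 1. $S(1)$ equals mean per-sample richness and
  $S(N)$ the observed richness to machine precision.
* Aggregation requires ≥ 3 replicates (trimming would otherwise leave
  nothing); normalization errors when every aggregated value is ≤ 0 (no
  positive binder to anchor the scale); an empty binder set is an error for
  motif mining, while an empty nonbinder set simply gives frequency 0.
* Empty gene catalogs yield all-false columns, not errors; duplicate sample
  ids are errors.
* Architecture ordering breaks ties by (start, end, domain id); equality
  ignores inter-domain spacing. Proteins with multiple CBMs contribute only
  CBM × non-CBM pairs to the co-occurrence matrix, never CBM–CBM pairs.
* All report JSON is written with fixed key order and no timestamps, so the
  end-to-end pipeline is reproducible to the byte.

## Problem sizes used by the test suite

The suite's oracle comparisons run at sizes where exhaustive enumeration is
exact and fast: rarefaction against all subsets for up to 8 samples × 12
lectins (200 random matrices), clustering against a step-by-step replay on
100 instances of ≤ 10 sequences × ≤ 30 residues plus 10 seeded family
datasets (5 families × 6 members), motif mining against full subtree
enumeration on libraries of 12 glycans of ≤ 6 residues, filtering on 5
seeded universes of 200 records, and trimming on 1000 random
replicate vectors. These sizes are the package's own choice of
exhaustively-checkable instances; the algorithms themselves have no
small-size assumptions.

## Known limitations

* Exact all-vs-centroid alignment scales quadratically in the worst case;
  at database scale a k-mer prefilter would be needed (out of scope).
* The binder threshold and motif score are deliberately simple substitutes
  for unspecified upstream conventions; both are exposed as parameters and
  reported alongside results.
* Coverage filtering is nearly inert under global alignment (see above);
  a local-alignment backend would make it load-bearing.
* One sample is one person throughout; visit structure is not modelled.
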