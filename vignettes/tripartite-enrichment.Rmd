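---
title: "Tri-partite enrichment for miRNA clusters: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tri-partite enrichment for miRNA clusters: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtrigo)
```

## The statistical model

A miRNA cluster analysis involves three linked universes: the miRNAs
(every miRNA with at least one predicted target link), the links
themselves, and the genes (every gene with at least one link).  For a
cluster $C$ and a GO term $t$ with annotated gene set $A_t$, each
universe is partitioned into a 2×2 contingency quartet $(i, j, k, l)$ —
inside/outside the cluster-derived set crossed with connected/not
connected to $t$:

* **ρ (gene-centric)** partitions the gene universe by membership in
  the *target gene cluster* $T$ (genes targeted by ≥ 1 member) and by
  annotation to $t$.
* **τ (link-centric)** partitions the links by whether they leave a
  cluster member and whether they land on an annotated gene.
* **μ (miRNA-centric)** partitions the miRNAs by cluster membership and
  by whether they target at least one annotated gene.

Each quartet is scored by the exact upper tail of the hypergeometric
distribution, $p = P(X \ge i)$ with population $i+j+k+l$, success count
$i+k$ and sample size $i+j$, computed through `stats::phyper`'s
survival form (log-space internally; naive factorial products would
overflow at genome scale).  The three tests are *different statistics on
the same null randomization*, not three corrections of one statistic: ρ
is invariant to any rewiring of links that preserves $T$, τ counts
wiring density, μ counts member multiplicity.  The constructed fixtures
in `make_discriminability_fixtures()` realize exactly these contrasts
(equal ρ quartets with 8 vs 22 links; equal link counts carried by 6 vs
3 distinct members) and the test suite asserts them.

### Assumptions

The hypergeometric null treats the cluster-derived draw as a simple
random sample from its universe.  For τ this is the strongest
assumption: links from one miRNA are not independent draws, so τ
p-values are best read comparatively (ranks) rather than as calibrated
tail probabilities.  μ's draw — which miRNAs belong to the cluster — is
the cleanest match to the sampling model, which is also why the
synthetic null calibration below is run on μ.

## Combining and ranking

With two or three measures requested, Fisher's combined probability is
computed per term: $S = -2\sum \ln p$ referred to $\chi^2$ with $2k$
degrees of freedom.  A `method = "literal"` variant referring
$\sum -\ln p$ to $\chi^2(k)$ is kept for comparison with descriptions
that treat each $-\ln p$ as a one-degree $\chi^2$ variable; the
standard form is the default (it is what `fisherSum`-style
implementations compute, and it alone satisfies `combine(1, 1) = 1`
exactly at the boundary).  Zero p-values are clamped to the smallest
positive double with a warning.

Because the three statistics have very different discreteness (μ lives
on at most $|C|+1$ support points), cross-measure comparison uses rank
normalization: within a GO category, ascending competition ranks (ties
share the minimum rank of their block).  The top-$n$ set $S_\theta(n)$
contains every term with rank ≤ n — boundary ties are included, so the
set can exceed $n$ but is never silently smaller.  Multi-measure sets
use set intersection by default (a consensus reading; union is
available), while the Fisher-combined p-value columns carry their own
ranks so that all seven measure combinations can be evaluated uniformly
by `compare_measures()`.

No multiple-testing correction is applied anywhere in the ranking path;
an optional Benjamini–Hochberg column (`bh_adjust = TRUE`) is provided
for diagnostics only.

## Term-set evaluation

Specificity is the mean Information Content,
$IC(t) = -\log(freq(t)/freq(root))$.  The frequency of a term counts
its direct annotations plus those of *all* descendants ("children"
transitively).  Two counting conventions are offered:

* `paper_sum` (default): the literal sum of direct-annotation counts
  over the term and its descendant terms.  A gene annotated to two
  descendants counts twice.  This convention requires *unpropagated*
  annotations, otherwise every descendant's genes would be re-counted
  at each level.
* `unique_genes`: the size of the gene union — the standard IC corpus
  convention, free of double counting.

Both give $IC(root) = 0$ and IC non-decreasing from ancestor to
descendant.  The log base (natural by default, 2 and 10 available)
rescales all ICs equally, so any comparison between term sets is
base-invariant.

Functional homogeneity is the semantic similarity density: the mean
Resnik similarity over all unordered distinct pairs in the set.  Resnik
similarity is the IC of the most informative common ancestor — in a DAG
"lowest common ancestor" is ambiguous, and the highest-IC common
ancestor is the standard resolution ("lowest" = most specific).
Self-pairs are excluded; a singleton set therefore has *undefined*
density (`NA`) rather than trivially reporting its own IC.  Similarity
is only defined within a GO category; cross-category requests error.

## Annotation handling

GAF rows with ND (No biological Data) or NR (Not Recorded) evidence are
excluded by default, NOT-qualified rows are dropped, and duplicate
(gene, term) pairs collapse to one logical association.  Gene identity
defaults to the GAF symbol column (column 3) because target-pair tables
use symbols; column 2 is available via `id_column = "db_object_id"`.

Whether the annotated gene set $A_t$ used in the enrichment counts
should obey the true-path rule is genuinely open; the package defaults
to propagated annotations (`propagate = TRUE`) — a gene annotated to a
term counts for every ancestor within the category, which matches how
GO annotations are defined semantically — and exposes the flag for the
direct-annotation reading.  Only `is_a` edges define ancestry by
default; `part_of` can be included when parsing.

## The synthetic scenario generator

`generate_scenario()` exists so every stage — parsers, propagation,
quartets, p-values, ranking, evaluation — can be exercised end-to-end
without external databases.  One integer seed drives a single generator
pass and the caller's RNG state is untouched; identical seeds produce
byte-identical written scenarios.

What it emulates, and the defaults chosen for it:

* **A rooted annotation DAG** (150 terms, one category), grown top-down
  with Poisson branching (mean 5) plus sparse extra `is_a` edges (20% of
  terms get a second, strictly shallower parent), giving multiple
  inheritance without cycles.
* **Annotations**: each of 2000 genes draws on average 2 direct terms
  uniformly from the non-root terms.  The 10:1 gene:miRNA ratio keeps
  the proportions of genome-scale prediction compendia (tens of
  thousands of genes, hundreds of miRNAs) at desk scale.
* **Heavy-tailed targeting**: miRNA out-degrees follow a truncated
  discrete power law $P(d) \propto d^{-2}$ on $[3, n_{genes}]$ — most
  miRNAs target a handful of genes, a few target hundreds, matching the
  "very uneven" link distributions that motivate the link- and
  miRNA-centric measures.
* **A planted signal**: one leaf term whose direct annotations are
  topped up to 4% of the gene universe; each link of a cluster member
  falls into that pool with probability `planted_term_fraction`
  (default 0.9).  At fraction 0 the cluster's links are drawn exactly
  like the background's, so cluster membership is exchangeable with
  non-membership and the μ null is *exactly* hypergeometric — the
  generator doubles as a null-calibration harness.

The defaults were fixed by a design-time calibration of that null:
given a term's miRNA hit count $K$, the attained size of the level-0.05
μ test is computable exactly, so the expected type-I proportion over
terms is an analytic property of the generator, not a simulation
outcome.  The frozen defaults place it near 0.022; with a 6-member
cluster the test statistic has at most seven support points, so the
attainable ceiling of that proportion is roughly 0.03 under any
realistic configuration — discreteness, not implementation, is the
binding constraint.  The same discreteness means the planted term's
null p-value distribution cannot be close to uniform in
Kolmogorov–Smirnov distance (seven support points bound the distance
from below at roughly 0.2); the suite therefore asserts the meaningful
discrete property — validity, $P(p \le x) \le x$ up to sampling noise —
rather than proximity to the continuous uniform.

What the generator does **not** emulate: realistic GO topology (depth
15+, tens of thousands of terms, part_of/regulates edges), skewed
annotation popularity, correlated targeting between paralogous miRNAs,
miRBase identifier drift, or the false-positive structure of any actual
prediction algorithm.  Passing tests on synthetic scenarios demonstrate
the statistical machinery, not biological performance on real
compendia.

## Problem sizes used in the test suite

Module tests run on toy corpora (≤ 20-term DAGs, ≤ 60 genes) checked
against brute-force oracles: exhaustive ancestor walks, exact
enumeration of hypergeometric tails with binomial coefficients (exact
in double arithmetic for universes ≤ 40, where every intermediate
integer is below 2^53), and double-loop pairwise similarity means.  The
calibration and power checks use the default 200-miRNA scenario scale
with 200 null and 100 alternative replicates; `compare_measures`
checks use 40–60-miRNA scenarios.  These sizes were chosen so the whole
suite exercises every contract in about a minute on one CPU.

## Numerical choices

* Upper-tail p-values via `phyper(i - 1, ..., lower.tail = FALSE)`;
  never via factorials.
* `i = 0` gives exactly 1; quartets are validated non-negative with a
  positive universe.
* Competition ("min") ranking for ties; deterministic and
  inclusion-monotone in $n$.
* Terms with zero annotated genes in the gene universe are excluded
  from enrichment records (rather than reported at p = 1) to keep rank
  denominators meaningful; terms with zero corpus frequency have
  undefined IC (`NA`, with a warning) rather than infinite.
* Written result files fix column order and print probabilities at 6
  significant digits, so identical fits produce byte-identical files.

## Known limitations

* τ p-values inherit the independence caveat above.
* miRNA identifiers are compared case-insensitively after trimming, but
  no miRBase version harmonization is attempted; identifiers are opaque
  strings.
* Only Resnik similarity is implemented (no Lin/Jiang–Conrath), and no
  GO-slim mapping.
* The cluster under test must have at least one target gene in the
  network; target-less clusters are skipped with a logged message, and
  downstream evaluation requires the full seven rank columns (fit with
  all three measures and `combine = TRUE`).
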