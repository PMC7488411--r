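---
title: "Pattern-specific detection of Boolean relationships in microbial communities"
author: "BoolPatterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-specific detection of Boolean relationships}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolPatterns)
```

## The problem

Members of a microbial community are often involved in several relationships
at once, so the joint distribution of two organisms' abundances need not form
a visually uninterrupted cloud that correlation, covariation or
mutual-information methods can pick up. A dependent organism may appear only
when its provider is present (a *one-way relation*), two organisms may never
be observed together (*co-exclusion*), or they may appear only together
(*co-presence*). In three and more dimensions, one organism can switch the
relationship between two others — for instance, two genera co-present
whenever a third is present and mutually exclusive when it is absent.

BoolPatterns scores each such Boolean pattern directly instead of through a
generic dependence measure.

## The score

Write $X_1, \dots, X_k$ for the abundance profiles of $k$ organisms over $n$
samples and $\varepsilon_1, \dots, \varepsilon_k$ for organism-specific
presence thresholds (organism $i$ is *present* in a sample when
$X_i > \varepsilon_i$; the strict inequality makes zeros absent at
$\varepsilon = 0$). Binarizing at a threshold assignment partitions the
samples over $2^k$ presence/absence cells with occupancy fractions
$p_{b_1 \dots b_k}$. Every pattern in the catalog is a pair of cell sets:

* the *included* cells, whose fractions sum to the score, and
* the *constrained* cells, each of which must hold more than a fraction
  $m$ of the samples.

For example
$$S_{\text{co-presence}} = \max_{\varepsilon_1, \varepsilon_2}\,(p_{00} + p_{11}),
\qquad p_{00} > m,\; p_{11} > m,$$
$$S_{\text{co-exclusion}} = \max_{\varepsilon_1, \varepsilon_2}\,(p_{00} + p_{10} + p_{01}),
\qquad p_{10} > m,\; p_{01} > m.$$

The all-absent cell is included in every pattern: mutual absence contradicts
none of them, and demanding $p_{0\cdots0} > m$ for co-presence
distinguishes a genuine co-presence from two organisms that are simply
always there. The population threshold $m$ is what prevents the degenerate
optimum in which raising $\varepsilon$ pushes every observation into the
all-absent cell and scores a perfect 1.

`patternCatalog()` carries the interpretable cell sets for $k = 2$ (four
patterns), $k = 3$ (five cell sets) and $k = 4$ (two): co-presence,
co-exclusion and the two one-way orientations in 2D; two 3D co-exclusion
types, 3D co-presence, "pattern A" (two organisms co-present exactly when a
third is present — identical cells to the 3D one-way relation, so one
catalog entry carries both readings), and all-together-or-alone in 3D; 4D
co-presence and the 4D one-way relation. Bit 1 of a cell name always refers
to organism 1, and for directional patterns organism 1 is the provider.

## Exact threshold maximization

Because presence is the strict comparison $X_i > \varepsilon_i$, only the
observed values of a profile produce distinct binarizations, so the
continuous maximum over thresholds equals the maximum over the finite grid
of sorted unique values (`candidateThresholds()`). `bestScore()` enumerates
the full Cartesian product of candidate thresholds with an incremental
prefix sum, costing one `tabulate()` per assignment; `scanPatterns()` does
this for every $k$-combination of organisms. This is deliberately the naive
exact algorithm — at the scale this package targets (tens to a few hundred
organisms after the prevalence filter, 2D and selected 3D scans) it runs in
seconds, and every optimization is required by the test suite to agree
exactly with brute-force per-sample counting.

Numerical choices:

* Ties between threshold assignments are broken toward the
  lexicographically smallest $\varepsilon$ vector, i.e. the most inclusive
  presence calls; the choice is arbitrary but deterministic.
* A new assignment replaces the incumbent only when it improves the score
  by more than $10^{-12}$. True score differences are multiples of $1/n$,
  so this absorbs floating-point noise without ever masking a real gap.
* The $m$-constraint is strict ($p > m$). `scoreFromCounts()` accepts a
  `tol` argument for fractions known only to finite precision (published
  tables print two decimals, so a reported 0.10 may stand for any value in
  $[0.095, 0.105)$; `tol = 0.005`, half the last printed digit, is the
  appropriate slack there). Internally computed counts always use
  `tol = 0`.
* Directional patterns are evaluated once per coset of the pattern's
  role-permutation symmetry group: a fully symmetric pattern once per
  organism set, pattern A three times (each organism conditioning), the 2D
  one-way twice. The mirrored one-way spec is folded into this orientation
  enumeration so no mirror duplicates are reported.

## Why not mutual information

`misScore()` implements the baseline: the mutual information
$H_1 + H_2 - H_{12}$ of the binarized pair, maximized over the same
candidate-threshold grid, with natural-log entropies. Its ceiling depends
on the pattern type — $\ln 2 \approx 0.693$ for a balanced co-presence or
co-exclusion but only $2H(1/3) - \ln 3 \approx 0.174$ for an ideal one-way
relation — and occupancy disbalance between the all-absent and all-present
cells lowers it further even when the pattern itself is intact. The test
suite reproduces both facts; they are the motivation for scoring patterns
by occupancy fractions instead.

## Statistical gating by shuffling

An arbitrary choice of $m$ and of the minimal reported score $S_{\min}$
controls how many patterns appear by chance. `shuffleProfiles()` permutes
each organism's profile independently across samples — preserving each
organism's abundance distribution (rare organisms stay rare, dominant stay
dominant) while destroying all between-organism structure — and
renormalizes each sample of a relative table; whole-matrix shuffling is
available as an alternative null. `feasibilityGrid()` counts patterns in
the shuffled data for every $(m, S_{\min})$ cell of a grid (default
$m \in \{0.05, 0.075, \dots, 0.35\}$, $S_{\min} \in \{0.90, \dots, 0.99,
1\}$) and marks as *feasible* the cells with zero shuffled patterns.
`significantPatterns()` then scans the real data only inside the feasible
region, so by construction the identical scan of the shuffled data reports
nothing — zero type-1 error against that null, with no distributional
assumptions. One shuffle is the default; more shuffles (counts summed) can
only shrink the feasible region. Each reported hit is annotated with the
least stringent feasible cell it passes, smallest $m$ first, then smallest
$S_{\min}$.

Shuffled pattern counts are non-increasing along both grid axes (a stricter
gate can only remove patterns), which the suite asserts, and which makes
the feasible region an upper-right block of the grid in practice.

## Preprocessing

The ingestion pipeline mirrors standard relative-abundance practice:
samples outside a read-depth window (defaults 2000–50000 reads, strict on
both sides, so totals exactly at a bound are kept) are dropped before
normalization; each sample is normalized to proportions; lineages are
merged at a chosen rank (labels keep the lowest assigned rank in the
bracketed convention `"[G] Rothia"`, `"[F] Lachnospiraceae"`); organisms
with nonzero abundance in fewer than 5% of samples are removed ("fewer
than" is strict, so an organism at exactly 5% prevalence stays). Presence
for the prevalence filter means abundance $> 0$ — the per-pair
$\varepsilon$ optimization happens later and must not be anticipated here.

## The synthetic generator

`generatePatternTable()` exists so that every claim above is testable
without any external download. For each planted pattern it spreads samples
round-robin over the included cells (balanced occupancy), draws "present"
abundances uniformly above the organism's generating threshold and sets
"absent" values to exact zeros (optionally to sub-threshold positives,
which forces the scan to recover a nonzero $\varepsilon$). A fraction $d$
of samples is moved to non-included cells, taken evenly from the included
cells so no constrained cell is starved; the recoverable score is then
exactly $1 - \mathrm{round}(dn)/n$. Discordant samples take extreme values
— absent exactly 0, present above every concordant draw — so no threshold
assignment can reclassify a discordant sample into the pattern without
first emptying a constrained cell. Noise organisms are independent sparse
profiles with prevalence drawn in $[0.3, 0.7]$ and uniform positive
abundances, a deliberately featureless null rather than a realistic
compositional community model (no log-normal structure, no
compositionality coupling, no sequencing noise). Passing tests therefore
demonstrate correctness of the machinery on data whose generating truth is
known, not performance on real communities.

One caution the generator makes visible: scores of patterns with different
included-cell counts are not comparable after each is re-maximized over
its own thresholds. A pattern whose included cells strictly contain
another's (one-way contains co-presence) mechanically scores at least as
well on the smaller pattern's data, and with any planted discordance it
scores strictly better. Competing interpretations of one tuple should be
compared on a single binarization — the hit's own partition — which is how
the suite phrases its planted-recovery checks. This incomparability is
precisely why the method is pattern-specific rather than winner-takes-all.

## Problem sizes and determinism

The shipped tests run the full pipeline at desk scale: tables of 5–12
organisms over 20–50 samples, 200 random instances for the
oracle-equivalence property, 20 seeds for the type-1-control property, and
reduced $4 \times 3$ grids where the full $13 \times 11$ grid adds nothing
to the property being checked — sizes chosen so the whole suite exercises
every code path in about a minute and a half. All randomness flows through
explicit integer seeds (`shuffleProfiles()`, `feasibilityGrid()`,
`generatePatternTable()`, and the `--seed` flag of the command-line
front end); identical inputs and seeds give byte-identical outputs, and the
RNG state of the calling session is never disturbed.

## Networks

`buildNetwork()` renders hits in the field's graph convention: OTU nodes
(attributes: label, phylum parsed from the lineage, mean relative
abundance) with one typed edge per 2D hit, directed provider → dependent
for one-way relations. Patterns of three and more organisms do not reduce
to edges; they become *pattern nodes* carrying the pattern type and score,
linked to their member organisms — a multi-layer graph with two node kinds.
Relationship types are stored as attributes (`pattern_type`, `direction`),
never as colors; GraphML and edge-list TSV are the on-disk formats, and the
GraphML round-trips through `readNetwork()` with all attributes intact.
Tables from different environments should not be pooled into one scan —
composition differences between datasets manufacture spurious co-exclusion
— so networks are built per dataset and compared afterwards.

## Known limitations

* The exhaustive threshold enumeration is exponential in $k$; the catalog
  stops at $k = 4$, and genome-scale 3D/4D scans of hundreds of organisms
  are outside this implementation's scope.
* The zero-pattern gate is conservative by design: it reports nothing
  rather than something when even one shuffled pattern survives everywhere
  on the grid.
* With a single shuffle the feasible region is itself a random object;
  `nShuffles` trades runtime for stability of the gate.
* Printed two-decimal proportions can sit exactly on the strict $m$
  constraint; use `tol` consciously when scoring published tables.
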