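---
title: "Appraising marker panels with variety discrimination power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Appraising marker panels with variety discrimination power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdpower)
```

## The model

A marker panel for variety discrimination is good exactly insofar as it
keeps the given varieties apart. `vdpower` therefore scores a loci
combination through a three-step procedure applied to the samples
themselves, not to per-locus summary statistics:

1. **Pairwise difference.** For samples $i$ and $j$, only loci called in
   both (the overlap) are compared; the difference is either the count of
   differing loci or that count as a fraction of the overlap. A locus
   differs when the unordered diploid allele pairs are unequal — there is
   no partial credit for sharing one allele, because the downstream
   classification is binary (same variety / different variety) and a
   genotype either matches or it does not.
2. **Variety threshold.** A `threshold_rule(metric, M)` declares the pair
   "different varieties" when the difference reaches $M$. The unit of $M$
   has to match the metric: a locus count ($M \ge 1$, integer) or a
   fraction of the overlap ($0 < M \le 1$). `threshold_rule("count", 1)`
   is the *perfect match* rule — any single differing locus separates —
   and is the default everywhere because it is the setting under which
   all four statistics are simultaneously valid and comparable. Raising
   $M$ is a species-specific calibration choice (varieties within a crop
   may legitimately differ at a few loci) and only affects the
   comparison-based and ratio-based statistics.
3. **Repeated groups.** Same-variety pairs are merged transitively (the
   *discrimination chain*: A~B and B~C imply A~C), so groups are the
   connected components of the same-variety relation, computed by
   union-find. Under perfect match on complete data this coincides with
   grouping by exact genotype-vector identity; under partial match it is
   a genuine modelling choice — the chain can merge samples whose direct
   difference exceeds $M$. We use the chain for every threshold because
   it is the only rule under which "number of groups" is well defined for
   threshold sweeps; no alternative linkage is implemented.

With $m$ samples in $t$ groups — $T_i$ groups of size $R_i$ per category
$i$, $D$ singletons — the statistics are

$$\mathrm{P\!-\!VDP} = 1 - \frac{\sum_i \binom{R_i}{2} T_i}{\binom{m}{2}},
\qquad
\mathrm{C\!-\!VDP} = \frac{\sum_{i \ne j} d_{ij}}{m(m-1)},
\qquad
\mathrm{R\!-\!VDP} = \frac{t}{m},$$

and the classical total discrimination power
$TDP = 1 - \prod_j (1 - DP_j)$ with $DP_j = 1 - \sum_k g_{jk}^2$ over the
genotype-class frequencies $g_{jk}$ at locus $j$. $DP$ deliberately uses
*genotype-class* frequencies (unordered diploid pairs as classes), not
allele frequencies: the index is the probability that two random
individuals carry different marker *genotypes*, and this form also
reproduces the benchmark's terminal value (below).

### Validity conditions

P-VDP presupposes that grouped samples are mutually identical and that
groups are exact, so it refuses partitions built under a partial-match
rule or from data with missing calls (`vdp()` records a note and returns
`NA` instead of failing the whole appraisal). C-VDP and R-VDP remain
defined there; with missing data both can only *under*-estimate, since
masking a locus can hide a real difference but never invent one (a
type-II error, verified as a property test). A pair of samples with no
overlapping called locus has no defined difference at all; the default
policy is an error naming the pairs, with `undefined = "same"` or
`"different"` as explicit overrides. We default to the error because any
silent choice biases the indices in an unreported direction.

Two algebraic facts anchor the implementation and are enforced as tests:
the chain form $1 - 2\sum_i \binom{R_i}{2} T_i / (m(m-1))$ of C-VDP is
identical to P-VDP on any partition, and under perfect match on complete
data the traversal form of C-VDP agrees with both (to within one
floating-point ulp; the equality is asserted at $10^{-12}$).

## The benchmark generator

`table1_specs()` hard-codes the four benchmark arrays of group
structures: 21 populations each, always 206 samples over 10 SNP loci
with four allelic variants, hence 10 unordered genotype classes per
locus. A population is $D$ singleton varieties plus $T$ repeated groups
of $R$ identical samples, $D + RT = 206$. Array 1 grows one group's size
$R$ (convergence toward a single variety); arrays 2–4 grow the group
count $T$ at fixed $R = 2, 5, 10$. `make_population()` realises a
structure with concrete genotypes in two regimes:

- `all_loci`: every pair of varieties differs at *every* locus. Each
  variety then occupies its own genotype class at each locus, capping
  the variety count at 10; feasible only for the near-degenerate rows,
  but required for the terminal array-1 population, whose published TDP
  (0.09) pins the per-locus class counts at (205, 1):
  $DP_j = 1 - \left[(205/206)^2 + (1/206)^2\right]$ at all ten loci.
- `at_least_one`: varieties draw independent genotype vectors, kept
  unique, so distinct varieties differ at one or more loci. This is
  sufficient for every partition-based statistic, which sees only the
  group structure, and is the automatic fallback.

The generator emulates the *group structure* of real fingerprinting
populations, not their genetics: loci are independent, class frequencies
are uniform, and there is no linkage, population structure, allele
dropout bias or genotyping error. Tests passing on these populations
establish that the statistics compute what their formulas say on known
partitions — they do not establish robustness to the correlated loci and
structured missingness of real panels (the missing-data sweep injects
missingness completely at random).

`inject_missing()` masks an exact per-sample quota,
`round(rate * n_loci)` calls per sample at uniform positions — matching
a design where each sample loses a fixed proportion of its calls — with
a `global` mode (grid-level quota) as a sensitivity check.
`nested_subsets()` randomizes the locus order once and truncates it, so
smaller panels are always contained in larger ones and a statistic's
response to panel size is not confounded by which loci happen to be
drawn. All three take explicit seeds and restore the caller's RNG state.

## The harness

`sensitivity_curve()` applies one statistic to an ordered series of
populations; its OLS slope against the 1-based population index is the
discrimination-sensitivity summary (the abscissa is the population
number 1..21, which reproduces the published array slopes exactly).
`threshold_sweep()` grids C-VDP and R-VDP over $M$ and nested panel
sizes; P-VDP (pinned to perfect match) and TDP (threshold-free) are
refused by construction. `missing_sweep()` masks the panel at each rate,
evaluates the missing-tolerant statistics over nested subsets, and
reports each rate's Pearson correlation with the complete-data series,
paired by subset size with undefined cells dropped pairwise.

## Numerical choices

- Appraisal values are kept at full double precision; only comparisons
  against published decimals round, half away from zero
  (`round_half_up()`), since banker's rounding can differ at printed
  ties.
- Union-find uses path halving; group identity is order-invariant, and a
  property test shuffles sample order to confirm it.
- OLS slopes come from `stats::lm`; Pearson correlations from
  `stats::cor` on pairwise-complete series, returning `NA` when fewer
  than two paired points remain or a series is constant.
- Allele labels are opaque strings (SSR fragment sizes are not parsed
  numerically); calls are stored canonically as `"a/b"` with sorted
  labels so genotype equality is string equality.
- Ploidy is fixed at two; single-allele cells are a format error, not an
  imputation target.

## Problem sizes

The test suite and the acceptance script work at the benchmark's native
scale — 206-sample populations, $\binom{206}{2} = 21115$ pairs, 84
populations for the full partition-recovery check — plus randomised
property tests at 4–50 samples. A full four-array regeneration with all
indices takes a few seconds on one core.

## Known limitations

- Genetic-distance pairwise metrics (an allowed step-1 choice in
  principle) are not implemented; only locus counts and percentages are.
- Grouping under partial match is transitive-chain only; complete-linkage
  alternatives would give different R-VDP values at $M > 1$.
- The generator cannot reproduce populations whose varieties share
  per-locus genotype classes in specific patterns (the intermediate
  TDP trajectory of benchmark array 1 depends on such unpublished
  structure); its TDP values are exact only where the class structure is
  pinned, as in the terminal population.
- Combinatorial optimisation over locus subsets (using VDP as a fitness
  function) is out of scope; the package provides the index, not the
  search.
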