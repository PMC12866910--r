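---
title: "Estimating global ancestry from long haplotype matches: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating global ancestry from long haplotype matches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdancestry)
```

## The model

Let the reference panel `P` hold `M` phased binary haplotypes over `N`
biallelic sites, each haplotype labelled with one of `K` populations
`R = (r_1, ..., r_K)` with sizes `s_k` (counted in haplotypes). For a query
haplotype `Q_i`, a match `M(Q_i, P_j, s, e)` is a maximal run of allele
equality over the half-open site range `[s, e)`; the estimator consumes all
such matches with `e - s >= L`. Long exact matches act as proxies for
identity-by-descent: the longer the match, the more likely the two
haplotypes co-inherited the segment from a recent common ancestor, and the
reference haplotype's population label is evidence for that population's
contribution over the covered sites.

Scoring proceeds per query haplotype and chromosome. A `K x N` score matrix
`S` accumulates one unit in row `k = label(P_j)` at every site covered by
each match. Three normalizations follow:

1. **Column weighting.** Every covered column is divided by its sum, so each
   site distributes one unit of probability mass across populations — a
   *site-wise ancestry dosage*. Sites covered by several populations split
   their votes instead of being forced to a single best call; aggregating
   dosages rather than hard local-ancestry calls is the core accuracy
   advantage of the approach.
2. **Panel-size adjustment.** Row `k` is divided by `s_k`, so a population
   is not favoured merely because the panel over-represents it.
3. **Genome aggregation.** Scores are summed over all sites of all
   autosomal chromosome panels and divided by the total site count.

The two haplotype score vectors of an individual are summed and rescaled to
produce the ancestry proportion estimate `p~` with `sum(p~) = 1`. Summing
before rescaling weights each haplotype by its matched coverage — a
haplotype with twice the match evidence contributes twice the weight. The
per-site division and the final rescaling mean several constants cancel;
they are kept because the intermediate quantities (dosage per site,
genome-normalized score per haplotype) are meaningful exports in their own
right.

### Degenerate inputs and numerical choices

* Sites covered by no match contribute nothing; they remain in the total
  site-count denominator, which cancels in the final rescaling. The covered
  fraction is reported separately (`fit$covered_fraction`) as the method's
  confidence signal.
* An individual with no matches at all yields an `NA` estimate. A uniform
  vector would be indistinguishable from a genuinely even admixture call,
  so "no data" is propagated explicitly.
* All normalizations run in double precision; conservation tests assert
  unit sums to an absolute tolerance of 1e-9.
* Matches are *maximal* runs. Counting every sub-interval of a long match
  would multiply-count the same evidence, so only maximal spans enter the
  score matrix.
* Site coordinates are 0-based half-open throughout (`[s, e)`); population
  indices are 1-based, following R's factor-level convention.

## The match engine

The engine is a positional Burrows-Wheeler transform over the reference
panel: per-site sorted prefix orders with divergence values, built in
O(MN) and immutable afterwards. For an out-of-panel query the virtual
insertion position is swept through the sorted orders; haplotypes matching
the query's recent suffix are contiguous around it, and their match starts
follow from running maxima of the divergence values, so every maximal match
of length at least `L` is reported exactly once, when it terminates. The
query cost does not grow with the panel size except through the number of
reported matches. A brute-force oracle (`brute_force_long_matches()`,
equality-mask run extraction per reference row) validates the engine
exactly on hundreds of random instances in the test suite; the two
implementations share no code.

`L` is measured in sites (default 500), not centimorgans: the estimator is
deliberately map-free. On a panel with roughly one retained variant per
10 kb, 500 sites correspond to a few centimorgans — long enough that exact
matches are rarely coincidental, short enough to retain coverage.
Genotyping errors break exact matches rather than corrupting them, which is
why the method degrades gracefully: raising the per-allele error rate from
0 to 0.1% mostly shortens coverage (each flip splits a match) while leaving
the dosage composition, and hence the estimate, nearly unchanged.

## Panel refinement

Reference panels are usually proxy panels: their haplotypes are themselves
admixed. Refinement builds synthetic, ancestry-homogeneous haplotypes. The
chromosome is partitioned into `ceiling(N / W)` non-overlapping windows of
`W` sites (default 200; the last window may be shorter). For each window and
target population, the candidate set contains the population's haplotypes
whose *mean* dosage for that population over the window's sites reaches the
cutoff (default 0.7); one contributor is drawn uniformly and its window is
copied. When a window has no candidate, the contributor is drawn from all
haplotypes of the target population (not the whole panel — this preserves
the label semantics of the synthetic haplotype) and the window index is
recorded as a fallback. When no window falls back, the synthetic haplotype's
genome-wide target dosage is at least the cutoff up to the short-last-window
effect.

Two design points were genuinely open:

* *Per-window statistic.* "At least 60% contribution within the window" is
  read as the mean dosage over the window's sites reaching 0.6 — the mean is
  the only statistic that makes the windowed guarantee compose into the
  genome-wide one.
* *Dosage source.* The dosage panel is pluggable: simulator truth
  (`dosage_from_labels()`), the scoring module's own per-site dosage export,
  or any external per-site dosage table (`read_dosage()`), so posterior
  dosages from a dedicated local-ancestry tool can be substituted without
  code changes.

Windowed copying truncates match continuity at window boundaries: a query
match against a synthetic haplotype must cross boundaries where consecutive
windows happen to carry compatible segments. Coverage against a refined
panel is therefore sparser than against the original panel (observed ~0.67
vs ~0.77 on the two-way benchmark below); the accuracy gain from label
homogeneity outweighs the coverage loss by roughly a factor of two in RMSE
on ambiguous panels.

## The simulator: what it emulates, and what it does not

The generator stands in for forward/coalescent simulations of a recently
bottlenecked admixed population — the regime where IBD-based inference is
strongest — at desk scale. Its defaults are the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| founders per population | 5 haplotypes | a small founder pool concentrates co-ancestry, so long exact shared segments are abundant, emulating a recent bottleneck |
| sites `N` | 10 000 | one chromosome's worth of common variants after MAF filtering |
| differentiation (Balding-Nichols F) | 0.15 | continental-scale allele-frequency differentiation |
| ancestry switch probability per site | 0.002 | ~20 ancestry switches per 10k-site chromosome, matching ~20 generations of admixture on a chromosome of about one Morgan |
| admixture sampler (K-way) | Dirichlet(0.2 per component) | a strongly drifted admixed population: broad spread with many near-pure individuals. Calibrated once so that majority-labelled reference haplotypes average ≈0.83 own-ancestry dosage, placing the recovery benchmark in the regime the estimator is designed for; not revisited |
| genotyping error `g` | 0 (benchmarks use 0, 0.0005, 0.001) | spans the error rates at which exact-match methods must stay robust |
| split | 100 query / 400 reference individuals | reference-heavy split typical for supervised ancestry estimation |

Each admixed haplotype is a Markov mosaic: geometric segment lengths
(rate = switch probability), segment ancestry drawn from the individual's
proportion vector, segment alleles copied *intact* from a uniformly chosen
founder haplotype of that ancestry. Founder alleles are site-independent
Bernoulli draws from Balding-Nichols population frequencies
(`Beta(p(1-F)/F, (1-p)(1-F)/F)` around a shared ancestral frequency drawn
uniformly on (0.05, 0.95) — the panel is assumed MAF-filtered). Truth is
exact by construction: per-site ancestry labels are recorded, and each
individual's true proportion vector is their site-average. All randomness
flows from one seed through named substreams (founders, mosaics, errors,
split), so components are independently reproducible and a dataset is
byte-identical across runs.

What the generator does **not** reproduce — and hence what passing tests do
not show about real data:

* **No linkage disequilibrium beyond the ancestry mosaic.** Founder alleles
  are site-independent. The estimator only consumes exact matches, which the
  copying process creates directly, so this is sufficient for validating
  the pipeline — but accuracy numbers do not transfer to real panels with
  background LD.
* **Ancestry signal is carried by founder identity, not allele
  frequencies.** Exact segment copying makes founders individually
  recognisable even when population frequencies coincide, so accuracy is
  nearly flat in the differentiation parameter and the F = 0 case remains
  identifiable — unlike coalescent reality, where differentiation drives
  identifiability. The differentiation parameter still controls the
  frequency gap (tested), just not downstream accuracy.
* **No recombination map, no coalescent segment-length distribution, no
  multi-chromosome structure.** Segment lengths are geometric in site count.
* **Reference individuals are drawn from the same admixed population** and
  labelled by majority true ancestry (or by designed bias group for the
  two-way sets) — deliberately modelling the proxy-panel problem rather than
  clean source panels.

## Benchmarks computed by the test suite

The acceptance tests (`tests/testthat/test-acceptance.R`) compute, at fixed
seeds, with the generator defaults above:

* three-way recovery (N = 10 000, 5 founders/population, 400 reference /
  100 query, F = 0.15, L = 500, g = 0.0005): mean RMSE and mean KL against
  truth both below 0.10;
* two-way 55:45 ambiguous panel: refining the panel (cutoff 0.7, W = 200,
  400 synthetic haplotypes per population from truth dosage) strictly lowers
  mean query RMSE — measured 0.074 to 0.044 on the fixed-seed dataset;
* error robustness: moving g from 0 to 0.001 changes mean RMSE by well
  under 0.05 (measured change 0.003).

Problem sizes were chosen so the whole suite runs in well under a minute on
one CPU; the properties they check (oracle equivalence, conservation, exact
single-ancestry recovery) are size-independent.

## Known limitations

* Exact matching requires phased, error-modest data; unphased or heavily
  erroneous genotypes shrink coverage. Sites with any missing or unphased
  genotype are dropped, never imputed — imputation would fabricate matches.
* The method reports dosage-weighted proportions, not hard local-ancestry
  tracks; no confidence intervals are attached.
* `L` in sites ignores recombination-rate variation; regions of unusual
  marker density are implicitly weighted by their site count.
* Refinement assumes the labelled populations are meaningful targets; with
  badly mislabelled panels the windowed cutoff cannot recover the truth.
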