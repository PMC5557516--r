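---
title: "Merging taxonomic profiles across metagenome classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging taxonomic profiles across metagenome classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(taxmerge)
library(dplyr)
```

## The problem

Whole-metagenome classifiers disagree. Taxonomic profilers (which predict
organisms and relative abundances for a sample) and binning tools (which
classify each read individually) are built on different reference databases
and different algorithms, so each one sees a different slice of the same
community: their true positives are complementary, their false positives are
largely tool-specific, and their abundance estimates scatter around the
truth. taxmerge integrates the per-sample profiles of several such tools
into one profile that keeps corroborated identifications, filters the
tool-specific noise, and combines abundances robustly.

## The model

Everything operates per taxonomic rank, independently, over the seven
canonical ranks superkingdom through species.

**Normalization.** Tool abundances are first rescaled so every rank sums to
100%. This is required because some tools account for unclassified reads
and others do not, which makes raw outputs incomparable.

**Binning tools** are converted to profiles first. For a taxon $n$ with
directly assigned reads, the raw abundance is

$$a_n = \frac{\sum_j b_j}{\ell_n},$$

the summed assigned lengths $b_j$ of its reads divided by the total
reference length $\ell_n$ of that taxon in the tool's database — a coverage
proxy that removes the bias toward large genomes. Parent taxa receive the
cumulative sum of their descendants' values. Two choices here are ours:
reads assigned directly to internal taxa (an LCA-style genus assignment)
contribute through the same formula using the ancestor-closed database
length, which keeps the cumulative rule well defined; and per-reference
contributions are pooled into per-taxon totals, so the database profile only
needs one total length per taxon. Pooling differs from a per-reference sum
only by within-taxon reference-length skew, and the subsequent per-rank
normalization makes the merged result insensitive to the distinction.

**Scoring.** For each taxon at a rank, let $i$ be the number of tools that
reported it and $j$ the number of tool databases that contain it. The
co-occurrence score is

$$S_{ij} = \frac{(i+1)^2}{j+1}.$$

The square biases the score toward $i = j$: a taxon found every time it
could be found scores high even if only one database holds it (the
benefit-of-the-doubt case of a tool with a unique reference set), while a
taxon sitting in many databases but reported by few tools scores low. A
taxon reported by a tool whose own database profile lacks it still counts
toward $i$ but not $j$; this combination indicates a stale database profile
and is logged.

**Integration.** The merged abundance of a taxon is the harmonic mean of
the normalized abundances of its reporting tools. The harmonic mean damps
outliers: `integrate_abundance(c(1, 100))` is about 1.98, not 50.5, so one
tool over-reporting a taxon cannot drag the ensemble with it.

**Binning and filtering.** Scores at a rank are divided into `bins`
equal-width intervals over the observed score range (degenerate ranges put
everything in the top bin, which reduces filtering to the plain
percentile-on-abundance rule). Within each bin, entries are sorted by
descending integrated abundance and only the top fraction is kept. The
fraction is $x^e$ with $x = (b+1)/B$ the normalized bin position and the
exponent $e \in \{3, 2, 1, 1/2, 1/3\}$ for the modes very-precise, precise,
linear (default), sensitive and very-sensitive. The survivor count is
rounded up, so no non-empty bin is emptied outright. Separately, any taxon
whose integrated abundance falls below `cutoff` is removed regardless of
bin; the cutoff is applied before the percentile so that bin sizes reflect
what the percentile actually selects from. Survivors are re-normalized to
100% — without this the removed mass would leave ranks summing below 100 —
and sorted by descending abundance with taxid as the tie-break, so outputs
are byte-reproducible.

The power family for the mode functions is a design choice of this package:
it satisfies the constraints the method imposes (keep fractions monotone in
bin position, the whole top bin always kept, strictly more stringent
cutoffs for the precise modes, five named modes around a linear default)
with a single exponent parameter, and `mode_percentile()` isolates it so an
alternative family can be dropped in.

Ranks are filtered independently; the final profile is not forced to be
hierarchically consistent across ranks (a genus can survive while all its
species are cut). We prefer reporting each rank on its own evidence over
inventing mass for taxa no tool reported.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `bins` | 4 | score bins per rank; more bins = finer separation of corroboration levels |
| `mode` | `"linear"` | precision–sensitivity trade-off of the per-bin percentile |
| `cutoff` | 1e-4 | minimum integrated abundance in percent; set it to the lowest abundance you expect a real organism to have |
| `ranks` | all seven | ranks to process |

## A worked example

```{r example}
ens <- simulate_ensemble(ensemble_spec(seed = 1))
merged <- merge_profiles(ens$profiles, ens$dbprofiles, merge_config())
glance(merged)

evaluate_profile(merged$profile, ens$truth)

# how each single tool fared at species rank, for comparison
sapply(ens$profiles, function(p) {
  e <- evaluate_profile(p, ens$truth)
  e$sensitivity[e$rank == "species"]
})
```

`tidy(merged)` exposes the full pre-filter detail (i, j, score, bin,
per-tool abundances, survival), and `autoplot(merged)` draws the
score-versus-abundance landscape that the bin filter cuts through.

## What the synthetic ensemble emulates

`simulate_ensemble()` generates the regime the merge is designed for, with
no external data. Its defaults define the package's reference study
conditions: 50 species truly present with log-normal abundances
(meanlog 0, sdlog 1.5); 6 tools; each tool's database covers a true species
with probability 0.8; a covered species is reported with probability 0.7;
abundances are perturbed by multiplicative log-normal noise with CV 0.3;
and each tool adds 15 false species, drawn from its own disjoint pool of
off-truth leaves, at abundances uniform below the 10th percentile of the
true abundances. These values mirror the behavior reported for real
classifier panels: complementary true positives (the union of tool reports
recovers far more than any single tool), database-limited sensitivity, and
a long tail of low-abundance, tool-specific false positives. A `shared_fp`
stress flag draws all tools' false positives from one pool to probe the
merge's failure mode, false co-occurrence.

What the generator does **not** emulate: correlated errors between tools
that share reference databases, abundance-dependent detection probability,
strain-level structure, or sequence-level effects (chimeras, contamination).
Passing the ensemble tests therefore demonstrates the merge logic under the
stated statistical assumptions, not performance on any real dataset.

## Numerical and degenerate-input choices

* Abundances are carried on the 0–100 percentage scale end to end; inputs
  that look 0–1 scaled (every rank sum at most 1.5) are rescaled on read
  with a warning.
* Profile files are written with six decimal places; a read-write-read
  cycle is byte-stable and abundances round-trip to 1e-6.
* Normalization tolerates all-zero ranks (left untouched, warned) and is
  idempotent to 1e-12.
* Unresolvable taxids are dropped with counted warnings wherever they can
  occur in real inputs (profiles, binning rows, database rows); they are
  errors only where the caller must have resolved them already
  (`lineage_at_ranks()`, `write_profile()`).
* Off-ladder nodes (strains, subspecies, unranked clades) project to their
  deepest fixed-rank ancestor, typically the species; `keep_strains = TRUE`
  preserves them verbatim, in which case the fixed-rank merge ignores them.
* Equal scores at a rank collapse to a single top bin; ties in the
  per-bin abundance sort break by higher score, then lower taxid.

## Problem sizes used in the checks

The packaged checks run 20 replicates of the default 50-species, 6-tool
ensemble; the estimator oracle uses 100 random instances of at most 5 taxa
and 50 reads; the binning recovery experiment draws 10^4 reads. These sizes
keep every distributional property measurable while the whole suite stays
fast on a laptop.

## Known limitations

* The occurrence/database counts treat all tools equally; there is no
  weighting or training, by design.
* Equal-width score bins over the observed range make bin membership
  sensitive to the extremes of the score distribution: when no taxon
  reaches the maximal possible corroboration, the range compresses and
  weakly corroborated taxa shift one bin up. On small ensembles this can
  admit noticeably more low-score taxa in a minority of samples — visible
  in the packaged ensemble experiment, where the merged false-positive
  count at species rank fluctuates around the single-tool mean instead of
  staying below it, while sensitivity and L1 improvements are robust.
* The database-limited sensitivity ceiling (`max_sensitivity()`) is only as
  good as the supplied database profiles.
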