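---
title: "Methods behind the ecological index of hydrocarbon exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the ecological index of hydrocarbon exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eihe)
```

## The index

Deep 16S rRNA amplicon sequencing of a sediment or seawater sample yields,
after classification, read counts per bacterial genus. The ecological index
of hydrocarbon exposure (EIHE) condenses that table into one number per
sample:

$$\mathrm{EIHE} = \sum_{i=1}^{n} HC_{deg,i}$$

where $HC_{deg,i}$ is the relative abundance, as a percentage of the total
reads, of the $i$-th genus in a fixed guild of $n$ genera linked to
hydrocarbon biodegradation. The index estimates the fraction of the
community potentially capable of degrading hydrocarbons; chronically or
freshly polluted marine sediments show values several-fold above nearby
pristine sites.

The guild is a functional grouping, not a clade. The packaged default holds
63 genera, each with at least one described hydrocarbon-degrading strain:
45 Proteobacteria (71.4%), 12 Actinobacteria (19.0%), 3 Bacteroidetes
(4.8%) and 3 Firmicutes (4.8%), spanning marine obligate hydrocarbonoclastic
organisms (*Alcanivorax*, *Cycloclasticus*, *Oleispira*, *Oleiphilus*,
*Thalassolituus*), generalist degraders from soils (*Pseudomonas*,
*Rhodococcus*, *Mycobacterium*) and anaerobic degraders (*Geobacter*,
*Thauera*, *Desulfobacula*). The full supplementary catalogue of the study
that defined the index is not redistributable here, so the shipped list is a
documented reconstruction: the fifteen genera named in that study's text
plus canonical hydrocarbon-degrading genera from the primary literature,
constrained to the published size and phylum composition. The list is a
data asset, not code: `load_guild_list()` accepts any TSV with the same
columns, and `extend_guild()` appends candidates (e.g. *Psychromonas*,
deliberately absent from the default because no degrading strain had been
described) while bumping the version that is stamped into every output.

### Denominator and name matching

Two decisions shape the number itself:

* **The denominator is the root count** — total classified reads — not the
  sum of genus-level rows. Reads that classify no deeper than an
  intermediate rank still dilute the index, matching the definition as a
  percentage of *total* reads. Rows labelled `unclassified` at genus depth
  are kept in the table for the same reason: they contribute to the
  denominator, never to the guild.
* **Matching is exact after normalization, never fuzzy.** Classifier labels
  are compared to guild names after optional case folding and decoration
  stripping (surrounding quotes, `Candidatus` markers, bracketed
  qualifiers); per-entry synonyms are accepted. Substring matching is
  excluded by design — `Oleispira_unclassified` must not silently count as
  *Oleispira*. Two table labels normalizing onto one guild genus abort with
  an ambiguity error rather than picking one.

## Input formats

`read_mothur_tax_summary()` parses the hierarchical taxonomy summary
dialect (columns `taxlevel`, `rankID`, `taxon`, `daughterlevels`, `total`,
then one count column per sample). Parsing re-derives the `total` column
from the per-sample counts and only warns on mismatch, because hand-edited
summaries are common; hierarchical consistency — each internal row equal to
the sum of its daughters, per sample — is enforced as an error, because a
broken hierarchy silently corrupts every percentage downstream.
`read_single_sample_summaries()` merges demultiplexed one-file-per-sample
archives by taxon union with zero fill, and `read_genus_matrix()` accepts a
plain genus-by-sample TSV for pipelines that bypass the mothur dialect.
Counts are stored as integers; percentages are computed on demand and never
written to files that are read back as counts, which avoids
double-normalization bugs.

## Statistical comparisons

Sequencing surveys of this design frequently have one library per site, so
the primary contrast is between two proportions of reads: $k$ guild (or
genus) reads out of $n$ total reads in each sample.

* **Exact p-value.** `fisher_exact_two_proportions()` computes the
  two-sided conditional exact p by summing hypergeometric probabilities of
  all 2×2 tables with the observed margins whose probability does not
  exceed the observed table's (relative tolerance 1e-7 guards ties lost to
  floating point). This is the permutation view of a difference in
  proportions; `permutation_two_proportions()` provides a seeded
  Monte-Carlo cross-check. Degenerate margins return p = 1 rather than an
  error.
* **Interval.** The Newcombe hybrid score interval combines the two
  per-sample Wilson score intervals $(l_1,u_1)$, $(l_2,u_2)$:
  $d \pm \sqrt{(p_1-l_1)^2 + (u_2-p_2)^2}$ (and symmetrically above),
  clipped to $[-1,1]$. The normal quantile is computed from the inverse
  CDF, so non-95% levels work. This interval behaves well for the rare
  proportions typical of individual genera (coverage stays near nominal
  even at $p \approx 0.05$, which the test suite checks by simulation).
* **Replicated designs** use Welch's unequal-variance *t* (two groups) or
  the tie-corrected Kruskal–Wallis *H* with Dunn's rank-based pairwise
  *z* comparisons under Bonferroni adjustment as the post-hoc. The post-hoc
  choice is this package's: Dunn's test is the standard companion to
  Kruskal–Wallis and is stated in every report so it can be swapped later.
  With both group variances zero, Welch's statistic is undefined; the
  documented policy returns p = 1 for equal means and p = 0 otherwise.
* **Multiple testing** across the per-genus screen defaults to *none*,
  reproducing the original per-genus reporting; Benjamini–Hochberg is one
  flag away and is the better default for exploratory screens of many
  genera.

A deliberate consistency contract ties modules together: the guild-level
test's proportions times 100 equal the two samples' EIHE values to within
1e-9, so the statistical and index views can never drift apart.

Compositional effects are not modelled: no CLR transform, no
Dirichlet-multinomial test. These tests treat read counts as simple
proportions, which is exactly what they assume; the simulator exists partly
to probe when that assumption misleads.

## Alpha diversity

Inputs begin at per-sample OTU count vectors; clustering, alignment and
chimera removal are upstream concerns of external pipelines. Implemented
estimators, with their exact variants recorded in each report:

* Good's coverage $100(1 - f_1/N)$.
* Chao1, bias-corrected by default
  ($S_{obs} + f_1(f_1-1)/(2(f_2+1))$, defined even when doubletons are
  absent) with the classic form ($S_{obs} + f_1^2/2f_2$) behind a flag
  because the original reference defines it. Confidence intervals use the
  log-normal construction on $T = \hat S - S_{obs}$:
  $K = \exp\!\big(z\sqrt{\ln(1 + \mathrm{var}(T)/T^2)}\big)$,
  CI $= [S_{obs} + T/K,\; S_{obs} + TK]$, with the variance formula matched
  to the chosen form; $T = 0$ collapses the interval to $[S_{obs}, S_{obs}]$.
* Shannon $H = -\sum p_i \ln p_i$ in natural log — survey values of 5–6.8
  over thousands of OTUs are only consistent with base *e* — with base 2
  available; the interval is $H \pm z\sqrt{\mathrm{var}}$ using the
  analytic variance $(\sum p_i \ln^2 p_i - H^2)/N + (S_{obs}-1)/2N^2$.
* `subsample_otus()` rarefies to a fixed depth by drawing reads without
  replacement (multivariate hypergeometric), deterministically per seed, so
  samples of unequal depth can be compared at a common cutoff such as
  25,000 reads.

## The simulator and what passing tests mean

`simulate_two_group_study()` emulates the two-condition design the index
was built for, at the level the index operates on. A base composition over
`n_genera` genera is drawn from a symmetric Dirichlet
(`baseline_concentration`, default 1 — a flat prior over compositions) and
rescaled so a designated guild of `guild_size` genera holds exactly
`guild_baseline` of the community. The polluted condition multiplies guild
genera by `enrichment_fold` and renormalizes; each sample is then a
multinomial draw of `depth` reads. Defaults mirror the regime the index was
validated in: 500 genera, a 63-genus guild at a 1% pristine baseline,
four-fold enrichment, 25,000 reads per sample — a pristine EIHE near 1% and
a polluted one near 4%, the shape observed in contaminated intertidal
sediments.

Closure matters: multiplying 1% by 4 and renormalizing yields
$0.04/1.03 = 3.88\%$, not 4%. The recorded ground truth is always the
post-renormalization expectation, and recovery is judged against it, not
against the nominal fold. An optional Dirichlet-multinomial mode
(`overdispersion`) adds between-sample variance beyond multinomial noise to
let tests violate the proportions assumption on purpose.

What the simulator does *not* emulate bounds what green tests can claim: no
sequencing error, chimeras, primer bias or copy-number variation, no
taxonomy misclassification, and (by default) no overdispersion between
replicate samples. Passing calibration and recovery checks therefore
demonstrate that the software computes its statistics correctly under the
model those statistics assume — not that a field survey meets that model.

## Problem sizes and numerical choices

The validation suite exercises: exhaustive agreement of the exact p with
direct hypergeometric enumeration over all 2×2 tables with margins up to
12 (8,100 tables, tolerance 1e-10); closed-form agreement of both score
intervals on 1,000 random configurations; 10,000-draw coverage simulations
for both intervals; 1,000 null replicates and 200 effect replicates of the
full pipeline at 25,000 reads and 500 genera. These sizes make every run
exactly reproducible in seconds while leaving Monte-Carlo bands
(e.g. nominal 95% coverage within [0.93, 0.97]) comfortably wider than
binomial noise at 10,000 draws (±0.4 percentage points at one standard
error).

Ties in the exact test are compared with relative tolerance 1e-7;
percentages print at one decimal in report mode and full precision in
machine mode; all simulation functions are pure functions of their seed.

## Known limitations

The index inherits every bias of amplicon surveys: primer coverage, copy
number, DNA from dead cells. Genus membership in the guild is binary —
presence of one described degrading strain — so the index counts potential,
not activity, and a genus's non-degrading members inflate it. The default
guild is a reconstruction at the published composition, not the original
supplementary catalogue, and published per-sample values additionally
depend on the classifier database version, so external datasets should be
compared with a consistent pipeline end to end. Diversity reporting stops
at single-depth rarefaction; rarefaction curves, beta diversity and
phylogenetic metrics are out of scope.
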