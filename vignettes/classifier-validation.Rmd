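---
title: "Naive Bayesian k-mer classification of COI barcodes: model, validation design and simulator"
author: "barcodeNBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naive Bayesian k-mer classification of COI barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeNBC)
```

# The classification model

A query sequence is decomposed into all overlapping words of length
$k$ (default $k = 8$). For a reference database of $N$ sequences in
which word $w$ occurs in $n(w)$ sequences, the prior probability of
observing $w$ is smoothed as

$$\Pi(w) = \frac{n(w) + 0.5}{N + 1},$$

and the probability of $w$ conditional on genus $G$ with $M(G)$
sequences, $m(w, G)$ of which contain $w$, is

$$P(w \mid G) = \frac{m(w, G) + \Pi(w)}{M(G) + 1}.$$

The posterior score of a genus is the naive product
$\prod_{w \in W} P(w \mid G)$ over the query's *deduplicated* word set
$W$, computed in log space; the genus with the highest score is the
assignment and its full lineage (family, order, class, phylum,
kingdom) is reported with it. Because $\Pi(w) > 0$ even for words never
seen in training, no score is ever $-\infty$ and any A/C/G/T query can
be scored against any model.

Word *containment* is counted once per sequence, not per occurrence;
this is what makes $m(w, G) \le M(G)$ hold and keeps the conditional a
probability. Windows containing a character outside A/C/G/T are
dropped from the query (reference curation removes such sequences
entirely).

Confidence is estimated by bootstrap: each of 100 trials draws
$\lceil |words| / 8 \rceil$ words with replacement from the query's
word *multiset* and recomputes the winning genus. The support of a
taxon at any rank is the percentage of trials whose winner's lineage
passes through that taxon, so support is an integer count of trials
and never decreases toward the root. Summarizing an assignment to a
more inclusive rank under a support cut-off
(`summarizeToRank()`) therefore trades resolution for accuracy.

## Assumptions

* Word occurrences are treated as independent given the genus (the
  "naive" assumption). COI is protein-coding with strong site-to-site
  dependence, so scores are useful for ranking genera, not as
  calibrated probabilities; the bootstrap support is the package's
  confidence measure.
* The true taxon is assumed to be present in the reference. The
  classifier is not a novelty detector: queries from absent taxa are
  assigned to the best available genus, and only a support cut-off can
  withhold such calls (see the coverage-gap analyses below).

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `k` (word size) | 8 nt | the word length used throughout for COI; small enough that a 650 nt barcode yields ~640 words, large enough to be discriminative |
| `nBootstrap` | 100 trials | supports are then integer percentages, matching percent-scale cut-offs |
| `bootstrapFraction` | 1/8 | each trial resamples one eighth of the query's words |
| `checkReverseComplement` | on | barcode reads arrive in either orientation; both are scored and the better one kept |
| `minLength` (curation) | 500 nt | full-length barcode threshold below which records are excluded |

# Numerical and design choices

* **Bootstrap resampling pool.** Trials draw from the word multiset
  (with multiplicity), not the deduplicated set, and trial scores sum
  the drawn words with multiplicity. This keeps homopolymer-rich
  queries from collapsing to a handful of effective draws.
* **Tie-breaking.** Ties at the top score are broken by lexicographic
  taxon name — deterministically — and flagged on the `Assignment`.
* **Orientation.** When both orientations are scored, the one with the
  higher best-genus score wins; forward wins exact ties.
* **Support by lineage prefix.** A trial supports a taxon when the
  trial winner's lineage *path* passes through it (prefix comparison,
  not name equality), so identically named placeholders under
  different parents are never conflated and monotonicity toward the
  root is structural.
* **Leave-one-out by decrement.** LOOCV subtracts the held-out
  sequence's counts ($N$, $n(w)$, $M(G)$, $m(w, G)$) rather than
  retraining; a genus emptied by the removal is excluded from the
  candidates for that query. The test suite verifies outcome-identity
  against a naive full retrain per query.
* **Taxids.** The taxonomy file's integer ids are assigned
  deterministically (root 0, then depth-first in lexicographic name
  order): identical inputs give byte-identical training files.
* **Placeholders.** A record lacking an intermediate rank is placed
  under `undef_<nearest named ancestor>` (e.g. `undef_Insecta` for a
  missing order); a missing name *at the trained rank* rejects the
  record instead.
* **Reject precedence.** Screening reports the first failing rule in
  the fixed order length → N → ambiguity → name → rank completeness,
  so filter reports are deterministic. "Ambiguity" means any
  character outside A/C/G/T/N; N is counted separately because missing
  data and ambiguity codes are distinct data-quality problems.
* **Name screening.** Insufficiently identified names (`sp.`, `nr.`,
  `aff.`, `cf.`) are matched as whitespace-delimited tokens, so taxon
  names merely containing those letter runs are not rejected.
  Family-trained policies permit such names, which maximizes taxon
  diversity when only family-level resolution is needed.
* **Duplicates.** Duplicate sequences for the same taxon are retained
  unconditionally: they carry information about within-species
  variation. Note that LOOCV accuracy is optimistic for taxa with
  identical duplicates (the held-out query still has an exact twin).
* **Rounding.** Report percentages are rounded half-up to integers;
  raw ratios are kept internally. In the coverage summary, orders
  without a described-count estimate are excluded from described
  totals and from averages, while their represented counts still enter
  represented totals; a described count of zero is an error rather
  than a silent infinity.
* **Cut-off grid.** `selectCutoffs()` scans support cut-offs in
  5-point steps from 0 to 100; an entry is NA when no grid value
  attains the target accuracy with at least one query retained. Both
  "never reaches the target" and "nothing retained" map to NA.
* **Singleton handling.** Accuracy and cut-off tables exclude
  singleton queries by default (their LOOCV call cannot be correct at
  the trained rank); type I/II error and per-group misclassification
  tables include them. Both are parameters.

# What the simulator emulates — and what it does not

`simulateReference()` evolves a uniform random root sequence down a
balanced taxonomy by independent per-site substitution to one of the
three other bases (Jukes–Cantor-like), with no indels: supra-species
branches at `interGenusDivergence`, species ancestors at
`intraGenusDivergence`, individual sequences at
`intraSpeciesDivergence`. The defaults — 5 orders × 2 families × 3
genera × 3 species × 2 sequences of 650 nt, rates 0.12 / 0.02 / 0.005
— give a reference of 180 sequences with a clear barcode gap:
within-genus identity far above between-genus identity, on the scale
of full-length COI barcodes. The within-species rate of 0.5% reflects
the limited intraspecific variation typical of well-sampled barcode
data sets. These sizes also keep the full validation suite (four LOOCV
sweeps plus self-classification) comfortably within an interactive
run.

Novel taxa are simulated by *generating extra* genera (one per family)
and one extra order, then withholding them from the training set —
rather than deleting reference taxa — so reference and query sets are
independently sized. `makeQueries()` draws fresh sequences from
species ancestors (never verbatim training copies) and takes the
requested fraction of query taxa from the novel pool, reproducing the
situation where a whole order is present in one reference database and
absent from another.

Indel-free uniform substitution is a deliberate simplification: real
COI evolves under codon structure, transition bias and rate
heterogeneity, and real reads carry platform errors (e.g. homopolymer
artifacts). Passing the simulated benchmarks therefore demonstrates
the machinery's correctness — count bookkeeping, LOOCV semantics,
error partitions, cut-off calibration — and the classifier's behaviour
under controlled divergence, not its field accuracy on real insect
communities, which depends chiefly on reference-database completeness.

```{r example, eval = FALSE}
sim <- simulateReference(SimParams(seed = 101))
full <- loocv(sim@reference, ClassifierParams(), seed = 102)
accuracyByRank(full, cutoff = 0, includeSingletons = TRUE)
errorRates(full, cutoff = 90)
```

# Known limitations

* Dense count storage (a genera × 4^k matrix) is comfortable at
  k = 8 and a few hundred genera, but is not engineered for
  reference sets with tens of thousands of genera; k is capped at 12.
* Species-rank assignment is out of scope: training stops at genus (or
  family), as does every summary.
* The classifier offers no novelty detection; the coverage-gap
  analyses quantify, but do not remove, the resulting nonmatch risk.
* Lineages above the trained rank are taken from the first record of
  each genus; conflicting higher classifications within a genus are
  not reconciled.
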