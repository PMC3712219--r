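---
title: "Profile-matching taxonomic assignment: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-matching taxonomic assignment: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanner)
```

## The model

A sequence's **LCA Profile** is the set of its homology matches, reduced to
the best hit (by bitscore) per taxon and trimmed to bitscores at least
`p` times the best retained bitscore.  Both reductions matter: deduplication
first, so that a taxon's weaker secondary alignments never influence the
threshold, then the inclusive cut (`bitscore >= p * best`).  The classical
LCA rule assigns the lowest common ancestor of the profile's taxa; the
best-hit rule assigns the top taxon.  Both use only marginal information
about each hit.

The profile-matching classifier instead treats the whole profile as the
classification feature.  Matches are embedded in a 2-D grid: the **taxonomy
axis** (grouping by ancestor) and the **e-value axis** (each e-value mapped
to `x = -log10(max(e, evalue_floor))` and min–max rescaled within its own
profile, best match at 1, worst at 0).  Two profiles are compared with a
pyramid match: for iterations `i = 1 ... h` (with `h = 8`, the number of
canonical ranks), matches are pooled by their ancestor at rank depth `h - i`
while the e-value axis is cut into `2^(h-i)` equal, half-open bins (closed
at the top, so position 1 falls in the last bin).  At the final iteration a
single bin spans both axes.  The total intersection count
`I_i = sum over bins of min(count_a, count_b)` is weighted by
`w_i = 2^(1-i)` and the similarity is `sum_i w_i I_i`.  Two properties
follow directly and are enforced by tests: `I_i` is non-decreasing (bins
only coarsen), and the score is bounded by
`min(|a|, |b|) * (2 - 2^(1-h))`, attained by identical profiles.

Note the variant weights **total** counts per level, not the increment over
the previous level as the original pyramid match kernel does; the reduced
4-rank worked example (`pmk_example_fixture()`), whose per-iteration counts
are (0, 1, 2, 3) and whose similarity is 1.375, pins this down — increment
weighting cannot reproduce that trace.

A query is scored against every reference profile (built from an
all-versus-all search of the reference proteins); references with score at
least `y` times the best score vote, and the lowest common ancestor of their
source taxa, truncated to `max_depth`, is the assignment.  The root is the
explicit "unclassified" answer.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `p` | 0.85 | bitscore fraction for profile membership (dimensionless, in [0, 1]); inclusive boundary |
| `y` | 0.95 | kernel-score fraction for the reference vote; inclusive boundary |
| `h` | 8 | pyramid levels; must equal the taxonomy's rank count |
| `evalue_floor` | 1e-180 | clamp for e-values reported as 0 before the log transform |
| `max_depth` | 6 (genus) | deepest assignable rank; species/strain naming in reference databases is too inconsistent to predict |

Ranks are the fixed ordinals 0 ("cellular organisms", effectively
unclassified) through 7 (species).  Taxonomies loaded from NCBI dumps or
simple TSVs are canonicalized at load time: nodes with non-canonical ranks
("no rank" intermediates, strains, subspecies) are collapsed onto their
nearest canonical ancestor and their ids kept as aliases, so strain-level
subject ids still resolve.

## Evaluation framework

A prediction at depth `d` has **precision** `d`; its **correct** ranks are
the depth of the lowest common ancestor of prediction and truth (the longest
common lineage prefix — in a tree the matching ranks always form a prefix);
**incorrect = precision − correct**, an exact integer identity.  Averaging
over a query set gives the precision / incorrect-ranks trade-off between
methods: best-BLAST maximizes precision at the cost of incorrect ranks, LCA
the reverse, profile matching sits between, tunable by `y`.

The **leave-one-out** experiment simulates taxonomic novelty at a chosen
rank: for each reference protein used as a query, all matches to taxa
sharing the truth's ancestor at the novelty rank are removed from the query
profile and from every reference profile, reference profiles whose *source*
shares that ancestor are dropped entirely (a genome absent from the database
contributes no profiles — the stricter reading of leave-one-out), and
assignments are capped at one rank above the novelty (genus for species
novelty) because deeper ranks cannot be correct.  Two orderings matter and
are deliberate:

* **Masking precedes thresholding.** The experiment consumes profiles built
  with `p = 0` (full match lists) and applies the working `p` *after*
  masking, relative to the best surviving match.  Removing a clade from the
  database lets weaker matches enter the window of a real search, and the
  masked-then-thresholded order reproduces that.
* **Deep assignments are penalized, not truncated.** A method that assigns
  below the novelty cap accrues incorrect ranks for the excess depths.  This
  is what lets a rank-fixed baseline be measurably "too precise";
  truncation would hide the error.  (Truncated evaluation remains possible
  by lowering `max_depth`.)

## What the simulator emulates

`simulate_reference_world()` generates hit tables, not sequences.  Each
sequence from species `s` registers one hit per reference species `t`:

```
bitscore(s -> t) = base * F(dist(s, t)) * exp(w_t - w_s) * exp(eps)
```

with `dist` the lineage distance (depth of the deeper node minus the depth
of their LCA), and e-values derived monotonically
(`e = 10^(-bitscore / evalue_k)`) so the two axes order hits consistently.
Three structural choices deserve explanation:

* **The decay profile `F` saturates, then falls off a cliff.**  Default
  fractions (0.96, 0.92, 0.70, 0.55, 0.45, 0.35, 0.25) for distances 1–7.
  Protein similarity behaves this way — high and slowly decaying among close
  relatives, dropping steeply toward the twilight zone — and it produces
  `p = 0.85` profiles that span roughly the family, as profiles from real
  searches do.  A single geometric factor cannot do this: it either empties
  the window (fast decay) or parks whole distance clusters on the window
  boundary, where their membership flips with noise.  The default world
  shape `(2, 2, 1, 1, 2, 2, 2)` (32 species, cluster distances
  {1, 2, 3, 6, 7}) keeps every cluster several noise standard deviations
  away from both the reference window edge (`0.85 * base`) and the
  deeper-reaching masked-query window edge.
* **Rate variation is a property of the species, not the hit.**  Each
  species draws one factor `w` per world, applied to every hit it receives
  in every profile (relative to the source's own factor, so self-hits stay
  at `base`).  This is what makes match patterns *reproducible* across
  profiles from the same neighbourhood — precisely the structure
  profile-matching exploits; purely i.i.d. per-hit noise would contradict
  the method's premise.  The default sd (0.01) is kept below the
  congener-vs-confamilial gap `log(0.96/0.92) ≈ 0.043`: beyond that,
  bitscore order no longer tracks taxonomic proximity and no
  homology-strength method can recover the genus — a genuinely hard regime,
  not the clean one the generator's defaults represent.
* **Per-hit jitter is small** (sd 0.005): alignment scores are essentially
  deterministic given the sequences; most profile-to-profile variation in
  real data is structured.

LGT is injected at the hit level: a carrier species (probability
`lgt_rate`) gets a fixed donor from the other domain; its queries and a
fraction of its reference proteins receive the *same* donor hit at
`0.95 * base`, inside the `p = 0.85` window.  This reproduces, on synthetic
data, the confounded-gene phenomenon: the LCA rule collapses to the root
while profile matching, recognising the shared anomaly in the recipient
lineage's reference profiles, assigns at family depth or below.

What the simulator does **not** emulate: sequence-level effects (read
length, gene prediction errors, composition), unbalanced taxonomies with
wildly varying database density, multi-gene genomes with heterogeneous
gene-specific decay curves, and partial or chimeric alignments.  Passing
tests on these worlds therefore demonstrate the algorithmic machinery —
thresholds, binning, voting, masking — under a controlled regime, not
field performance on real metagenomes.

## Numerical choices and degenerate inputs

* E-value bin assignment is `min(floor(pos * nbins), nbins - 1)`: half-open
  bins, closed at the top.
* Single-match profiles (and profiles whose e-values all coincide) place
  every point at position 1.
* Matches whose lineage is shallower than the current binning depth (or has
  collapsed intermediate ranks) bin by their deepest available ancestor.
* Ties in bitscore break by ascending e-value, then lexicographic taxon id;
  reference score ties break by source id — all outputs are deterministic.
* Empty profiles are an explicit sentinel and classify to the root; a best
  kernel score of 0 likewise yields a flagged root assignment.
* Both thresholds keep their boundary points (`>=`), for `p` and `y` alike.

## Known limitations

* The kernel score is not normalized for profile size: among references
  co-binned with the query to the same extent, those with more matches score
  higher.  The `y`-relative vote absorbs most of this, but extremely
  unbalanced reference databases may need per-size calibration.
* The min–max e-value normalization pins each profile's *worst* match at
  position 0, so two profiles sharing their weakest taxon always intersect
  at the finest level.  With well-populated profiles this is a small,
  symmetric effect; with two-match profiles it can dominate the score.
* Collapsing non-canonical ranks is a modelling choice; taxa whose canonical
  lineage skips ranks bin by their deepest available ancestor, which makes
  their fine-level bins coarser than species resolution.
* Leave-one-out experiments are run here at desk scale (tens of species,
  a few reference proteins per species, chosen so the full suite runs in
  seconds); the experiment functions accept arbitrarily larger worlds.
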