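---
title: "Building semi-quantitative seasonal metawebs from literature interaction records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building semi-quantitative seasonal metawebs from literature interaction records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metawebr)
```

## The problem

Regional food webs for remote systems — high-Arctic archipelagos are the
motivating case — cannot be measured in one campaign. What exists instead is
a century of scattered literature: diet studies using incompatible metrics
(frequency of occurrence, relative biomass, caloric fraction, whole-scat
equivalents), anecdotal reports that an interaction merely exists, heavy
summer bias in fieldwork, and research effort concentrated on a handful of
flagship taxa. `metawebr` turns such a corpus into a *metaweb*: the regional
pool of potential consumer-resource links, weighted on a common
semi-quantitative scale, stratified by season and by interaction layer
(predation `Pr`, scavenging `Sc`, herbivory `He`, pollination `Po`,
kleptoparasitism `Kl`, coprophagy `Co`, detritus flow `De`), together with
an explicit accounting of how unevenly the underlying knowledge is
distributed across nodes.

A metaweb deliberately does not filter links by local co-occurrence; it is a
conceptual blueprint of who *can* eat whom, not a realized network.

## The scaling procedure

For each study $s$ and consumer $c$, the raw values $v_i$ reported for the
consumer's resources are standardized so they sum to 100%:

$$\mathrm{share}_i = 100 \cdot \frac{v_i}{\sum_j v_j}.$$

This removes the native scale of the metric; it requires (and the code
enforces) that a study-consumer group uses a single metric. No conversion
between metrics is attempted — relative biomass and occurrence frequency are
simply treated as alternative measurements of the same relative-importance
quantity, which is the assumption that makes a heterogeneous corpus usable
at all.

Shares are then binned on a log2 ordinal scale reflecting the nonlinear
growth of ecological importance:

| share of intake | score | class |
|---|---|---|
| 0% | 0 | absence |
| (0, 5]% | 1 | marginal |
| (5, 20]% | 2 | auxiliary |
| (20, 67]% | 4 | primary |
| (67, 100]% | 8 | keystone |

Two numerical choices are ours. First, the intervals are half-open and
upper-inclusive: the keystone class is "over 67%", so a share of exactly
67% is primary. Second, the 67% cut is applied as the literal value, not as
$200/3$, even though the keystone gloss ("twice as strong as any other
interaction") would suggest two-thirds; the printed constant wins.

Per-study scores for the same consumer-resource-layer link and season are
averaged with equal weight — studies are not weighted by sample size, year
or metric, because the corpus provides no defensible weighting — and the
average is rounded to one decimal, half away from zero. Intermediate values
between the ordinal categories are therefore meaningful (a strength of 3.0
may be the average of a primary and an auxiliary measurement).

### Seasons

A study is classified by the strict majority of its covered months: winter
is November-March, summer May-September. April and October belong to
neither block, so a study covering only them — or tied between blocks — is
*unclassified*; unclassified quantitative studies are excluded from the
seasonal averages with a warning. This tie-handling is our convention; the
corpus the method was developed for apparently contained no such study.

### Case studies and extrapolation

Anecdotal case reports establish existence without magnitude. A link-season
covered only by case studies receives the constant floor 0.1 — a constant,
not a sum: ten anecdotes are still 0.1. Where any quantitative study covers
the link-season, case reports are ignored. A case report without a
classifiable season is taken as season-agnostic and floors both seasons;
this is our reading of "complementing" the quantitative table with case
studies.

Winter data are chronically scarce. Summer strengths may be copied to
winter, but only for an explicit, user-supplied list of links (provenance
`extrapolated`, `n_studies = 0`); extrapolation never overwrites a measured
winter value, and is never automatic, because no rule can decide which
summer interactions persist through the polar night.

## Network assembly

`metaweb()` assembles the directed multilayer graph. Edges run in the
energy-flow direction, resource to consumer; the layer is an edge attribute,
so parallel edges between the same pair in different layers coexist.
Pollination stays in the same unipartite graph (energy transfer via
nectar/pollen); kleptoparasitism book-keeps the robbed victim as the
resource. Links with averaged strength 0 — measured absences — are not
edges.

Layers supported by fewer than `min_links` measured links are excluded as
unresolvable (`exclude_sparse_layers()`); case-only links do not count
toward retention, so a layer cannot survive on anecdotes. The default
`min_links = 3` is our choice of the smallest count from which a layer's
presence is more than a single observation plus noise; the source procedure
says only "too scarce" and in practice drops coprophagy and detritus flow.

`extract_subweb()` restricts the web to edges from a resource set to a
consumer set in named layers (e.g., terrestrial plants to pollinators), and
`crossover_summary()` splits a consumer's incoming strength by the realm
(marine / terrestrial / coastal) of its resources — the quantity behind
marine-terrestrial energy-crossover statements about top predators.

## Knowledge bias

Literature-derived networks are only as good as the literature's coverage.
For each (paper, species) pair we score 1 if the paper measured interaction
strength for that species and 0.25 if it is a case study; a paper that both
measures and anecdotally mentions a species counts once, as measured. Node
knowledge is the sum over its species; *weighted* knowledge divides by the
node's species count, so aggregated nodes are not credited for knowledge
about one member. The canonical worked example — a 3-species node covered
by one paper measuring species A, one measuring A and B and a case study on
C — gives $1 + 2 + 0.25 = 3.25$ and weighted $3.25/3 = 1.08$:

```{r}
fx <- reference_fixtures()$knowledge
knowledge_score(fx$records, fx$nodes)
```

Species granularity comes from an optional `species` column on the record
table; without it each (paper, consumer-node) pair counts as one species.
Whether 0.25 applies per species or per paper when a case study mentions
several species is not specified anywhere we know of; we apply it per
(paper, species) pair, symmetric with the measured case.

## The synthetic literature generator

`simulate_records()` emulates the statistical structure the method must
survive, not any real species list. Each consumer receives a fixed "true"
diet (shares from a symmetric Dirichlet over a random resource set, each
resource with a layer); studies then sample consumers with flagship
oversampling, observe the diet under one of several native metrics that
differ only by scale (percent, per-mille, proportion, arbitrary index), and
report either the full quantitative table or a single anecdotal row.
Defaults describe the corpus the method targets: 30 nodes, 120 studies
accumulated over a century with recent-skewed publication years, 10% of
consumers flagship and studied 4x as often, 10% winter studies, 30% case
reports, Dirichlet concentration 0.8 (skewed diets with dominant prey).
Measurement noise resamples per-study shares from a Dirichlet centred on
the truth with concentration $2/\mathrm{noise}$; `noise = 0` reproduces the
truth exactly, which is what makes parameter-recovery testing sharp: with
zero noise the pipeline must recover every link's true ordinal class
(the suite requires at least 95%), and recovery must degrade monotonically
as noise grows.

What the generator does *not* emulate: spatial structure, correlated
year-to-year diet shifts, taxonomic misassignment, or the possibility that
different metrics are not scale-equivalent. Passing tests on synthetic data
therefore show the bookkeeping is right, not that real diet metrics are
commensurable — that assumption is inherited from the method itself.

## Problem sizes and reproducibility

The test suite runs the full property suites at moderate sizes chosen to
exercise every code path many times over: 200 random tables for the
brute-force equivalence check, about 1,000 study-consumer groups for the
normalization invariant, and 150-study corpora for parameter recovery. All
randomness flows through explicit seeds; `run_pipeline()` writes a manifest
with a config hash and row counts, and identical inputs and config produce
byte-identical output bundles.

## Known limitations

- Within-group metric uniformity is enforced, never reconciled; a corpus
  mixing metrics for one study-consumer pair must be split upstream.
- Averaging over studies ignores study quality and duration; a multi-year
  monitoring program counts like a single-season note.
- The case floor 0.1 is a convention for "exists, magnitude unknown" and
  should not be read as a measured strength.
- Kleptoparasitic energy is booked from the victim, which double-counts the
  victim's own intake at the level of the full web; no correction is
  attempted.
- The metaweb is not a realized network: no co-occurrence filtering, no
  abundance weighting, no spatial resolution.
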