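---
title: "Evaluating DNA barcodes: distances, identification, monophyly, and a known-truth simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating DNA barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A DNA-barcoding study asks whether a short, easily amplified locus (or a
concatenation of a few) can assign specimens of a difficult genus to
species. The data are one aligned matrix per locus over the same samples:
one to a few individuals per species, some species inevitably sampled
once ("singletons"), plus a handful of outgroup accessions used only for
tree context. `barcodeval` implements the three evaluation families such
studies run side by side — pairwise-distance criteria, nearest-neighbour
identification, and tree-based monophyly — behind one front door,
`barcode_eval()`, and pairs them with a seeded simulator so every stage
can be exercised against known truth.

## The distance model

All criteria consume Kimura 2-parameter (K2P/K80) distances. For a pair
of aligned sequences, sites where either member carries a gap (`-`),
missing data (`?`) or an IUPAC ambiguity code are removed *for that pair
only* (pairwise deletion, the MEGA default — complete deletion would
discard most of a length-variable spacer such as *trnH-psbA*). With `P`
and `Q` the transition and transversion proportions over the remaining
sites,

$$d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

When no sites remain, or the log argument is non-positive (saturation),
the distance is *undefined*: it propagates as a flagged `NA` rather than
an error or a silent drop, so one divergent outgroup cannot kill a whole
matrix, and every downstream summary reports how many pairs it excluded.
Distances are held at full precision internally and rounded (4 decimals)
only in printed reports.

`distance_matrix()` computes all pairs at once through indicator
cross-products (seven matrix products instead of $n(n-1)/2$ per-pair
scans); `k2p_pair()` is the transparent per-pair route exposing the site,
transition and transversion counts. The two routes are checked against
each other, and against an independent implementation, in the test suite.

## Discrimination criteria

**Local barcoding gap (PWG).** A species with $\ge 2$ sampled individuals
succeeds when its smallest interspecific distance (any member to any
non-member, singletons included) *strictly* exceeds its largest
intraspecific distance. Ties fail: the criterion demands "larger than",
and a tie means an allospecific sequence is indistinguishable from a
conspecific one. The global gap (`global_gap_exists()`) is the analogous
statement over the pooled distance classes; `gap_histogram()` (default
bin width 0.005, configurable) shows both distributions on one grid.

**Best Match / Best Close Match.** Every individual of a non-singleton
species is queried against all other samples. The match set is every
sample tying the minimal distance within a relative tolerance of `1e-9`
(floating-point equality would be meaningless); the verdict is *correct*
if all tied matches are conspecific, *incorrect* if none are, *ambiguous*
otherwise. Best Close Match adds a threshold — the 95th percentile
(linear interpolation) of all intraspecific distances, the TAXONDNA
convention — and returns *no match* when the minimal distance strictly
exceeds it. Singletons serve as references (potential wrong matches) but
never as queries.

**NJ monophyly.** Neighbor-joining on the K2P matrix (agglomeration
delegated to ape's NJ), with two determinism measures on top: the input
matrix is put in lexicographic label order first, so the result cannot
depend on row order, and negative branch lengths are clamped to zero with
the excess moved to the sibling edge. Support comes from a nonparametric
bootstrap over alignment columns (default 1,000 replicates, seeded;
replicates whose resampled matrix contains undefined distances are
skipped and counted, more than 20% skipped is an error). A species counts
when some edge of the unrooted tree isolates exactly its samples — either
side of the edge — with support strictly above 50%.

One numerical choice deserves emphasis: internal edges of numerically
zero length (tolerance `1e-12`) are collapsed before bipartitions are
read. NJ resolves a polytomy of identical sequences arbitrarily; without
the collapse, such an arbitrary resolution can isolate "exactly" one
species's samples and — being driven by ties, hence stable across
bootstrap replicates — acquire full support. A cluster separated by zero
branch length is not a cluster.

**Accounting.** All rates are per individual, not per species: every
individual of a successful species counts, and the eligible set is the
individuals of species with $\ge 2$ samples *in the analysed matrix*.
This reproduces the familiar denominators of a 52-sample study with nine
singletons: 43 eligible individuals at a locus held by all samples, 41
at a locus missing two samples of one four-individual species. Reports
carry integer numerators and denominators so every percentage is exactly
recomputable. Outgroups ride along into trees but are excluded from every
statistic.

## Multi-locus combinations

`enumerate_combinations()` lists all subsets of size $\ge 2$ (eleven for
four loci), ordered by size then lexicographically. `concatenate_loci()`
joins alignments sample-wise in the stated locus order and **drops**
samples missing any member locus (logging them and emitting a 0-based,
half-open partition table) rather than padding with `?`: padding would
leave pairwise-deletion distances dominated by whichever loci remain,
silently changing what a "combined barcode" distance means, and the
dropped-sample convention is what makes plastid-combination denominators
come out at 41 rather than 43.

## What the simulator emulates

`generate_dataset()` draws, from one mandatory seed with per-stage
substreams:

1. a Yule species tree (backward construction; expected root height
   $(1/\lambda)\sum_{k=2}^{n} 1/k$), optionally rescaled to a target mean
   tip-to-tip divergence and/or stretched at the tips to enforce a floor
   on the smallest divergence (both keep it ultrametric);
2. per-individual genealogies: conspecific individuals join their species
   lineage as a star at an exponential within-species depth (mean
   `intra_depth`, truncated below the terminal branch). All plastid loci
   share one genealogy; the nuclear locus gets an independent one. With a
   configured probability per sister pair — or forced for named pairs —
   the recipient's plastid samples are moved wholesale into the donor's
   cluster (chloroplast capture), and the event is recorded in the truth
   table;
3. sequences under K80 with per-locus rate multipliers and $\kappa$, plus
   indel events (Poisson count per alignment; branch chosen proportional
   to length; contiguous columns gapped in all descendants, so the
   alignment stays rectangular without an aligner).

The `pulsatilla_profile()` preset fixes the conditions of a typical
congeneric four-locus study: 19 species as 5,4,5,4,5,4,4,4,4,4 individuals
plus nine singletons (52 samples); locus lengths 1207/835/379/589; rate
multipliers 0.11/0.20/0.19/1 (the mean-interspecific ratios such a study
reports, nuclear locus fastest); mean species divergence 0.032 and
within-species depth 0.0016 substitutions/site, matching the reported
mean inter- and intraspecific ITS distances; indel regimes 11 events of
1–25 columns on the spacer and 5 of 1–2 on ITS; and two samples of one
four-individual species missing the two slow plastid loci, which is what
produces the 50- vs 52-individual matrices and the 41/43 denominators.
$\kappa = 2$ throughout — unreported in the emulated design, set to the
textbook transition bias. The default capture probability is 0; scenario
runs force the pair explicitly, since no quantitative introgression rate
is available to emulate — the value is illustrative, not estimated.

What the simulator deliberately does **not** emulate: alignment error
(indels are clean, shared blocks — real spacer alignments are messier),
rate variation across sites, recombination within loci, concerted
evolution of ITS arrays, and base-composition bias. Passing the
known-truth tests therefore shows the *pipeline logic* is right under the
model's assumptions; it does not certify accuracy on real data, where
those violations are exactly what erodes barcode resolution.

## Known-truth scenarios

Two scenarios anchor the test suite and the acceptance script:

* **Clean recovery**: within-species depth 0 and a species-tree floor of
  $0.05/0.11$ substitutions/site, so even the slowest locus (rate 0.11)
  separates every species pair by $\ge 0.05$. All four criteria must
  return 100% on every locus.
* **Chloroplast capture**: the same conditions plus forced capture on one
  sister pair in which both species have several individuals (the seed
  sequence is scanned deterministically for a species tree containing
  one). Plastid-locus PWG and NJ rates must lose exactly that pair's
  individuals; the nuclear locus must stay at 100%. This reproduces, in
  miniature, the cyto-nuclear discordance that hybridization or plastid
  lineage sorting imprints on real plastid barcodes.

## Problem sizes

The test suite works at deliberately small scales — random alignments up
to roughly 10 × 150, 200-matrix oracle sweeps for the classifiers,
exhaustive NJ recovery over all unrooted topologies on 4–6 taxa,
bootstraps of 50–200 replicates, and the 52-sample preset with 100
bootstrap replicates for the end-to-end scenarios; the acceptance script
uses 200 replicates for the study-scale run. These sizes give stable
verdicts for properties that are either exact (oracle equality,
structure recovery) or coarse (100% vs reduced rates) while keeping the
whole suite fast enough to run habitually.

## Limitations

Only NJ trees are built: the evaluation families that require likelihood
or Bayesian machinery (ML, BI) belong to external tools and their columns
are not reproduced here. The K2P model is fixed (no model selection), as
it is the de-facto standard for barcode distance reporting. Indel columns
never contribute to distances or site counts, matching the
DnaSP/MEGA conventions, so information in shared indels is summarised
(event counts, length ranges) but not used for discrimination.
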