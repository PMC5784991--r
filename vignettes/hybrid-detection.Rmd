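---
title: "Dual-marker hybrid detection and mating simulation in Eisenia earthworms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker hybrid detection and mating simulation in Eisenia earthworms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridworms)
library(dplyr)
```

## The problem

*Eisenia andrei* (Ea) and *E. fetida* (Ef) are simultaneous hermaphrodites
with reciprocal insemination, both capable of self-fertilization. When a
virgin Ea is paired with a virgin Ef, an offspring can be a self-fertilized
pure-species worm or an interspecific hybrid, and no phenotype reliably
distinguishes the two. The resolution is a dual-marker design:

* **Mitochondrial COI** is uniparentally inherited from the ovum, so its
  haplogroup (`a` for Ea, `f` or `f2` for Ef) identifies the *maternal*
  lineage only.
* **Nuclear 28S rRNA** is diploid and biparental: `AA` in Ea, `FF` in Ef,
  and `AF` in hybrids, visible in a Sanger consensus as double peaks
  (IUPAC two-base ambiguity codes) at species-diagnostic sites.

Each worm is labelled by a genotype code: lowercase mitochondrial clade
followed by the two nuclear alleles, **maternal allele first** — `aAA`,
`fFF`, `f2FF`, and the two hybrid classes `aAF` (from an Ea ovum) and `fFA`
(from an Ef ovum). The package implements the full analysis chain: marker
discovery and genotype calling, the gamete model that interprets offspring,
a pedigree census, and a forward mating simulator with rate estimation.

## Marker model

**Diagnostic sites.** Given reference alignments of both species,
`find_polymorphic_sites()` reports columns where the pooled references carry
two or more distinct unambiguous bases, and `find_diagnostic_sites()` keeps
the subset fixed for one base in every `A` reference and a different base in
every `F` reference. In the study system the two species differ at 9
polymorphic 28S sites of which 7 are diagnostic; the remaining two segregate
within a species. All columns are 1-based; gaps and `N` are excluded
pairwise, never globally; input is uppercased on read.

**Nuclear calls.** `call_nuclear()` scores each diagnostic column of a query
as `homA`, `homF`, `het` (exactly the two-base IUPAC code covering both
alleles — the standard Sanger convention for a heterozygote consensus, which
the source data never states explicitly but almost certainly used), or
`unresolved`. The genotype is `AA`/`FF` only if *all* resolved sites agree,
and `AF` if at least 80% of resolved sites (and at least 2 sites) are `het`.
The 80%/2 rule tolerates one miscalled peak among 7 sites while refusing to
call a hybrid from a single ambiguous column. Mixed `homA`/`homF` patterns
*without* ambiguity codes are not heterozygotes but candidate
chimeras/contamination, and come back `ambiguous`. A query with zero
resolved sites warns and returns `ambiguous` rather than erroring, so one
bad record cannot kill a batch.

**Haplogroups and distances.** `p_distance()` is the uncorrected proportion
of differing sites among pairwise-comparable columns. `call_mito()` assigns
the clade with the smallest mean p-distance to its references and reports
the margin to the runner-up; calls with margin below 0.02 are `ambiguous`.
The 0.02 default sits an order of magnitude below the smallest between-clade
divergence in this system (0.114) and well above typical within-clade
variation, so it only fires for genuinely intermediate sequences.
`group_p_distance()` is the arithmetic mean over all between-group pairs;
the source reports single p-distances per species pair (0.150 COI between
species, 0.114 f vs f2, 0.017 for 28S) without stating the averaging, and
mean-over-pairs is our choice. `cluster_sequences()` partitions sequences by
single linkage cut strictly below a threshold (default 0.05, between
within- and between-clade distances), implemented as union-find over the
thresholded distance graph with cluster numbers ordered by smallest member
id, so results are deterministic; it replaces the original
maximum-likelihood phylogram, whose inference and bootstrap are out of
scope.

## The gamete model

A worm of genotype `m·XY` makes ova `mX` and `mY` (one type if homozygous)
and sperm `X` and `Y`; sperm carry no mitochondria. An offspring is
`ovum clade + ovum allele + sperm allele`, which is exactly the
maternal-first code convention. Two refinements:

* **Incompatible ova.** Ova whose nuclear allele belongs to the other
  species than their mitochondria (`aF`, `fA`) are regarded as less probable
  and excluded by default (`exclude_incompatible = TRUE`); the exclusion is
  a policy switch, not a law, because the evidence is "less probable", not
  impossible.
* **Facilitated self-fertilization.** Selfing in a *paired* worm is
  genetically identical to ordinary selfing; biologically it appears to be
  triggered by copulation and sperm mixing. `explain_offspring()` therefore
  labels self-scenarios of paired worms `facilitated_self`, and the
  simulator draws it with probability `1 - h`.

The model makes the observed asymmetry structural: an interspecific pair can
produce `aAF` (from the `aA` ovum of the Ea partner) and `fFA` (from the
`fF` ovum of the Ef partner) but never `fFA` from an `aA` ovum. `f2` is a
distinct maternal lineage whose nuclear allele is `F` throughout (only
`f2FF` was ever observed); no separate nuclear allele class is introduced.
Viability is deliberately *not* encoded in the enumeration: hybrid × hybrid
pairs have enumerable offspring, and their observed sterility lives in the
simulator parameters where it belongs.

## Pedigrees and the census

`parse_family_table()` reads the family-table dialect (TSV; one row per
family; offspring `;`-separated with an optional `F1:`/`F2:` generation
prefix; square brackets record box-mates and are ignored for counting;
`---` is an empty family). Individuals are deduplicated by genotype plus
overlapping numeric alias sets — repeated tail-tip sampling gives one worm
several numbers, so `aAF96` ≡ `aAF96/103`. Mentions sharing a number across
*different* genotypes (the table contains `aAA96` and `aAF96/103`, and
`aAA141` next to `aAF86/141`) are kept distinct and flagged; `strict = TRUE`
upgrades the flag to an integrity error. `hybrid_census()` counts distinct
hybrid offspring by class and by the cross type of their family of birth.
On the packaged transcription it reports 26 `aAF` (18 from interspecific
families, 8 from backcrosses) and 4 `fFA` (all from `aAF` × `fFF`
backcrosses, none in interspecific F1) — the headline asymmetry. Pure
`aAA`/`fFF` totals from the table are *not* comparable to whole-colony
counts, because the table records only close relatives of hybrids.
`generation_labels()` assigns `P` to founders and `F(1+max(parent gen))`
otherwise, with an override map for the study's convention of relabelling
one pure-species F1 couple as parental.

## The simulator

`simulate_pair()` models one pair for `weeks` weeks. Per worm-week, cocoon
counts are Poisson; each cocoon is sterile with a per-class probability;
viable cocoons yield a zero-truncated Poisson number of hatchlings; each
hatchling is drawn through the gamete model, cross-fertilized with
probability `h_a`/`h_f` keyed by the ovum's clade. Distributional forms are
a modelling choice — the source reports only means ± SE — and we interpret
`hatchlings_per_viable_cocoon` as the *mean* of the truncated distribution
(the rate is solved numerically), so calibration from reported means is
direct.

Default rates transcribe the measured three-arm design: cocoons per worm
per week 2.9 / 3.4 / 4.3 and sterile-cocoon fractions 0.07 / 0.48 / 0.77
for Ea+Ea, Ef+Ef and Ea+Ef; hatchling means per viable cocoon follow from
those same rows (e.g. 5.6/(2.9 × 0.93) ≈ 2.08 for Ea+Ea). These are
calibrations, not estimates. Backcross and hybrid-hybrid arms were not
measured: backcrosses reuse the Ef+Ef rates and hybrid-hybrid pairs the
interspecific cocoon rate — placeholders, clearly overridable. The observed
asymmetry enters as `fFA_F1_viability = 0` (no `fFA` among interspecific
F1) and `hybrid_pair_fertility = 0` (hybrid pairs laid plenty of cocoons
but hatched none); both observations are censored ("so far"), hence
parameters rather than rules. The reported sterile-cocoon percentage is the
per-cocoon sterility event itself, so its mean estimates the calibrated
parameter; embryo loss through the viability switch reduces hatch counts
instead. `h_a` and `h_f` default to 0.3: the real rates are unquantified,
and 0.3 is of the order suggested by the hybrid fractions in the recorded
F1 families — a placeholder, flagged as such. A run is driven by a single
global RNG stream; `sim_params(seed = )` makes `simulate_experiment()`
exactly reproducible.

`estimate_hybridization_rate()` inverts the model per maternal line: among
an interspecific pair's a-line offspring, `aAF` are crosses and `aAA`
facilitated selfs, so `h_hat = n_aAF / (n_aAF + n_aAA)` is the binomial
MLE, with a Clopper–Pearson 95% interval. The analogous f-line estimate is
biased downward when `fFA` survive with probability `v < 1`; passing
`viability = v` applies the correction `h = p / (v + p(1 - v))` (off by
default).

## What the generator emulates — and what it does not

`generate_reference_panel()` plants the study's structure exactly: 9
polymorphic / 7 diagnostic 28S columns (the two non-diagnostic columns
segregate within a species; the source does not say which species carries
them, so we plant one in each), COI clades at divergences 0.150 (a–f) and
0.114 (f–f2) on disjoint site sets, and optional within-clade noise.
With the default 412 bp 28S alignment the 7 fixed differences reproduce the
reported 0.017 between-species 28S distance. Defaults use 600 bp COI,
6 references per clade. `simulate_individual_sequences()` writes hybrids'
28S as the IUPAC consensus of their two alleles.

Passing round-trip tests on this material shows the detectors invert the
generator — it does not show robustness to real-data pathologies the
generator omits: alignment error, indels, heteroplasmy, chromatogram noise
miscalling single peaks, paralogous rRNA copies, or COI numts. Sequences
are treated as already aligned; no aligner is bundled.

## Numerical and design notes

* Strict `<` at the clustering threshold; ties in cluster numbering broken
  by lexicographic id; identical sequences always co-cluster.
* p-distance with no comparable columns is an error (undefined), not 0.
* The zero-truncated Poisson sampler inverts the CDF on `(P(0), 1]`, exact
  for all rates, with a guard for means within 1e-9 of 1.
* Problem sizes in the test suite (hundreds of exhaustively enumerated
  scenario cases, 200-replicate calibration runs, 500-replicate coverage
  studies at n = 1000) were chosen to make Monte-Carlo error small relative
  to the tolerances being checked.
* The command-line dispatcher (`inst/scripts/hybridworms`) is a thin layer
  over exported functions; exit codes are 0 (ok), 2 (input error),
  3 (integrity error).

## Known limitations

Scenario lists are unweighted (no probabilistic paternity; the source
defers that to microsatellites). The pedigree parser does not infer which
box-mates mated. Seasonal reproduction dynamics and environmental modifiers
of hybridization are out of scope. The `aAA96`-vs-`aAF96/103` number
collision is flagged, not resolved — the underlying records do not say
whether one worm was re-genotyped or two worms shared a number.

## A short tour

```{r}
fx <- system.file("extdata", "table2_families.tsv", package = "hybridworms")
res <- run_census(fx)
res$census
res$consistency

explain_offspring(c(hybrid = "aAF", pure = "aAA"), "aAF")

refs <- generate_reference_panel(seq_gen_params(), seed = 1)
panel <- build_marker_panel(refs$s28_refs_a, refs$s28_refs_f)
panel

sim <- simulate_experiment(table1_design(), sim_params(seed = 1))
tidy(sim)
glance(estimate_hybridization_rate(
  dplyr::filter(sim$offspring, arm == "Ea+Ef"), line = "a"
))
```
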