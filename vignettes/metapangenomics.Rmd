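---
title: "Coverage-based metapangenomics: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based metapangenomics: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapanr)
library(dplyr)
```

metapanr infers the environmental distribution of closely related bacterial
genomes — and of their individual genes and metabolic capabilities — from
metagenomic read-recruitment coverage. The motivating setting is the human
oral microbiome, where related species of a genus partition the mouth's
habitats (dental plaque, tongue dorsum, buccal mucosa, ...) into distinct
niches, but every step is generic: any collection of reference genomes, any
set of per-sample per-nucleotide depth profiles, any habitat labelling.

This vignette explains the statistical model behind each stage, the
thresholds and their units, the behaviour of the synthetic-data generator
the tests rely on, and the places where the design was genuinely open and a
choice had to be made.

## The reference set: QC and dereplication

Public genome collections over-represent some clades enormously, and
near-identical genomes make read recruitment ambiguous (a read maps equally
well to each copy). The preparation stage therefore:

* drops contigs shorter than 300 nt and masks every non-canonical
  nucleotide letter to `N` (`sanitize_genome()`);
* keeps genomes with estimated completeness >= 90% (inclusive) and
  contamination < 5% (strict) (`qc_filter()`);
* dereplicates at 98% average nucleotide identity: no two retained genomes
  may exceed 98% ANI (`dereplicate()`).

The dereplication algorithm is a greedy sweep in dRep style: candidates are
ranked by `completeness - 5 * contamination` (ties by genome id) and
accepted unless their ANI with an already-accepted genome exceeds the
threshold. ANI from alignment-based estimators is directional; we
symmetrize by taking the maximum of the two directions, which is the
conservative choice (it merges more). Both the scoring rule and the
symmetrization are our decisions — the upstream convention is not
standardized — and both are isolated behind function arguments.

## Genome detection and the Q2Q3 abundance statistic

A genome is **detected** in a sample when at least 50% of its nucleotide
positions have depth >= 1X (both bounds inclusive). Breadth, not mean
depth, drives detection because a handful of conserved or mobile segments
can attract reads from unrelated community members and inflate the mean
arbitrarily while covering almost none of the genome.

The abundance statistic is built the same defensive way. Positions are
ranked by depth and the mean is taken over the middle half — 0-based sorted
ranks `floor(n/4) .. ceiling(3n/4) - 1`, the **Q2Q3 interquartile mean**.
The top quarter of positions is excluded entirely, so multiplying the
depths of up to `floor(n/4) - 1` positions by any factor leaves the
statistic unchanged — an exact robustness guarantee the test-suite asserts,
not an asymptotic one. We use the rank-based slice rather than
value-interpolated quartiles because it is unambiguous under heavy ties
(integer depths are extremely tied) and degrades gracefully: for n < 4 the
slice is the whole vector and the statistic is the plain mean.

Relative abundance of genome g in sample s is `q2q3(g, s)` divided by the
sum of `q2q3` over **all** reference genomes in s — not only detected ones;
undetected genomes typically contribute ~0 but are kept in the denominator
so abundances always sum to exactly 1 over the reference set. Samples in
which no genome is detected are excluded outright rather than reported as
zeros. Species-level abundance is the sum over member genomes.
For display, species and samples-within-site are ordered by average-linkage
hierarchical clustering of Bray-Curtis distances (`vegan::vegdist`); a pair
of all-zero profiles has an undefined Bray-Curtis distance and is assigned 0
by convention, with a message.

## Gene-level detection

A gene is detected in a sample when >= 90% of its nucleotides have >= 1X
coverage. The deliberate 10% slack tolerates small sequence differences
between the reference isolate and the environmental population; demanding
100% would erase detection for genes with a single diverged segment.
Detection maps are computed over the `samples_per_site` samples with the
greatest genome-wide median depth per site (default 30; sites with fewer
samples are clamped, ties broken by sample id), genes are ordered by
detection frequency and samples by the proportion of genes they detect.
Core/accessory labels come from the gene-cluster matrix: a cluster is core
for a species when present in >= `core_fraction` of its genomes, default
1.0 — the upstream convention is unpublished, so the threshold is exposed.

## Metabolic modules and enrichment

A module definition is an ordered list of enzymatic steps, each satisfiable
by alternative KO accessions (`"K1|K2"`). Completeness is the fraction of
satisfied steps; a module is complete at >= 0.75, and the generator plants
a genome carrying exactly 3 of a 4-step module so the boundary is pinned in
the tests. The full KEGG boolean grammar (nested AND/OR, minus terms) is
out of scope; flat steps with alternatives cover the analyses here.

Enrichment of a binary trait (function presence, module completeness)
across genome groups uses the Rao score statistic of a logistic regression
of the trait on group membership. For the saturated group model this equals
the Pearson chi-squared statistic (no continuity correction) on the
groups-by-presence table, so the implementation computes the closed form
and needs no iterative fitting; p-values use the chi-squared reference with
(groups - 1) degrees of freedom, and q-values are Benjamini-Hochberg within
each call. Traits present everywhere or nowhere are degenerate by
definition (score 0, p 1) rather than an error, because annotation tables
routinely contain universal housekeeping functions.

## The reciprocal-dominance permutation test

Among close relatives one often sees mutual exclusion: in any given sample
only one of a small set of taxa is at high abundance. To quantify this, the
focal taxa's abundances are renormalized within each sample to shares of
their combined total, a taxon is *dominant* when its share is >= `tau`, and
the statistic `T` counts samples with two or more simultaneously dominant
taxa. The null hypothesis — taxa occupy samples independently — is
simulated by permuting each taxon's abundance vector independently across
samples, which preserves every marginal distribution and destroys only the
cross-taxon coupling. The one-sided p-value is
`(1 + #{T_perm <= T_obs}) / (1 + B)`, never exactly zero.

Two design points deserve a careful record:

* **`tau` defaults to 0.3, not 0.5.** With shares renormalized to sum to 1,
  two taxa can both reach a 0.5 share only on an exact tie, so a 0.5
  threshold makes `T` identically zero under data and null alike and the
  test powerless by construction. A 30% share of the focal group's total is
  a demanding notion of "high abundance" for three or more taxa while
  keeping co-dominance observable. `tau`, the permutation count, the
  renormalization and the tie handling are all arguments.
* **Tie-breaking.** `T` is a coarse integer; with tens of samples the null
  distribution puts ~10% mass on single values, and the add-one Monte-Carlo
  p-value of a heavily tied statistic is conservative (realized size ~0.026
  at nominal 0.05 in our null simulations). The permutation ordering
  therefore refines `T` lexicographically with a continuous severity
  measure — the summed second-largest within-sample share, smaller meaning
  more reciprocal — which makes ties measure-zero and the null p close to
  uniform, while the reported statistic remains the interpretable count.
  `tie_break = "none"` restores the raw count ordering.

The 95% CI on the p-value is the normal approximation to the binomial
permutation count, clipped to `[1/(B+1), 1]`. The permutation stream is
anchored to sorted sample ids, so a seeded result is invariant to input row
order.

## The synthetic-data generator

Real inputs to this kind of study — reference assemblies and hundreds of
multi-site metagenomes — are far too large to ship, so the generator
produces miniature studies with planted, exactly known structure:

* **Catalog**: a few species, each a few genomes, one contig per genome,
  random nucleotide sequences, genes tiling >= 80% of each genome with
  short intergenic gaps (gap length set so the genic fraction is ~0.85,
  with a tail-filling gene so short genomes stay above the bound). Strand
  is uniform at random and affects nothing downstream.
* **Coverage**: per-nucleotide depths are independent negative binomials
  with mean `base_depth * multiplier` at a subgroup's preferred site(s) and
  `background_depth` elsewhere, variance `mu + dispersion * mu^2`. The
  defaults (10X preferred, 0.05X background, dispersion 0.5) put preferred
  breadth near 0.97 and background breadth near 0.05 — cleanly on either
  side of the 0.5 detection threshold. `dispersion = 0` short-circuits to
  the rounded mean so noise-free fixtures are exact. No per-position noise
  model is canonical for shotgun coverage; the negative binomial is the
  standard overdispersed choice and is cheap.
* **Spikes**: `spike_fraction` of every genome (capped at 0.24, i.e. under
  the quarter the Q2Q3 statistic provably ignores) is covered by segments
  whose mean is multiplied by `spike_multiplier`, placed at identical
  coordinates in all genomes to emulate cross-mapping mobile elements.
* **Annotations**: per-species core gene clusters, random accessory
  clusters, universal core functions, 50%-presence background functions,
  subgroup-exclusive planted functions, per-subgroup exclusive modules, and
  the 0.75-boundary module fixture.
* **QC/ANI**: near-duplicate genome pairs are planted above the 98% ANI
  threshold with a deterministic completeness handicap, so the
  dereplication ground truth is exact.

All randomness flows from one root seed through fixed per-stage offsets, so
identical designs are bit-identical across runs and stages can be
regenerated independently. What the generator does **not** emulate:
read-level errors, mapping ambiguity between related genomes (competitive
mapping is upstream of this package), genome-length variation, strain
mixtures within a sample, or compositional correlations between taxa beyond
site preference. Tests passing on synthetic data therefore certify the
*computations* — thresholds, statistics, orderings, inversions of planted
truth — not the upstream mapping pipeline.

## Problem sizes and numerics

The shipped tests and the acceptance script run miniature studies: genomes
of 1-20 kb, 2-3 sites, tens of samples, permutation counts of 10^3-10^4,
and replicate counts of 50-500 chosen to keep Monte-Carlo standard errors
well inside the asserted bands. Tolerances are exact where the quantity is
exact (oracle equality for the interquartile mean, BH q-values,
checksummed pipeline reruns), 1e-9 for abundance conservation, and 3
Monte-Carlo standard errors for stochastic comparisons. Degenerate inputs
are contracts, not surprises: empty depth vectors, all-zero abundance
profiles, constant traits, missing coverage cells (all-zero by the
competitive-mapping convention) and sub-minimum sample counts each have a
stated behaviour tested explicitly.

## A short worked example

```{r example}
design <- sim_design(seed = 11)
sim <- simulate_metapangenome(design)
det <- detect_genomes(sim$profiles)
ab <- relative_abundance(sim$profiles, det)
species <- aggregate_species_abundance(ab, sim$catalog$genomes)

# specialists are detected at their preferred site and nowhere else
det |>
  inner_join(sim$catalog$truth$preferred_sites, by = c("genome_id", "site")) |>
  summarise(preferred_site_detection = mean(detected))

dom <- dominance_test(rename(species, taxon = species), tau = 0.3,
                      n_permutations = 999, seed = 11)
glance(dom)
```

## Known limitations

* The Q2Q3 slice convention at very small n (< 8) is one of several
  defensible readings of "interquartile"; divergence from other toolchains
  is possible there.
* Enrichment uses the score-test closed form; for tiny groups an exact
  (Fisher) test would be less approximate, but the chi-squared reference is
  what the field's tooling reports and what we match.
* The reciprocal-dominance construction (statistic, threshold, null
  scheme, permutation count) is a reconstruction of an informally described
  procedure; every ingredient is configurable and the printed result of the
  original analysis is not treated as a reference value.
* `run_pipeline()` orchestrates the function layer over a fixed on-disk
  layout; it is a convenience for reproducible runs, not a workflow engine.
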