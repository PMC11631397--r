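---
title: "Measuring the beneficial tail of the distribution of mutational effects: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the beneficial tail of the distribution of mutational effects: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
```

# The problem

Comparative mutagenesis screens ask whether two related species differ in
the resistance mutations available to them: how often resistance mutations
arise (mutational target size), how strong they are (effect size), and what
they cost in permissive conditions (pleiotropy). The concrete system this
package models is a UV-mutagenesis screen for copper and sulfite resistance
in *Saccharomyces cerevisiae* and *S. paradoxus*: mutagenized pools are
plated on stressor media, surviving colonies are arrayed on dense agar
plates across a concentration series, colony sizes are imaged, and a subset
of mutants is whole-genome sequenced to identify causal genes, aneuploidies
and copy-number variants.

`mutscreen` implements every analysis stage of such a screen as tested,
reusable functions, and ships a synthetic-data generator with planted ground
truth so the entire pipeline can be exercised and validated without any
external data. The `analysis/` scripts run the stages end to end on the
default synthetic screen.

# Resistance phenotyping

## Dose-response AUC

Each strain's colony size on a stressor plate is normalized to its own
no-stress colony (`relative size`), and resistance is the trapezoid-rule
area under relative size as a function of concentration (mM):
`dose_auc()`. For the copper assay's 18 concentrations spanning 0–0.8 mM,
a strain that grows fully at every concentration attains the assay ceiling
AUC of 0.8. Effect sizes are reported as `delta_auc()`, the strain's AUC
minus the mean AUC of the ancestor replicates on the same plate series.

Normalizing to the strain's own no-stress colony makes the dose series
dimensionless and cancels multiplicative position effects (a colony keeps
its plate position across replica-plated conditions), which is why edge
normalization is not applied to stress data.

## Physiological escapees

Some isolates form colonies on stressor plates without carrying a heritable
resistance mutation; re-phenotyped, they track the ancestor's decline.
`classify_escapee()` implements the operational rule: a strain is an
escapee unless its AUC *strictly exceeds* the ancestral mean plus `k = 3`
sample standard deviations. The boundary value is classed escapee, because
retention requires exceeding the threshold. Escapees are excluded from all
effect-size and cost comparisons downstream. With at least two ancestor
replicates the threshold is estimable; with zero measurement noise the
threshold collapses to the ancestral mean, and true mutants (whose planted
effect is positive) are still retained.

## Edge-layer normalization

Colonies near the edge of dense arrays grow larger. `layer_index()` groups
positions by their distance to the nearest plate edge — a 1536-format
(32 × 48) plate has 16 distinct layers — and `normalize_edges()` divides
each colony by its layer mean and rescales by the plate grand mean. The
operation equalizes layer means, preserves the grand mean, and is
idempotent to numerical tolerance (~1e-9). It is applied to
permissive-condition data only (see above). A fully missing layer is left
unscaled with a warning. Row/column normalization is deliberately not
offered: in the motivating design, row is confounded with strain group.

## Pleiotropic costs

`cost_profile()` reports growth relative to the ancestor mean in six
permissive media (MMD, MMG, CMD, CMG, YPD, YPG) after edge normalization;
1 means a colony the size of the ancestor's. Conditions with an undefined
ancestor mean are dropped with a warning and the mean cost is taken over
the remaining conditions.

## Group statistics

`compare_groups()` is a tie-corrected Kruskal–Wallis test (equivalent to a
rank-sum test for two groups) with optional Bonferroni multiplication
capped at 1; two groups with all values tied return statistic 0 and p = 1
by convention. `correlate()` provides Pearson and Spearman coefficients
with two-sided p-values and signals zero-variance input.

# Mutation rates and screen saturation

`estimate_rate()` computes phenotypic mutation rates as colonies recovered
per cell plated, with the Poisson standard deviation
`sqrt(colonies)/cells`. `compare_rates()` performs 2 × 2 chi-square tests
on (colonies, cells − colonies) — per concentration or pooled — with
optional Yates correction (off by default, matching the asymptotic test)
and Bonferroni adjustment, and also offers the paired t-test across
concentrations used for canavanine controls.

The canavanine arithmetic converts a phenotypic fold increase into genome
units: `induced_per_bp_rate()` multiplies the spontaneous per-bp rate
(default 6.44e-10 per bp per division, with the companion spontaneous
phenotypic rate 1.52e-7 per cell) by the observed fold increase, and
`genome_saturation()` yields mutations per genome (per-bp rate × genome
length, default 1.2e7 bp) and the per-site saturation of the screen
(per-bp rate × cells plated). The fold increase is taken at the highest
canavanine concentration; the analysis driver divides by the published
spontaneous phenotypic rate rather than by mock-plating counts, whose
expected colony numbers are too small to give a stable denominator. These
calculations ignore the biased mutation spectrum of UV, which is out of
scope by design.

# Site filtering and gene tallies

`filter_sites()` applies six ordered filters to a haploid
ancestor/derivative genotype matrix (VCF-style calls, GT:GQ):

1. ≥ 4 unique genotype calls across all strains → removed. Missing is not
   counted as a genotype call (missingness is rule 5's concern); a switch
   restores the stricter reading.
2. Lacking two different homozygous calls → removed (a haploid site is
   uninformative unless at least two distinct homozygous values appear).
3. Ancestral strain heterozygous → removed (haploid ancestors cannot be
   het; such sites are alignment artifacts).
4. Ancestral call shared by no other strain → removed.
5. If > 10% of an ancestor's derivatives lack a call, the site is removed
   *for that ancestor group only* — retention is therefore bookkept per
   group.
6. More than one distinct indel allele called across strains, or site
   genotype quality below 10 (minimum GQ over non-missing calls) →
   removed.

Removal counts attribute each site to the first failing rule in this
order; since rules 1–4 and 6 are pure site predicates and rule 5 is
group-scoped, the final retained set equals what simultaneous application
of all six predicates gives — a property the test suite verifies against an
independently coded brute-force oracle on randomized toy matrices.

A retained site is attributed to every derivative whose call differs from
its ancestor's (`strain_mutations()`), and `tally_disruptive()` counts
protein-altering classes (nonsynonymous, frameshift, nonsense, in-frame
indel, stop-lost) per gene; synonymous and intergenic changes are excluded.
`filter_svs()` applies the structural-variant analogue: drop imprecise and
low-quality calls, drop non-singletons, and among heterozygous singletons
keep only duplications (a duplication in a haploid may legitimately appear
heterozygous to a short-read caller).

# Enrichment nulls

`simulate_gene_null()` implements the "rain-down" null: each iteration
places the observed number of disruptive mutations onto the coding genome,
each mutation landing in a gene with probability proportional to its coding
length (mutations are independent, so two can hit one site; overlapping
genes are weighted independently). The empirical P-value of a gene is the
fraction of iterations with at least as many hits as observed, Bonferroni
corrected over the number of genes. The method default is 1,000,000
iterations; tests and the analysis drivers use 1e4–1e5 to stay fast, and
the empirical-P floor scales accordingly. When no iteration reaches the
observed count the result is reported as `1/(n_iterations + 1)` and flagged
as a bound — avoiding literal zero P-values.

`simulate_aneuploidy_null()` permutes the observed configuration (how many
aneuploid strains, how many aneuploid chromosomes each) uniformly over the
karyotype without replacement within a strain; chromosome sampling is
uniform rather than length-weighted, with weights available as a
sensitivity analysis. `cooccurrence_p()` assigns each of two aneuploidies
to independent uniform strain subsets of the observed marginal sizes and
counts double carriers; its null is hypergeometric, which the tests use as
an exact oracle while the implementation samples subsets literally.

# Karyotypes, CNVs and inverted repeats

`chromosome_copy_numbers()` averages 1-kb window depth per chromosome over
non-excluded windows (the rDNA cluster is excluded by default in the
generator), normalizes to the least-covered chromosome, and rounds to the
nearest integer (ties away from zero) under a min = 1 assumption, plus a
second estimate under min = 2. Relative depths more than 0.35 from the
nearest integer (e.g. 1.35–1.65) are flagged anomalous rather than forced.
`detect_diploidization()` calls whole-genome doubling when more than one
chromosome fits the doubled grid strictly better than the haploid grid —
one defensible formalization of "coverage consistent with the diploid
estimates", which has no published numeric tolerance.

`locus_copy_number()` divides a region's mean window depth by the
genome-wide median of non-excluded windows (robust to the focal CNV
itself) and exposes the per-window ratio profile so stepwise CNV
boundaries are visible. `scan_partial_events()` flags candidate partial
chromosome gains/losses via a sliding mean-shift boundary scan, mirroring
manual review rather than replacing it.

`find_inverted_repeats()` reports all maximal substring pairs whose right
member is the reverse complement of the left, with arm length ≥ `min_len`
(default 10 bp, the scale of ODIRA-style flanking repeats) and spacer
≤ `max_spacer`. Maximal means not extendable inward or outward while
keeping complementarity and non-overlapping arms. Palindromes (arms
abutting, spacer 0) are reported once and flagged. The scan walks
anti-diagonals of the implicit self-comparison matrix; tests verify exact
agreement with an independent string-matching oracle on random kilobase
sequences. Non-ACGT characters never match and produce a warning.

# The synthetic world

`screen_scenario()` fixes the generator's stated world; its defaults are
the copper arm of the motivating screen:

* 378 mutants per ancestor group + 6 controls (2 ancestor replicates, 2
  resistant reference strains, 2 mock-mutagenesis isolates) on a
  384-format plate;
* 18 concentrations spanning 0–0.8 mM;
* exponentially distributed planted effect sizes (theory expects the
  beneficial tail to be exponential) with mean 0.1 ΔAUC, truncated at the
  assay ceiling;
* escapee fraction 0.244 (the screen retained 75.6% of copper isolates);
* multiplicative lognormal measurement noise with CV 0.10 — colony areas
  are positive and right-skewed; 10% is a realistic imaging CV and was
  fixed once, before any test was run;
* flat edge bias by default (the within-plate spatial structure of real
  edge effects is unpublished; layer-constant bias is the stated
  assumption).

The dose-response functional form is not published, so the generator uses a
logistic decline of relative size with concentration; the inflection is
solved by root-finding (tolerance 1e-12) so that each mutant's trapezoid
AUC on the assay grid equals the ancestor AUC plus its planted ΔAUC. This
makes noise-free truth recovery exact to root tolerance and keeps ΔAUC the
single effect-size dial. Planted pleiotropic cost follows
`1 − 0.5 × ΔAUC`, encoding the negative effect-size/cost relationship the
real screen observed; the slope is a stated-world constant, not a fitted
value.

The genotype generator plants exactly one disruptive causal mutation per
strain plus Poisson-distributed passengers, with artifact channels
(ancestral-het sites, missing calls, spurious multi-allelic sites) injected
at stated rates; with artifact rates zero, every planted site survives the
six filters — the round-trip identity the tests assert. The coverage
generator scales expected window depth by chromosome copy number and focal
CNV copies, inflates the rDNA interval to exercise exclusion, and draws
Poisson counts (negative binomial optionally). Plating counts are Poisson
with mean rate × cells.

What a green test does *not* establish: the generator does not model UV
mutation spectra, raw reads or images, spatially autocorrelated plate
artifacts, or partially penetrant escapees; real screens also require the
manual curation steps (dried plate regions, failed transfers) that the
missing-data policy only approximates.

# Numerical choices and degenerate inputs

* Trapezoid AUC requires ≥ 2 non-missing points; strains missing more than
  half their concentrations are dropped (configurable).
* Technical replicates of a strain are averaged before analysis.
* Copy-number rounding is ties-away-from-zero (1.5× → 2), since ties
  toward even would call 2.5× as copy 2.
* Chi-square tests have no continuity correction by default; Yates is a
  flag.
* Empirical P-values are floored at `1/(n_iterations + 1)` and flagged as
  bounds.
* All stochastic stages take explicit integer seeds; multi-stream runs
  derive child seeds with `derive_seed()` (kept below 2^31), and identical
  seeds give bit-identical outputs.

# Known limitations

The scaled-down toy genome (16 chromosomes, ~1.6 Mb) keeps
simulation-heavy tests fast; chromosome count and gene density are
realistic but absolute saturation numbers are not comparable to a 12 Mb
genome. The diploidization rule and the anomalous-coverage band are
defensible formalizations of qualitative published criteria, not the
original authors' thresholds. The six-filter interpretation questions
(whether missing counts as a genotype call in rule 1; the exact reading of
rule 6's indel clause) are resolved as documented above and are
config-switchable.
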