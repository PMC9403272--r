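---
title: "Predictive phenotype profiling of SCFA production in gut microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive phenotype profiling of SCFA production}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SCFAprofiler)
```

# The problem and the model

Short-chain fatty acids (SCFAs) — acetate, propionate, butyrate, formate —
and the two lactate enantiomers are the principal fermentation end products
of the human gut microbiota, with broad effects on host physiology.
Culturing individual gut species to measure what they produce is rarely
feasible, so SCFAprofiler predicts a community's *production potential*
from sequencing data in two steps:

1. **Genotype to phenotype.** Every reference genome is annotated for the
   presence of the functional roles (enzymes) participating in SCFA and
   lactate synthesis. A declarative rule set turns role presence into
   pathway-variant calls: a variant (e.g. butyrate P1, the acetyl-CoA
   route) is *complete* exactly when each of its role groups is satisfied
   by at least one alternative enzyme. Variant calls collapse to a binary
   producer/non-producer phenotype per product, collected in the Binary
   Phenotype Matrix (BPM).
2. **Phenotype to community index.** Community members (16S ASVs or WGS
   taxa) are mapped onto the reference genomes; each member inherits a
   Phenotype Index (PI), the fraction of its mapped genomes that are
   producers; and the Community Phenotype Index
   $\mathrm{CPI} = \sum_i A_i \, \mathrm{PI}_i$
   (abundance-weighted mean PI) estimates the fraction of community cells
   able to produce the compound. The associated prediction variance is
   $v = \sum_i A_i^2 \, \mathrm{PI}_i (1 - \mathrm{PI}_i)$,
   the exact variance of the cell-count estimator when each member's
   phenotype is an independent Bernoulli draw at its PI; we report
   $\sigma = \sqrt{v}$ as the error on the CPI scale and expose the raw
   sum as well.

## The rule grammar

A pathway definition is an AND over *role groups*; each group is an OR
over *alternatives* (non-orthologous gene displacements); an alternative
is one role or a co-required combination (e.g. the two-subunit
methylmalonyl-CoA mutase MutA2 + MutC). Segments shared by all variants
of a product — the universal crotonyl-CoA to butyryl-CoA step
(Bcd-EtfAB) and the terminal butyrate release group (But, CtfAB, or
Ptb + Buk) — are defined once and referenced, which both avoids
duplication and gives the WGS module a first-class "universal segment"
entity. The default configuration
(`inst/extdata/scfa_pathways.yaml`) encodes four butyrate routes
(acetyl-CoA, succinate, glutamate, lysine), three propionate routes
(succinate, lactate/acrylate, propanediol), and the acetate, formate and
L/D-lactate pathways, with a catalogue of 46 enzymes.

```{r}
ps <- loadPathwayDefinitions()
ps
callPathwayVariants(c("Thl", "Hbd", "Crt", "Bcd-EtfAB", "But"), ps)$butyrate
```

Three special cases are handled explicitly:

* **P3\*.** When the propanediol dehydratase group of propionate P3 is
  satisfied only by the B12-independent PduC2 + PduD2 pair, the call is
  decorated as `P3*`. The decoration is informational: it collapses to
  `P3` for phenotypes and producer summaries.
* **Relaxed propionate P1.** Some known propionate producers carry every
  P1 component except a recognizable succinate:propionyl-CoA
  transferase, suggesting an unidentified enzyme. The CoA-transferase
  group is therefore flagged `relaxable` in the config;
  `loadPathwayDefinitions(relaxed = TRUE)` waives it. Strict mode is the
  default.
* **MutB2** (accessory GTPase of the two-subunit mutase) is catalogued
  for annotation but never required.

Species counts in producer summaries include only taxonomically defined
species names; genomes with species `"undefined"` count as genomes but
not as species, since an unnamed species cannot be tallied.

# Phenotype variability within taxa

Within a species or genus, the producer fraction $p$ of each phenotype is
scored with the Gini impurity $s = 2p(1-p)$, which is zero exactly for
homogeneous groups and attains its maximum $0.5$ at an even
producer/non-producer split *for groups of any size*. The number of
variable phenotypes (NVP) counts phenotypes with $0 < p < 1$; the overall
phenotype variability score (OPVS) is the sum of the six scores, bounded
by 3. We deliberately use $2p(1-p)$ rather than the population variance
$p(1-p)$: only the former reaches the stated per-phenotype ceiling of 0.5
and keeps OPVS within $[0,3]$ consistently with reported group scores
(an 8-member group with five variable phenotypes can exceed the 1.25
ceiling that population variance would impose). Both alternatives remain
available through `variabilityScore(mode = )` for sensitivity analysis.
Ranking ties are broken alphabetically for reproducibility.

# 16S profiling choices

* **Copy-number renormalization.** Read fractions are divided by 16S
  rRNA gene copy numbers and renormalized, converting read fractions to
  cell fractions ($A'_i \propto A_i / c_i$). Unknown copy numbers
  default to 1 and are logged.
* **Mapping identity.** ASVs align semi-globally against each reference
  16S sequence: the ASV aligns end-to-end against a substring of the
  reference, because an amplicon is a fragment of the gene. Identity is
  matches over alignment length, with unit gap costs and `N` never
  matching; the end-to-end requirement on the query prevents degenerate
  short perfect overlaps from inflating identity. The default threshold
  of 90% corresponds roughly to family-level resolution. All hits at or
  above the threshold are retained, and PI averages phenotypes over all
  mapped genomes (per genome, not collapsed to species — the averaging
  set is the set of genomes the sequence cannot distinguish).
* **Coverage filter.** Sample coverage is the total abundance of mapped
  ASVs before renormalization; samples below 75% coverage are discarded
  (inclusive boundary: exactly 75% is retained). Retained samples'
  mapped abundances are renormalized to sum to 1 before CPI — required
  for the "fraction of cells" interpretation; the discarded unmapped
  fraction is assumed phenotypically exchangeable with the mapped part.

# WGS profiling choices

Taxon abundance profiles map to the BPM by walking the taxon's rank path
from its deepest defined rank upward; a taxon is mapped at the first
rank with reference matches, provided that rank is family or finer.
Non-mapped taxa are discarded and mapped abundances renormalized; CPI
and error then follow the 16S formulas exactly, so identical
abundance/PI inputs give identical results on either route.

Gene-count normalization uses trimmed-mean-of-M-values (TMM) factors
computed **from the universal single-copy core gene set only**, so
pathway signal cannot influence normalization; a config switch is
unnecessary because passing a joint core + pathway gene list as
`coreGenes` reproduces the joint behaviour. Defaults: M-trim 0.30,
A-trim 0.05 (the standard published values); reference sample = the one
whose core-gene CPM upper quartile is closest to the mean (configurable
to a fixed sample); genes with a zero count in either compared sample
are excluded (undefined log-ratio); weights are inverse approximate
variances computed on relative counts, which makes the factors exactly
invariant to multiplying a sample's counts by a constant. Factors are
rescaled to geometric mean 1.

Pathway abundance sums normalized gene abundances over roles *specific
to* one variant of a product; roles appearing in several variants or in
shared segments are excluded from variant signatures, and shared
segments (e.g. the universal butyrate segment) are reported as their own
entries — this prevents double counting across per-variant sums. Note
that a variant's summed abundance scales with the number of
variant-specific genes its carriers hold, so comparisons *across*
variants should divide by the expected per-carrier signature size.

# Diversity

Faith's phylogenetic diversity is the branch-length sum of the minimal
subtree spanning the observed leaves and the root (root branches
included, the standard convention). Weighted UniFrac is the normalized
form
$\sum_l b_l |p_A(l) - p_B(l)| \,/\, \sum_l b_l (p_A(l) + p_B(l))$,
bounded by 1 and hence comparable across datasets; the raw numerator is
available. Phenotype beta diversity (PBD) applies the metric to carrier
sub-communities (members with PI at or above the carrier threshold,
default 0.5 inclusive, renormalized), and relative PBD divides by the
whole-community distance per pair — the per-pair ratio is the primary
definition here, with the aggregate ratio obtainable by averaging the
matrices separately, since a per-pair ratio is undefined where the
whole-community distance is zero. CPI-versus-alpha-diversity summaries
bin samples into equal-width bins over the observed AD range (bin count
configurable) and report per-bin medians and quartiles.

# What the synthetic generators emulate

`fixtureSpec()` fixes every condition behind one seed. Defaults emulate
the reference-collection statistics the rule set targets: producer
prevalences follow the reference producer fractions (12.6% butyrate,
28.9% propionate, 86.8% acetate, 71.4% formate, 63.3% L-lactate, 45%
D-lactate); genomes are built *by the rules themselves* (one sampled
alternative per role group, optional extra variants, partial pathways
for some non-producers), which guarantees the intended BPM by
construction; 16S surrogates are 250 nt with i.i.d. substitutions
(2% per site species-from-family, 0.4% strain-from-species, independent
family roots), placing within-species identity above 97%, within-family
above 90% and across-family far below — so the 90% threshold behaves as
family-level, as intended. Compositions are Dirichlet; 16S copy numbers
are integers in $[1, 7]$ applied in the forward direction (read
fractions are copy-inflated, so the pipeline's correction must undo
them); WGS counts are multinomial draws over composition-weighted
single-copy gene content with 20 universal core genes.

```{r}
spec <- fixtureSpec(seed = 7, nSamples = 5)
ref <- generateReferenceCollection(spec)
asv <- generateAsvDataset(ref, spec)
res <- profile16S(asv$abundance, asv$sequences, ref$sequences, ref$bpm,
                  copies = asv$copies)
max(abs(cpi(res$profile) - asv$truth))
```

With the default family-level phenotype resolution, pipeline CPI equals
the generating producer fraction to machine precision; with
`phenotypeResolution = "strain"` (i.i.d. per-strain phenotype draws),
mapped sets become phenotypically heterogeneous and the reported
$3\sigma$ interval covers the deviation from truth in at least 99% of
samples.

What the generators do **not** emulate: realistic taxon-abundance
distributions of human cohorts, sequencing noise or chimeras, indels in
16S (substitution-only keeps identity arithmetic exact), incomplete
reference databases, or horizontal-transfer-shaped phylogenies. Passing
tests therefore demonstrate the correctness of the computations under
controlled conditions, not field accuracy on real cohorts.

# Problem sizes and numerical notes

The shipped tests run the rule engine over collections of up to ~1,200
genomes (encoding the reference producer-combination counts), 100-sample
communities of 36 genomes for end-to-end recovery, 100-seed round-trip
checks on 4-genome collections, and randomized trees of up to 5 leaves
against exhaustive branch enumeration — sizes chosen so the whole suite
exercises every path in well under a minute. Exact recovery is asserted
at 1e-9, oracle agreement at 1e-12. Degenerate inputs are defined
errors: empty genome collections, empty reference sequence sets,
zero-abundance samples in UniFrac, zero core-gene counts in TMM, and
producer fractions outside $[0, 1]$ all fail fast with named messages;
empty ASV sequences and missing copy numbers degrade gracefully
(unmapped with a warning, default 1 with a message).

# Known limitations

* Phenotype predictions are genomic potential, not expression: a
  complete pathway can be silent under given conditions, and
  cross-feeding (e.g. lactate to butyrate) is outside the model.
* PI averaging weights genomes equally; heavily sequenced species
  therefore dominate the index of a coarse mapping set.
* The rule content reconstructs the documented enzyme sets; minor
  auxiliary roles of the full annotation scheme may be absent, and the
  terminal butyrate transferase group is deliberately not extended
  beyond the named enzymes (the config is user-extensible).
* TMM assumes most core genes are not differentially abundant between
  samples; with fewer than ~10 usable core genes the trimmed mean
  becomes unstable.
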