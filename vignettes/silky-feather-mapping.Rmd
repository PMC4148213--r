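---
title: "Mapping a recessive trait to a single regulatory variant: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive trait to a single regulatory variant: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkymap)
```

`silkymap` re-implements, as tested and reusable code, the classical
positional-cloning chain for a fully penetrant recessive Mendelian trait:
segregation testing, two-point linkage, identical-by-descent (IBD)
haplotype-sharing fine mapping, causal-variant exclusion, pooled-sequencing
fixation scanning, and downstream expression statistics. This vignette is
the package's own account of the underlying models, the tunable parameters,
the synthetic-data generator, and the design choices made where the design
was genuinely open.

## Coordinates and genotype encoding

All positions are 1-based and inclusive: a span printed as
70,468,129–70,487,067 bp contains both endpoints and has length
`end − start + 1` = 18,939 bp, reported as 18.9 kb after rounding half-up to
one decimal. At kb precision the reported sizes are insensitive to the ±1
convention; the inclusive convention is the standard one for 1-based spans.
BED export converts to 0-based half-open (`start − 1`, `end`) and the
write/read round trip is exact.

Genotypes are stored unphased as 0 (hom-ref), 1 (het), 2 (hom-alt), `NA`
(missing). No phasing is ever needed: a recessive affected individual is
autozygous around the causal locus, so the shared haplotype is directly
readable from homozygous calls. Multi-allelic variant records are rejected
with an error rather than silently split, because every analysis in the
chain is biallelic.

Promoter positions use ATG-anchored numbering with the A of the initiator
codon as +1 and no position 0; `atg_from_offset()` / `offset_from_atg()`
convert between genomic and anchored coordinates for a plus-strand gene.
Minus-strand genes are not handled (the target gene of the motivating study
reads in increasing genomic coordinate).

## Two-point linkage in an F2 intercross

The likelihood treats each F2 offspring as two independent F1 gametes with
frequencies `hB = HA = (1 − θ)/2` and `hA = HB = θ/2` (trait allele *h*
coupled with marker allele B in the founders, both sexes at the same θ).
A case requires trait genotype *h/h*; wild-type pools *H/H* and *H/h*; no
penetrance parameter enters the likelihood because the trait is fully
penetrant. The six (marker genotype × phenotype) class probabilities sum to
one and give a multinomial log-likelihood for the observed 3×2 count table.

`two_point_lod()` maximises over θ ∈ [0, 0.5] with a coarse 0.005 grid to
bracket the optimum, golden-section/parabolic refinement (`optimize`,
tolerance 1e-6) inside the bracket, and explicit evaluation of both
endpoints so boundary MLEs are exact; ties break toward smaller θ. The
estimator is validated in the test suite against an exhaustive 1e-4 grid
built from independent gamete-pair enumeration (1,000 random tables: θ̂
agrees to 1e-4, LOD to 1e-3) and recovers true θ ∈ {0.01, 0.05, 0.1, 0.2}
within two standard errors over 200 simulated crosses of 229 offspring.

`scan_markers()` is complete-case per marker, flags monomorphic or
all-missing markers as non-informative instead of failing, and by default
maximises over both coupling phases, which makes the LOD invariant to how
the input happens to label marker alleles. This is an F2-only likelihood:
the original analysis used a full-pedigree linkage program whose options are
not recoverable, and founder/F1 genotypes add no linkage information when
the lines are fixed, so the F2-only contract is the defensible equivalent.
Published per-marker LOD values depend on unavailable individual-level
genotypes and are therefore validated by the oracle-agreement and recovery
properties above, not by value.

## IBD fine mapping

`shared_homozygous_blocks()` returns maximal runs of consecutive markers at
which every case is homozygous for one common allele. Missing cells are
*compatible* by default — they do not break a run but contribute no support —
because real genotype panels show missing calls inside accepted haplotypes;
a `"breaking"` policy is available for strict analyses. One heterozygous
case breaks sharing at that marker; `max_case_exceptions` (default 0) makes
any tolerated exception explicit rather than silent, since published
analyses have occasionally tolerated a single discordant bird. The finder
is exhaustively equivalent to a brute-force window oracle (10,000 random
case matrices up to 10 × 20 in the acceptance suite).

`exclude_control_matches()` marks a block excluded iff some control is
homozygous for the shared allele at every non-missing marker of the block
(and typed at at least one): a control must match the whole block, not a
sub-block, mirroring how a proximal shared block is discarded when a
wild-type bird carries it. `narrow_boundaries()` then trims a surviving
block with additional case individuals: the innermost marker at which any
panel case is heterozygous or opposite-homozygous becomes the boundary, and
the candidate region starts 1 bp inside it (boundary-exclusive, the
70,460,738 → 70,460,739 convention). A side with no discordant marker stays
at the block endpoint and is flagged open. Block spans are reported
marker-to-marker (conservative): the true boundary lies between the boundary
marker and its neighbour, and the marker-based convention is the one used in
published coordinates.

## Variant exclusion and complete association

`variant_exclusion_filter()` encodes the three clauses a recessive causal
variant must satisfy — cases share one homozygous genotype, no control is
homozygous for it, every obligate heterozygote is heterozygous — and reports
the first violated clause with a witness individual. Missing calls are
evidence of nothing and never violate a clause; a variant with no case data
is excluded as `no_data`. No multiple-testing machinery is involved: this is
deterministic filtering, not hypothesis testing. `association_table()`
tabulates one variant by population and phenotype class with a strict
complete-association predicate over the non-missing calls.

## Pooled fixation scan

`site_vaf()` computes per-site variant allele frequency `alt/(alt+ref)` with
a coverage floor (default 4 reads) below which the frequency is undefined —
skipped, never counted as 0 or as a failure. `fixed_runs()` reports maximal
runs of defined sites with VAF at or above the fixation threshold. The
default threshold is 0.95 rather than 1.0: pooled sequencing carries
base-call and alignment error, and a strict "fixed at all detected SNPs"
reading is available by setting the threshold to 1. `max_gap_sites`
(default 0) controls how many failing defined sites may separate consecutive
passing sites within one run; `min_sites` (default 5) drops short runs.
Raising either the threshold or `min_sites` can only shrink output
(monotone filtering, property-tested).

## Expression statistics

`ddct_fold_change()` implements the Livak 2^−ΔΔCt estimator: technical
replicates average per gene per individual, ΔCt = Ct_target − Ct_reference,
ΔΔCt is the difference of group-mean ΔCt from the reference group, and the
reference group's fold is 1 by construction. Group comparisons are t-tests
on ΔCt, not on fold values: ΔCt is the approximately Gaussian scale, fold is
its exponential transform. Where the source protocol says "Student's
t-test" without specifying variance pooling, the package defaults to
Welch's unequal-variance test (the robust modern default) with
`var_equal = TRUE` available everywhere for the classical pooled test.
Degenerate zero-variance comparisons resolve to p = 1 when the means agree
and p = 0 when they differ rather than erroring.

`aei_test()` compares cDNA to gDNA major-allele fractions within genotype by
a *paired* t-test on individuals (the gDNA ratio of the same bird is the
natural control for per-assay signal bias) and compares cDNA fractions
between genotypes unpaired. The test is invariant to relabelling which
allele is "major" (fractions replaced by complements). No per-assay
pyrosequencing bias correction is applied by default; gDNA pairing already
absorbs individual-level bias.

`luciferase_fold()` averages technical-replicate firefly/Renilla ratios per
construct per biological repeat, normalises within repeat by the reference
(empty-vector) construct, and summarises over biological repeats; a repeat
lacking the reference is excluded with a warning. Activities are invariant
to rescaling a repeat's luminescence values by a positive constant. The
published fold activities (~46× and ~53× for the wild-type promoter
constructs versus ~8× and ~9× for the mutant) are wet-lab quantities; the
package validates the *estimator* by recovering a simulated 46-vs-8
contrast to within [4, 8]-fold over repeated seeds.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are the motivating study's design sizes, and its
remaining free parameters were chosen once as field-realistic values.

**F2 intercross** (`simulate_f2_cross()`): two inbred founder lines fixed
for alternative alleles at every marker and at the trait locus; F1 double
heterozygotes of known phase; each F2 formed from two independent gametes
generated as a Markov chain along the chromosome with Haldane adjacent
recombination fractions `θ = (1 − e^(−2d))/2` — no interference and no
sex-specific map, the minimal assumptions when neither is stated. Defaults:
229 offspring, 22 markers, 1 cM spacing, full penetrance, no genotyping
error or missingness (both available as per-call rates, with errors flipping
uniformly to another state). Physical positions are invented at 3 cM/Mb, a
typical macrochromosome recombination density for the chicken. A single
phase-known F1 pair stands in for the unstated F1 family structure, which
leaves the F2 genotype distribution unchanged.

**Breed panel** (`simulate_breed_panel()`): 76 cases and 95 controls typed
on 34 SNPs spanning a 160 kb region; every case carries two copies of one
ancestral haplotype over a planted ~57 kb interval, eroded at each edge by
an exponential draw in genetic distance (a standard descent-segment
approximation; explicit genealogy simulation is out of scope). The default
erosion mean of 0.005 cM (~1.7 kb at 3 cM/Mb) keeps the causal position
recoverable while still exercising the boundary logic; background genotypes
are Hardy–Weinberg draws from per-marker frequencies (uniform on
[0.2, 0.8] unless supplied). The innermost eroded boundaries define the
recoverable truth, returned alongside the data.

**Pooled counts** (`simulate_pool_counts()`): 500 sites placed uniformly at
random over a 182 kb region, coverage Poisson(20), alternate reads
binomial in the site frequency; a planted ~22 kb interval is fixed
(frequency 1). Background frequencies follow Beta(2, 5) — a low-to-moderate,
SFS-like spectrum for segregating sites, under which spurious fixation of
adjacent background sites is vanishingly rare.

**Expression tables** (`simulate_ct_table()`, `simulate_aei_table()`,
`simulate_luciferase_table()`): Gaussian replicate noise at stated SDs;
AEI tables pair gDNA and cDNA rows per individual; luciferase tables carry
three technical replicates × three biological repeats with multiplicative
per-well noise.

One global integer seed drives everything; `child_seed()` derives a
deterministic per-stream seed so sub-tasks stay independent and a pipeline
run is reproducible bit for bit.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium structure and demographic
history in the breed panels (background genotypes are independent across
markers), allele-frequency ascertainment of SNP arrays, locus-specific
recombination hotspots and crossover interference, sequencing error beyond
the binomial/Poisson read model, microsatellite mutation, and plate or
batch effects in the expression assays.

## Validation scale

The shipped test suite validates at sizes chosen to make the statistical
checks decisive while keeping a full run around a minute: 1,000 random
count tables against the 1e-4 grid oracle; 200 crosses per true θ for
estimator consistency; 10,000 random matrices for the block-finder oracle;
100 seeds each for panel, pool and variant-retention recovery; 1,000 null
seeds for the t-test level (accepted within [0.03, 0.07] at α = 0.05) and
200 seeds for AEI power. `scripts/acceptance.R` recomputes the same
quantities from scratch under a user-supplied seed.

## Known limitations

- The linkage module is two-point and F2-only: no multipoint likelihoods,
  interference models, sex-specific maps, X linkage, or QTL interval
  mapping.
- IBD detection is rule-based sharing, not a probabilistic autozygosity
  HMM; there is no phasing, imputation, or LD modelling.
- Microsatellites are handled only after biallelic recoding; the VCF reader
  consumes the GT field only.
- The pooled scan starts from per-site counts; read alignment and variant
  calling are upstream of the package.
- qPCR analysis assumes equal amplification efficiency (the 2^−ΔΔCt
  premise); efficiency-corrected models are out of scope.
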