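---
title: "Counting and comparing substitutions in clonal diploid lineages"
author: "ClonalSubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and comparing substitutions in clonal diploid lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The scientific problem

Obligately parthenogenetic (asexual) lineages are genetically isolated
from one another: once two clonal lineages are founded by different
genotypes, every subsequent substitution accumulates independently within
each lineage. This makes pairs of asexual lineages of one species a
natural test bed for the nearly neutral theory: slightly deleterious
nonsynonymous mutations behave as effectively neutral when the effective
population size is small, so the lineage with the smaller population is
expected to show the higher ratio of nonsynonymous to synonymous change
(dN/dS). Within-lineage comparisons are particularly attractive because
pairwise differences between genotypes of one lineage arose strictly
after the founding of that lineage, so they are free of the shared
ancestral polymorphism that contaminates between-lineage dN/dS.

ClonalSubs implements the within-lineage side of such a study for diploid
clonal genotypes characterized by whole-genome variant calls against a
common reference:

1. per-genotype substitution rates and synonymous/nonsynonymous counts,
2. all within-lineage pairwise substitution counts, split into coding
   (synonymous dS, nonsynonymous dN) and non-coding (dn-C) and sorted by
   zygosity (hom/het),
3. randomization tests comparing regression slopes (e.g. dN on dS)
   between two lineages, plus Mann-Whitney and t tests for per-genotype
   quantities,
4. tallies of genes carrying genotype-specific ("unique") nonsynonymous
   substitutions, and
5. molecular dating of lineages from per-generation mutation rates.

Because the genotype data of any particular study are external, the
package ships a synthetic clonal-lineage simulator that reproduces the
structure of such data end to end; every analysis stage is tested against
it and against brute-force oracles.

## Counting definitions

**Per-genotype substitution rate.** For a diploid genotype,
\[
N_{sub} = \frac{2\,\mathrm{hom} + \mathrm{het}}{\text{number of nucleotides examined}},
\]
where hom and het count sites with both, respectively one, allele
substituted relative to the reference. Variant calls are filtered at read
depth >= 5 (inclusive) and site quality > 20 (strict), single-nucleotide
biallelic records only; the callable-site denominator cannot be recovered
from a VCF and is therefore an explicit input carried in the lineage
table.

**S and N versus the reference.** Each coding variant site is classified
by substituting the alternate base into its reference codon (spliced
across CDS segments, strand-aware) and comparing amino acids under the
standard genetic code; stop gains and losses count as nonsynonymous. A
site counts once regardless of zygosity (an allele-weighted mode, hom
counting twice, is available as `countSN(..., alleleWeighted = TRUE)`
for sensitivity analysis).

**Pairwise counts.** For two genotypes of one lineage, a site contributes
when their unordered diploid allele pairs differ, a missing call meaning
homozygous reference. Differing non-coding sites increment dn-C; coding
sites increment dS or dN by classifying the non-shared alternate
allele(s). When the two genotypes carry *different* alternate alleles
whose classifications disagree, the site is counted as nonsynonymous (the
conservative choice; such sites are logged in `n_class_ties` and are rare
at realistic divergences). Each coding difference is also sorted, without
regard to direction, as homozygous (both genotypes homozygous at the
site, homozygous reference included) or heterozygous (either genotype
heterozygous). Sites compared defaults to the full reference length;
supply the callable intersection when masks are available.

**Unique nonsynonymous genes.** For each genotype, the number of genes
containing at least one nonsynonymous variant (site + alternate allele)
found in no other genotype of the set supplied; pass one lineage's
genotypes for the within-lineage convention.

## Inference layer

Slopes are conventional least-squares fits with an intercept
(through-origin fits behind a flag), with 95% confidence halfwidths from
the t distribution. Differences in slopes between two lineages are tested
by the pooled-resampling randomization procedure: the pairwise rows of
both lineages are pooled; group-sized row sets are drawn with
replacement; both slopes are refit and their difference recorded, 1999
times by convention. A difference is significant when the observed value
exceeds 95% of the resampled differences (absolute values by default; a
one-sided mode exists), and the reported Monte-Carlo p uses the add-one
estimator, so it is never zero. Where the within-lineage regression is
itself non-significant (typically dN_hom on dN_het), the same resampling
machinery compares group means instead
(`randomizationLocationTest()`). Mann-Whitney tests (exact for small
tie-free samples, normal approximation otherwise) with a Bonferroni
family of 3 (S, N, N/S) and a pooled-variance t test (Welch behind a
flag) cover the per-genotype contrasts.

### What the calibration shows — and a caveat inherited from the design

The resampling unit is the pairwise row, and the package keeps it that
way deliberately. But all pairs drawn from $n$ genotypes are not
independent: rows sharing a genotype have correlation near 0.5, because a
pair's counts are sums of the two genotypes' private mutation counts.
`calibrateSlopeTest()` measures the consequences on simulated studies
(two lineages of 6 genotypes, roughly 100 coding candidate mutations per
genotype):

* On genuinely independent rows the machinery holds its nominal level
  (the test suite verifies a type-I rate consistent with 5% on iid
  regression data).
* On all-pairs lineage data the same procedure rejects a true null in
  roughly 30% of studies at the nominal 5% level, at every mutation
  count and genotype-age spread we simulated. The pooled bootstrap null
  is too narrow because it treats correlated rows as exchangeable units.
* Under a real difference (nonsynonymous retention 0.5 vs 0.1) its power
  is low (on the order of 10%), because pooling two slope regimes mixes
  them in every resample: the null spread grows with the very difference
  being tested.

Alternative resampling units do not rescue both properties at once: a
genotype-level bootstrap distorts slopes through self-pairs, and an exact
genotype-label permutation is correctly calibrated but powerless against
slope differences for the same mixture reason. These are properties of
the procedure on all-pairs data, not implementation artifacts; the
package reproduces the procedure faithfully and reports
`calibrateSlopeTest()` results so users can judge significance claims on
data of their own shape. In practice this means observed "significant"
slope differences on all-pairs data should be read as descriptive rather
than as controlled 5%-level inferences.

## Lineage dating

Within-lineage mean pairwise substitution rates convert to lineage ages
as
\[
\text{age (years)} = \frac{\text{rate}}{\mu \times g \times d},
\]
with \(\mu\) the per-site per-generation mutation rate (defaults: nuclear
7.17e-9 from a long-term *Daphnia pulex* mutation-accumulation estimate;
mitochondrial 4.3e-8 via `mtAgeModel()`), \(g\) generations per year
(default 5) and \(d\) a branch divisor. The default \(d = 1\) reproduces
the published arithmetic, which reads pairwise divergence directly as
lineage age; \(d = 2\) is the population-genetics convention (divergence
accrues along two branches) and halves every age. Ages are reported
unrounded and rounded to the nearest year (half away from zero).

```{r dating}
library(ClonalSubs)
lineageAgeYears(c(1.82e-5, 1.34e-5), AgeModel())
lineageAgeYears(c(9.32e-5, 31.3e-5), mtAgeModel())
```

One bookkeeping note: when dating two lineages from rates estimated
against two different reference assemblies, ages follow the *rate* used,
not the label attached to it; the package therefore reports rate-age
pairs explicitly so that swapped labels in source tables cannot
silently change a conclusion.

## The synthetic-data generator

`generateReference()` draws contigs at a configurable GC content (default
0.40, a crustacean-like composition) and places non-overlapping
single-CDS genes on random strands, each an ATG start, stop-free body of
sense codons, and terminal stop. `simulateLineages()` then grows each
lineage as a star: every genotype descends independently from the
lineage founder (identical to the reference), reflecting founding by a
single genotype with no recombination.

Per genotype, candidate mutations are drawn
Poisson(\(\mu L t_i\)) and placed uniformly with a configurable
transition bias (default none). A candidate with a nonsynonymous
amino-acid effect is retained with probability `omega` — the simulator's
one-knob stand-in for purifying selection, giving expected pairwise
dN/dS equal to `omega` times the genome's nonsynonymous:synonymous
opportunity ratio (`siteOpportunities()`), with no fitness or population
dynamics. Retained mutations are homozygous with probability `pHom`
(default 0.1, making homozygous substitutions the clear minority, as in
diploid apomicts where loss of heterozygosity is slow); later mutations
overwrite earlier ones at the same site.

**Genotype-age heterogeneity.** Real clonal genotypes are sampled from
populations founded at different times, so their divergences from the
lineage founder differ several-fold — visible in real studies as wide
ranges of pairwise counts within one lineage. The generator models this
with `tSpread`: genotype \(i\)'s branch length is
\(t_i \sim U((1-s)t, (1+s)t)\) with \(s = 0.5\) by default, preserving
the lineage mean \(t\). Setting `tSpread = 0` recovers the equal-branch
star; with equal branches, per-genotype synonymous and nonsynonymous
counts are independent Poisson thinnings, so dN and dS are uncorrelated
across pairs and *no* dN-on-dS slope structure exists for the inference
layer to find — the heterogeneity is what gives the regressions their
meaning, in the simulator exactly as in real data.

**Default study shape.** The default `SimulationConfig()` mimics a
two-lineage design — "JPN1" with 7 genotypes and "JPN2" with 5, the older
lineage carrying more substitutions (2540 vs 1860 mean generations) and
stronger purifying selection (omega 0.2 vs 0.5, the nearly-neutral
expectation for the larger population) — on a deliberately scaled-down
genome: 2 x 50 kb with 40 genes of 300 bp, and a mutation rate of 2e-6
per site per generation, roughly a thousandfold the real per-generation
rate so that a 100 kb toy genome accumulates the several hundred
substitutions per genotype that a ~100 Mb genome accumulates at the real
rate. Calibration runs (`calibrationConfig()`) use one 40 kb contig, 6
genotypes per lineage and 4000 mean generations, i.e. about 320 candidate
mutations per genotype of which ~96 fall in coding sequence. All
simulations are deterministic given the config seed; the reference and
the lineages use decoupled streams derived from it.

What the generator does **not** emulate: within-lineage tree structure
(all genotypes are independent branches), gene conversion and
loss-of-heterozygosity dynamics (zygosity is an iid mixture), indels and
multi-nucleotide events, mutation-rate variation along the genome, introns
in generated genes (the readers and classifiers handle multi-segment CDS,
and split-codon handling is tested with hand-built gene models), and
linkage or selective interference. Passing tests therefore demonstrate
correctness of the counting and inference machinery on data of realistic
shape — not that real *Daphnia*-like data satisfy the star topology or
the thinning model of selection.

## Numerical and interface choices

* Coordinates are 0-based half-open in all user-facing site arguments and
  tables; GFF3 (1-based inclusive) and VCF (1-based) are converted at the
  boundary; `GRanges` inside containers follow Bioconductor convention.
* Depth filter inclusive (>= 5), quality filter strict (> 20), mirroring
  the usual phrasing of such filters.
* Genes whose CDS length is not a multiple of 3 are skipped with a
  warning on GFF3 read; internal stop codons warn but keep the gene.
* Multiallelic records, indels and non-diploid genotypes: the first two
  are dropped with a logged count; the third is an error.
* Two variants in one codon of one genotype are classified independently
  against the reference codon (co-occurrence is negligible at the
  divergences this package targets).
* Monte-Carlo p-values use the add-one estimator; resamples with
  degenerate (zero-variance) x are redrawn and counted.
* Ages round half away from zero; unrounded values are always returned.
* `runAll()` writes fixed-column TSVs with unit-bearing header comments
  and a deterministic JSON manifest (config snapshot, seed, input
  digests, per-stage row and filter-drop counts), so a rerun with the
  same config is byte-identical.

## Problem sizes used by the test suite

Unit and property tests run on 12-50 gene genomes of 3-20 kb with a few
hundred simulated mutations per genotype; oracle-equivalence checks
compare against brute-force reimplementations (full-sequence diploid
reconstruction, whole-CDS re-translation, exhaustive Mann-Whitney
enumeration) on 100 random genomes of up to ~5 kb; calibration runs 500
equal-omega studies and 50 unequal-omega studies at 499 resamples each.
These sizes were chosen so the full suite exercises every code path in a
few minutes while keeping Monte-Carlo standard errors small relative to
the tolerances asserted.

## Known limitations

* The randomization slope test inherits the pairwise pseudo-replication
  of its design (see the calibration section); treat its significance
  flags on all-pairs data as descriptive.
* dN/dS here is count-based with a thinning interpretation; no
  codon-model (maximum-likelihood omega) estimation is provided.
* Dating assumes a strict molecular clock, known generations per year,
  and neutral accumulation of the counted substitutions; no confidence
  intervals are attached.
* mtDNA is treated as just another contig; no haploid-specific handling.
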