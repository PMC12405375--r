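---
title: "Tracing unadapted donor genome through marker-assisted pseudo-backcrossing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing unadapted donor genome through marker-assisted pseudo-backcrossing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbctrace)
library(dplyr)
```

## The problem

Major-effect disease resistance genes (R-genes) for apple — fire blight
resistance from ornamental and wild *Malus*, scab and mildew resistance
from wild relatives — sit in genetic backgrounds with tiny fruit and poor
quality. Introgression breeding moves such a gene into elite germplasm by
repeated crossing: each generation, carriers of the R-gene (identified by
marker-assisted selection, MAS) are crossed to a *different* elite
cultivar (a pseudo-backcross, pBC, which avoids the inbreeding a single
recurrent parent would cause). Under Mendelian expectation every such
cross halves the donor genome fraction, but selection on the R-gene pins
the donor segment around it in place — linkage drag.

`pbctrace` implements the analysis side of such a program:

1. a forward simulator of gametes, crosses and multi-generation
   MAS-driven pseudo-backcross programs on a genetic map, with
   ground-truth ancestry labels;
2. the shared-haplotype tracing rules used to quantify how much
   "unadapted exotic" donor genome a descendant still carries, working
   only from phased SNP data (no truth labels);
3. pedigree quality control based on Mendelian error rates, with
   null-allele handling;
4. program-level summaries: breeding-funnel statistics, seed planning,
   expectation tables, and one-way ANOVA with compact-letter Tukey
   groups for phenotype comparisons.

Everything is tabular and tidyverse-shaped: maps, pedigrees, panels,
segments and reports are tibbles; fitted summaries have `tidy()` and
`glance()` methods.

## Coordinates and data model

All positions are genetic (centimorgans); there are no base-pair
coordinates anywhere, because segment accounting for introgressions is
done in cM on a consensus linkage map. SNP alleles are array-style
`A`/`B` with missing as a first-class state. A null allele is *not*
missing: it makes a true heterozygote read as homozygous for the visible
allele, which is why it corrupts Mendelian checks rather than simply
removing data.

A `phased_pop` couples a genetic map to per-individual, per-chromosome
pairs of haplotypes, plus optional simulator truth (ancestry segments
per homolog) and an observed-genotype view that noise injection and QC
adjustment operate on. The true haplotypes are never overwritten, so
inference can always be scored against truth.

## The synthetic data generator

The generator emulates the shape of a dense curated apple SNP array
dataset:

* `make_apple_map()`: 17 linkage groups, 80 cM each, first and last SNP
  pinned to the chromosome ends, interior SNPs uniform. The desk-scale
  default is 100 SNPs per chromosome (1,700 total, 1,360 cM); the
  full-array regime (about 10,000 SNPs) is a parameter change. Desk
  scale keeps the whole test suite in minutes while leaving ~0.8 cM
  between SNPs, an order of magnitude finer than the 16-SNP segment
  rule needs.
* `make_founders()`: a donor with a stated unadapted-exotic diploid
  fraction (0.75 for an MR5-like donor, 0.50 for an 'Evereste'-like
  donor), built by the admixed-parent construction: one homolog fully
  exotic, the other a copy of a domestic pseudo-parent with one exotic
  block per chromosome sized to hit the target exactly (in cM). The
  pseudo-parent is returned, because the tracing method *defines*
  unadapted haplotypes by subtracting identified domestic ancestors.
  Exotic and domestic allele-frequency profiles are independent
  Uniform(0,1) draws per SNP — the field's observation is only that
  exotic haplotypes share no extended runs with domestic material, and
  independent frequencies deliver exactly that without inventing an
  unsupported frequency model. Linkage disequilibrium within the
  domestic pool is deliberately not modelled; shared-by-state runs
  between unrelated domestic founders are therefore rarer than in real
  germplasm, and the non-admixed-parent filter is exercised mainly by
  true inheritance (its state-match branch is covered by constructed
  unit cases instead).
* R-gene loci (`rgene_locus()`) get diagnostic SNPs inside their window
  whose coupling allele `B` is fixed absent from the domestic pool and
  fixed present on exotic haplotypes — which is precisely what a real
  diagnostic marker is (an allele in coupling absent from e.g. 'Gala').
  The donor is kept heterozygous at these loci: the non-carrier homolog
  carries no exotic material on R-gene chromosomes, and its exotic
  content is redistributed across the other chromosomes so the diploid
  total stays exact.
* `inject_null_alleles()` corrupts the observed-genotype view at true
  heterozygotes with a per-SNP rate. No quantitative null-allele rate is
  published for this material; the working default of 0.02 is a
  sensitivity-testing placeholder, not an estimate.

## The meiosis and program simulator

Gametes follow the Haldane model: per chromosome, a Poisson crossover
count with mean cM/100, uniform breakpoints, no interference, no
obligate chiasma, no sex-specific map. None of these refinements is
specified for this material, and the Haldane choice makes every
expectation analytically checkable (allele conservation is exhaustively
tested; the halving law falls out of the model). Ancestry labels are
spliced at the same breakpoints as the alleles, so truth fractions are
exact, not SNP-approximated.

`run_pbc_series()` chains generations: current carriers × fresh,
unrelated domestic recurrent parents (new draws from the domestic
frequency profile each generation, mirroring the use of many distinct
elite cultivars), foreground MAS via `screen_population()`, optional
flowering attrition, optional background selection on the lowest donor
fraction. Background selection uses truth labels by default so that
tracer evaluation stays independent of selection. A generation with no
surviving carriers aborts with an explicit extinction error naming the
generation.

Flowering attrition models the vernalization-cycle clock of fast-track
greenhouse breeding: an individual flowers at cycle *k* with probability
*p~k~* conditional on not having flowered, and is discarded after four
cycles. The default schedule `r paste(default_flowering_probs(),
collapse = ", ")` is calibrated to the two anchors reported for this
kind of program — about 20% flowering within two cycles and about 32%
within four — by solving the two cumulative equations with equal
per-cycle hazards within each phase.

## The tracing core

The analysis that motivates the package is genotype-only: given phased
SNP data for a donor, its identified domestic ancestors, descendants and
their non-admixed (elite) parents, quantify the residual unadapted donor
genome in each descendant.

**Shared segments.** `find_shared_segments()` finds maximal runs of
matching informative SNPs between two haplotypes. A mismatching
informative SNP breaks a run; SNPs missing on either side neither break
the run nor count toward its SNP total; runs start and stop at shared
SNPs (or chromosome ends). Segment length is measured from the first to
the last shared SNP (closed, in cM) — boundaries are anchored at SNPs,
so each boundary is conservative by at most one inter-SNP interval
relative to the (unknowable) recombination breakpoint. The caller is
verified against an independently written quadratic oracle on hundreds
of random instances.

**Subtraction.** `define_unadapted_haplotypes()` labels donor intervals
that share a segment of at least `min_snps` SNPs with any identified
domestic ancestor as domestic; the complement is unadapted. With no
ancestors the whole donor genome is unadapted — the analysis is then the
older convention in which the entire donor counts as exotic.

**Retention rules.** A donor-descendant shared segment is retained if it
has at least 16 informative shared SNPs ("more than 15") and is not
present in the descendant's non-admixed parent. A segment the parent
also carries survives only through the extended-region exception: walked
outward SNP-by-SNP, the descendant's haplotype must keep matching the
donor strictly further than it matches the parent on at least one side.
The published rule does not quantify "extended region"; we implement
strict extension by at least one informative SNP (configurable), and
reports flag every segment retained this way, because the exception is
the rule's most discretionary part. Whether the 15-SNP threshold counts
missing-spanned sites is also not stated; we count informative shared
SNPs only (`n_missing_spanned` is reported separately) — the stricter
reading.

**Accounting.** Retained segments are merged per descendant homolog
before cM accounting (no double counting when two donor homologs match
the same region), and the unadapted percentage is total cM over twice
the map length. Segments overlapping an R-gene window are labelled
R-gene-linked; `rgene_only_classifier()` reproduces the
end-of-program question "does this selection carry anything exotic
*besides* the R-gene block?".

**Phase corruption.** Null alleles put wrong alleles on homologs, which
phased comparison sees as mismatches. For corrupted data
`trace_unadapted(genotype_mode = TRUE)` compares the donor haplotype to
the descendant's *unphased* genotype (a site matches when the donor
allele is among the observed alleles), at the cost of not attributing
segments to homologs. With a 2% null-allele rate and duo-based call
adjustment, recall of truth segments degrades by about two points in our
tests — within the five-point robustness budget the design aims for.

## Pedigree QC

Parent-offspring relationships are screened by opposing-homozygote
counts over jointly typed SNPs (`mendelian_error_rate()`; threshold
0.5%, configurable — the method's sources quote no universal number).
`adjust_null_allele_calls()` resolves recurring conflicts: the
conservative default sets both sides of a conflict to missing; the
`recode` mode turns a parent call replicated across at least two
independent offspring into heterozygous-with-null. Both modes are
provided because the published procedure adjusted calls after manual
cluster-plot inspection without stating the recode rule; adjustment is
proven (by property test) never to raise a true duo's error rate.
`genomewide_sharing_fraction()` gives the haplotype-sharing screen for
more distant relatives: about 100% for duplicates, 50% for
parent-offspring, 25% for grandparent-grandchild.

## Expectations, funnels, phenotypes

`expected_unadapted_fraction(donor_pct, n_meioses)` is the halving law
with one-decimal output. The meiosis count is always explicit because
generation labels are ambiguous: the published expectations pair "pBC'4
of a 50% donor" with 3.1% (4 meioses) and "pBC'5 of a 75% donor" with
2.3% (5 meioses), while counting the F1 as the first meiosis would give
one more halving in each chain (1.6% and 1.2%). The calculator does not
decide which chain a label implies; callers state meioses.

`funnel_statistics()` derives ratios from raw cross-record counts
(never stored): fruits per pollinated flower, seeds per fruit, location
shares, and per-generation averages computed over generations with a
nonzero count of that metric at that location — the one convention that
reproduces the published per-generation averages (e.g. 96 crosses over
5 active generations = 19.2). Packaged fixtures
`fbe_cross_records()`/`fbmr5_cross_records()` carry the published
per-generation counts of the two fire blight introgression series.
`plan_seed_requirement()` inverts the funnel: with about 65% of sown
seeds reaching MAS, 50% carrying the gene and 20% flowering by the
second vernalization, 30-40 flowering carriers require roughly 600-800
seeds per generation.

`anova_tukey_letters()` is the phenotype comparison used across
generations (relative lesion length from `relative_lesion_length()`,
fruit weights): one-way ANOVA, Tukey HSD on all pairs, and a
hand-implemented insert-and-absorb compact letter display (groups
sharing a letter are not significantly different). The letter algorithm
is property-tested against the direct pairwise decisions on a thousand
random instances.

## What the tests do and do not show

The simulator is the package's own test bed, and its defaults *are* the
study conditions: donor fractions 0.75/0.50, 17 x 80 cM map,
heterozygous R-gene loci, four-cycle flowering attrition. Passing tests
show that the tracing rules recover truth segments with >= 0.95
precision and recall on noise-free simulated data, that MAS segregation
and the halving law behave exactly as Mendelian theory predicts, and
that the funnel arithmetic reproduces the published tables. They do not
show performance on real array data, where linkage disequilibrium,
genotyping-cluster artifacts, residual phasing errors and
shared-by-state matches to unrelated cultivars all occur; the observed
cohort means of the real program (on the order of 1.5-4% at four to
five meioses) can only be bracketed, not reproduced, at desk scale. Our
simulated five-meiosis MAS cohorts land in the same low-single-digit
regime, above the 2.34% neutral floor — the direction and rough size of
linkage drag, not its published value.

## Numerical choices

* `min_snps = 16` ("greater than 15 SNPs"), boundary-tested at 15/16.
* Segment bounds closed at shared SNPs; chromosome-end segments stop at
  the terminal mapped SNP.
* Interval bookkeeping merges overlaps with a 1e-9 cM tolerance;
  positions are written to 4 decimals so file round-trips are
  byte-stable.
* Map feasibility: a partial exotic block must exceed the widest
  inter-SNP gap on every chromosome, otherwise the requested donor
  fraction is refused rather than silently approximated.
* All randomness flows from explicit integer seeds; a saved
  configuration plus seed reproduces a run bit-identically.

## A worked run

```{r demo, eval = FALSE}
demo <- run_lift_demo("mr5", n_generations = 5, seed = 42)
demo$summary          # per-generation traced means vs halving expectation
demo$class_counts     # how many selections carry only the R-gene block
plot_generation_unadapted(demo$summary)
```

The README shows the printed output of this run and how
`scripts/acceptance.R` recomputes the headline numbers.
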