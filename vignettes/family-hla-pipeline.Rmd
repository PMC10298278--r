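---
title: "Family-based HLA population genetics with hlafam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based HLA population genetics with hlafam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafam)
```

## The analysis

`hlafam` implements the classical family-based workflow for HLA
population genetics. The input is a set of nuclear families (two
parents, one or more children) genotyped, unphased, at the five
classical loci HLA-A, -C, -B, -DRB1 and -DQB1. The analysis proceeds
in stages:

1. **Segregation phasing.** Each parent's two haplotypes are deduced
   from the Mendelian transmission pattern in the children. Only
   families whose four founder haplotypes are determined with
   certainty contribute to any statistic.
2. **Direct counting.** Allele and haplotype frequencies are counts
   over founder chromosomes (4 per family; 2n = 400 for a 100-family
   cohort). Children never enter frequency estimation: parents are
   assumed unrelated, so the founder chromosomes are the independent
   sampling units.
3. **Per-locus tests.** A Hardy–Weinberg exact test (Monte Carlo
   permutation) and the Ewens–Watterson homozygosity test of
   neutrality.
4. **Linkage disequilibrium.** Haplotype-level D, D′ and χ², the
   multiallelic summary Wn, and conditional asymmetric LD (ALD) in
   both directions for every locus pair.
5. **Population comparison.** Nei standard genetic distances between
   allele-frequency tables, neighbor-joining dendrograms with
   parametric bootstrap supports, and correspondence analysis.

A simulator (`simulate_cohort()`) generates family cohorts from a
known haplotype pool so that the whole pipeline can be validated
against ground truth.

## Segregation phasing

A genotype heterozygous at $h$ loci admits $2^{\max(h-1,\,0)}$
distinct splits into two haplotypes. `phase_family()` scans all joint
parental configurations (at most $16 \times 16$ for five biallelic
splits) and keeps those that explain every child as one paternal plus
one maternal haplotype with no recombination. Statuses:

* **unique** — all admissible configurations give the same founder
  haplotype *multiset*. Two configurations that differ only in which
  child received which haplotype (or in within-parent order) count as
  the same solution, because frequencies depend only on the founders.
* **ambiguous** — several founder multisets are admissible (common
  with a single child and uninformative genotypes).
* **inconsistent** — no configuration explains the children. This is
  how recombinant or mutant transmissions and genotyping errors
  surface; the family is excluded and reported, never silently
  repaired, since dropping the offending child would bias counting.

A family with missing alleles at any analyzed locus is excluded from
phasing and itemized in the report. Phasing always operates at the
input resolution; reduction to allele-lineage (one-field) names is
applied *after* phasing, so that a low-resolution analysis cannot
merge distinct parental haplotypes before segregation is resolved.

## Frequencies and their standard deviations

Frequencies are $p = \text{count}/2n$. Standard deviations use the
sample-corrected binomial form
$\sqrt{p(1-p)/(2n-1)}$. The uncorrected $\sqrt{p(1-p)/2n}$ differs in
the fourth decimal for about one row in ten at $2n=400$; the corrected
form is the one that reproduces, at four printed decimals, every SD in
the published Emirati frequency tables packaged under
`inst/extdata/` (161 of 162 values; the single exception is a stray
rounding in the source table and is documented in the tests).

Display thresholds (e.g. "haplotypes above 1%") are presentation
filters only and are never applied before statistics are computed.

## Hardy–Weinberg exact test

For a multiallelic locus the test conditions on the observed allele
counts: the $2n$ alleles are repeatedly shuffled into $n$ random
pairs, and the p-value is the proportion of shuffles whose conditional
probability,
$P(\text{array}) \propto 2^{\text{het}} / \prod_g n_g!$,
is at most that of the observed array (observed table included in
numerator and denominator, so $p = (r+1)/(R+1) > 0$). With a fixed
seed the result is fully deterministic. The estimator was checked
against exhaustive enumeration of all allele pairings at small $n$ and
is calibrated under null simulation (fraction of $p < 0.05$ close to
5% across hundreds of simulated loci).

## Ewens–Watterson neutrality test

The observed homozygosity $F_{\mathrm{obs}} = \sum_i p_i^2$ is
compared with its neutral expectation *conditional on the sample size
$n$ and the observed allele count $k$*. Conditional on $k$, the Ewens
sampling formula is free of $\theta$: a configuration with part-size
multiplicities $a_j$ has probability proportional to
$n! / \prod_j j^{a_j} a_j!$. The sampler:

* $n \le 20$ — exhaustive enumeration of all partitions of $n$ into
  $k$ parts, sampled exactly;
* larger $n$ — a Chinese-restaurant-process draw with rejection on the
  realized allele count. The CRP's $\theta$ is set by solving
  $E[K] = k$ (Watterson's moment choice); this affects only rejection
  efficiency, never the sampled law. The new-table indicators are
  drawn first (they alone determine $K$), so rejected draws cost a
  single vectorized Bernoulli pass.

$F_{\mathrm{exp}}$ and $\mathrm{sd}_F$ are the null sample's mean and
SD, $F_{nd} = (F_{\mathrm{obs}} - F_{\mathrm{exp}})/\mathrm{sd}_F$,
and the p-value is lower-tail ($F \le F_{\mathrm{obs}}$), since
balancing selection — the expected regime for HLA — depresses
homozygosity. Sampler moments were verified against exhaustive
enumeration up to $n = 30$.

## Linkage disequilibrium

For alleles $i, j$ at two loci with haplotype frequency $h_{ij}$:
$D_{ij} = h_{ij} - p_i q_j$, normalized by
$D_{\max} = \min\{p_i(1-q_j),\, q_j(1-p_i)\}$ for $D \ge 0$ (the
mirrored pair otherwise), and
$\chi^2_{ij} = 2n\,D_{ij}^2 / (p_i(1-p_i)q_j(1-q_j))$ with a 1-df
tail p-value and no continuity correction. Global summaries:

* overall $D' = \sum_{ij} p_i q_j \lvert D'_{ij}\rvert$;
* $W_n = \sqrt{\sum_{ij} D_{ij}^2/(p_i q_j) \,/\, (\min(k_a,k_b)-1)}$,
  the Cramér's-V analogue;
* ALD: $W_{a/b} = \sqrt{(F_{a/b}-F_a)/(1-F_a)}$ with
  $F_a = \sum_i p_i^2$ and $F_{a/b} = \sum_{ij} h_{ij}^2/q_j$.

`ald()` follows the convention of the asymLD/pould tools:
`W_a_given_b` is the variation at locus *a* explained by locus *b*,
so if *a* is a deterministic function of *b* then `W_a_given_b = 1`.
Note that some published tables print the transposed labeling (the
conditioning locus written first); when comparing against external
reports, check which direction equals 1 on a many-to-one toy table.
Zero-frequency alleles are dropped from joint tables before the
global statistics (they contribute nothing but break the divisions),
and raw p-values are reported by default, with a Bonferroni column
behind a flag.

## Population comparison

**Nei standard genetic distance.** Allele universes are unioned per
locus (absent alleles at frequency 0), $J_x$, $J_y$, $J_{xy}$ are
means over loci of $\sum x^2$, $\sum y^2$, $\sum xy$, and
$D = -\ln\!\big(J_{xy}/\sqrt{J_xJ_y}\big)$. Populations sharing no
allele have zero identity; that is reported as an error (infinite
distance) rather than a number.

**Neighbor joining** is implemented with the standard Q-criterion and
branch-length formulas, plus two explicit conventions: ties in the
Q-matrix are resolved toward the lexicographically smallest label
pair, and a negative branch length is clamped to zero with the
deficit moved to its sister branch (preserving the pair's total).
Trees are `ape` `phylo` objects; on additive matrices the
implementation reproduces the generating tree exactly and agrees with
`ape::nj()`.

**Bootstrap supports** resample allele *counts* per population and
locus from a multinomial over that population's chromosome sample
size, then rebuild the distance matrix and tree; an edge's support is
the percentage of replicates containing the same bipartition. The
resampling unit is the chromosome because single-locus trees cannot
bootstrap over loci; this is a documented package choice, as the
sampling unit is rarely stated in published dendrograms. Populations
are sorted by label internally so supports do not depend on input
order.

**Correspondence analysis** is the standard SVD of standardized
residuals $(P_{ij}-r_ic_j)/\sqrt{r_ic_j}$ of the population-by-allele
table (by default weighted by sample sizes, i.e. allele counts), with
mass-scaled principal coordinates; axis inertias are the squared
singular values and sum to the table's total chi-square inertia. CA
is defined on frequency tables, not on distance matrices; for the
case where only distances are available, `sgd_mds()` provides
classical metric scaling as an explicitly separate method.

## The synthetic cohort generator

`simulate_cohort()` emulates the sampling design of a family-based
HLA study: parents drawn independently from a five-locus haplotype
pool (random mating, no inbreeding), a uniform number of children per
family (default 2–7, the reported sibling range of the emulated
cohort), independent crossovers between adjacent loci at a
configurable rate (default 0, no interference), and optional allele
missingness. Defaults are the study conditions: 100 families, hence
400 founder chromosomes.

The default pool is built in `"table"` mode from the packaged
published five-locus haplotype list (mass 0.2925, including the most
frequent haplotype A\*26~B\*08~C\*07~DRB1\*03~DQB1\*02 at 0.0425);
the remaining mass is spread over filler haplotypes by a
deterministic comonotone (quantile) coupling of the residual
per-locus marginals. The coupling makes the pool marginalize back to
the published lineage frequencies *exactly* at every locus, needs no
random numbers, and induces moderate positive LD among filler
haplotypes — qualitatively like real HLA data, though the filler LD
structure itself is a construction, not an estimate.

What passing tests on synthetic cohorts do show: the phaser is sound
and complete (checked against a brute-force oracle), frequencies are
recovered without bias beyond binomial sampling noise, and
recombination raises the inconsistent-family rate monotonically. What
they cannot show: behavior under genotyping error models, population
substructure, or the ambiguity profile of real low-resolution typing
chemistry.

## Numerical and testing choices

* Joint tables must sum to 1 within 1e-9; frequency files within
  1e-3 (renormalized with a warning beyond that).
* Monte Carlo defaults: 10,000 replicates for HWE and EWH, 1,000 for
  bootstrap supports; seeds are mandatory arguments wherever
  randomness enters, and every stage derives its own stream from the
  pipeline seed.
* Oracle tests compare the vectorized statistics against literal
  loop-based implementations on 200 random joint tables at 1e-10;
  phasing against exhaustive configuration search on 400 random
  families; NJ against path-length recovery on random additive trees
  with up to 8 taxa; CA against `MASS::corresp` and the chi-square
  distance identity.
* Calibration tests use 250–500 simulated loci with 1,000 Monte Carlo
  replicates each — sizes chosen to keep the default suite fast while
  leaving the binomial error on the rejection-rate estimate well
  inside the asserted bands.

## Known limitations

* Phasing assumes exactly two parents per family and no genotyping
  error model; an erroneous genotype surfaces as an inconsistent (or
  spuriously unique) family rather than being imputed.
* GL-string / ambiguity-string encodings are not supported: one
  allele name per chromosome per locus.
* The Ewens–Watterson rejection sampler slows as the observed allele
  count moves into the far tail of the neutral $K$ distribution
  (acceptance falls with $|k - E[K]|$); for the locus/sample sizes of
  family cohorts this is not a practical concern.
* Reference population frequency tables for large-scale comparisons
  are not shipped; the distance/tree/CA machinery operates on any
  long-format frequency CSV the user supplies.
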