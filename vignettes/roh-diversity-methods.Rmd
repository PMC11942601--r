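---
title: "Methods: runs of homozygosity, inbreeding and effective population size"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: runs of homozygosity, inbreeding and effective population size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdiv)
```

`rohdiv` implements the genomic-and-pedigree diversity analysis used in
small-population conservation genetics: runs of homozygosity (ROH) and the
inbreeding coefficients derived from them, classical and ancestral pedigree
inbreeding, effective population size (Ne) from linkage-disequilibrium (LD)
decay and from closed forms on mean ROH coverage, and the mapping of
consensus ROH and ROH islands as candidate selection signatures. This
vignette records the models, the parameter conventions, and the design
choices made where the methods literature leaves room.

## ROH detection and calibration

A run of homozygosity is a contiguous stretch of homozygous genotypes that
is, at sufficient length, almost surely identical by descent. Detection
follows the overlapping-window approach popularized by PLINK:

1. every contiguous window of `window_snps` SNPs (default 15) is scored
   homozygous iff it contains at most `max_het_in_window` heterozygous
   (default 1) and `max_missing_in_window` missing (default 1) calls;
2. a SNP is run-eligible iff at least `window_hit_fraction` of the windows
   overlapping it are homozygous;
3. maximal runs of eligible SNPs are split at inter-SNP gaps above
   `max_gap_kb` (default 500 kb) and emitted when they hold at least
   `min_snps_in_roh` SNPs, span at least `min_length_kb`, and keep at least
   one SNP per `min_density_kb_per_snp` (default 100 kb).

The minimum run size is not a free parameter: `min_snp_count()` calibrates
it so that fewer than `alpha` chance runs are expected genome-wide,

$$l = \left\lfloor \frac{\ln(\alpha / (n_s n_i))}{\ln(1 - \bar h)} \right\rfloor,$$

with $n_s$ SNPs, $n_i$ individuals and mean SNP heterozygosity $\bar h$.
The count is floored, not rounded, because $l$ is the smallest count still
meeting the error bound ("$l$ or more"). On a 65k equine panel with
$\bar h = 0.273$ and 675 individuals this gives 64 SNPs and, at 34.84
kb/SNP, a 2230 kb minimum length — the package defaults. The minimum
run length in bp is $l$ times the mean inter-SNP spacing, i.e. covered
length over SNP count, where covered length sums last-minus-first mapped
position per chromosome.

Three conventions are worth stating because the window literature leaves
them open. First, `window_hit_fraction` defaults to 0.05, the PLINK
default, since published parameter lists typically omit it. Note that with
15-SNP windows any single homozygous window already clears 5%, so the rule
effectively demands one clean window per SNP. Second, emitted segments are
*not* re-limited to one heterozygote overall: the window rule alone decides
(PLINK semantics); a `strict` mode re-imposes the per-window allowance on
whole segments for sensitivity analysis. Third, no MAF or LD pruning is
applied before detection by default — pruning removes exactly the SNPs
that make long homozygous stretches detectable and biases ROH coverage
downwards.

Length classes are half-open intervals $[lo, hi)$ in Mb (2–4, 4–8, 8–16,
16–32, >32 by default), so every run falls in exactly one class and class
coverages add up exactly.

## Genomic inbreeding coefficients

* `f_roh()`: combined ROH length over the covered autosomal length
  $L_{auto}$, optionally restricted by a half-open length bound. Because
  classes partition the length axis, $F_{ROH}$ equals the sum of its
  class-restricted components plus the open top class — an identity the
  tests verify, not an approximation.
* The *generation-linked threshold*: under a 1 cM/Mb map, runs longer than
  $100/(2g)$ Mb reflect common ancestors within the last $g$ generations.
  With pedigree depth GE = 7.42 equivalent generations this gives the
  6.739 Mb threshold; the package computes it from GE rather than
  hard-coding it, so the "inbreeding the pedigree could have seen"
  comparison works at any pedigree depth.
* `f_hom()`: homozygous fraction of non-missing calls; on complete data its
  mean is exactly one minus mean SNP heterozygosity.
* `f_is()`: $1 - O_{het}/E_{het}$ with $E_{het} = \sum_j 2 p_j (1 - p_j)$
  over the individual's non-missing SNPs.
* `f_hat()`: the three GCTA estimators (variance-based, excess
  homozygosity, uniting-gamete correlation), with monomorphic SNPs
  excluded.

Allele frequencies are always taken from the full post-QC sample including
the focal individual (the GCTA convention). With a few hundred individuals
the resulting bias is below the reporting precision, and the convention
keeps single-pass computation possible.

## Pedigree inbreeding

`meuwissen_luo_f()` computes classical F — the kinship of an individual's
parents — with the Meuwissen–Luo tabular method: the diagonal of the
relationship matrix is accumulated from Mendelian-sampling variances along
a backwards sweep of path coefficients, linear time per individual, no
$n^2$ kinship matrix. The tests cross-check it against an independent
Wright path-counting oracle on random six-generation pedigrees.

`equivalent_generations()` measures pedigree depth as
$\sum (1/2)^{g}$ over all known ancestor paths, via the recursion
$GE(i) = \sum_{p \in \text{known parents}} (1 + GE(p))/2$. The
depth-corrected individual rate of inbreeding is
$\Delta F = 1 - (1 - F)^{1/(GE - 1)}$, zero for individuals with one
generation of pedigree or less.

`gene_drop_ancestral()` estimates the ancestral coefficients by dropping
uniquely labeled founder alleles through the pedigree. Each allele copy
carries a count of ancestral autozygosity events; at each individual the
drop records whether its two copies descend from one founder allele.
From replicate means: Ballou's $F_{a}$ is the probability a random allele
was autozygous in at least one ancestor; Kalinowski's $F_{a}$ is the
probability of being autozygous *for* such an allele, and $F_{New}$ the
probability of first-time autozygosity, so $F_{New} + F_{a,Kal} = F$
(exactly under exhaustive enumeration, within binomial error otherwise);
Baumung's AHC is the expected event count. Two conventions: the event
counts cover *ancestors only* (an individual's own autozygosity becomes
ancestral for its descendants, not for itself), which makes
$AHC \ge F_{a,Bal} \ge F_{a,Kal}$ an exact inequality (a count exceeding
zero is at least one); and an unknown parent contributes fresh founder
alleles, the PEDIG convention for incomplete pedigrees. Default 1e5
replicates put the standard error near 0.001 on coefficients of order
0.05, below reporting precision; `mode = "exhaustive"` enumerates all
transmission patterns on small pedigrees and is what the Monte Carlo path
is tested against.

## Effective population size

From LD: for SNP pairs at recombination distance $c$ Morgans (distance in
units of 100 Mb, i.e. 1 cM/Mb), the package bins squared dosage
correlations by physical distance and applies

$$N_e = \frac{1 - \overline{r^2}}{4 c\, \overline{r^2}}, \qquad
  t = \frac{1}{2c}, \qquad \Delta F = \frac{1}{2 N_e},$$

so each distance bin dates an estimate $t$ generations back: long-range LD
reflects recent Ne, short-range LD ancient Ne. Bin edges grow from 10 kb
wide at the near end to 100 kb and then geometrically to 50 Mb — recent
generations need the wide-distance resolution, distant ones need enough
pairs per bin; the edges are an explicit argument and are recorded in the
output. The dosage correlation is used as-is by default (no sample-size
correction, matching the standard PLINK-based workflow); `correct_n =
TRUE` subtracts the $1/n$ sampling inflation, which matters when $n$ is
small relative to $4 N_e c$ — the Wright–Fisher recovery analysis below
enables it because with $n = 100$ the raw bias would dominate every
distant-generation bin.

From ROH coverage: $\Delta F_{ROH} = 1 - (1 - \bar F_{ROH})^{1/(GE_{ROH} - 1)}$
and $N_e = 1/(2 \Delta F_{ROH})$, with $GE_{ROH}$ the generations captured
by runs above each threshold. The conventional constants 12.5, 6.25,
3.125 and 1.5625 for the >4, >8, >16 and >32 Mb thresholds follow from the
$g = 100/(2L)$ dating rule; the all-lengths constant 15.6691 is not
derivable from that rule and is treated as a given of the method.
Degenerate inputs are explicit: $\bar F_{ROH} = 0$ yields $\Delta F = 0$
and an undefined (NA) Ne rather than an infinity.

Birth-year cohort trajectories rerun the LD estimator per cohort
(right-closed year classes; cohorts under two individuals are skipped with
a warning). Per-generation decline between two trajectory points $a$ and
$b$ is $(N_{e,a} - N_{e,b})/(g_a - g_b)$, generations counted backwards
with 0 the present.

## Consensus ROH and islands

`roh_incidence()` counts, per SNP, the individuals whose runs cover its
position (runs of one individual never overlap, so no double counting).
Consensus ROH are maximal stretches of SNPs with incidence at or above a
sharing threshold; the defaults {0.20, 0.25, 0.30, 0.40, 0.45} cover the
thresholds in routine use. ROH islands are maximal stretches whose
incidence *count* strictly exceeds the genome-wide 99th percentile of the
per-SNP incidence distribution (linear-interpolation quantile; strict
exceedance per the definition "exceeds the percentile" — with a degenerate
distribution nothing qualifies and the function warns). Region bounds sit
at the first and last qualifying SNP position; `max_bridge` can merge runs
separated by a few SNPs but defaults to 0, since reported islands are
single contiguous stretches and merging is cosmetic. Gene annotation is a
local file join (GFF3/BED via `rtracklayer`, each gene id counted once per
region) — no external database is consulted.

## The synthetic population and what it does (not) show

All tests and the analysis scripts run on `simulate_population()`:
founder haplotypes drawn SNP-wise from a truncated Beta(0.5, 0.5)
frequency spectrum (mean SNP heterozygosity near 0.27, matching draught
horse panels), offspring haplotypes formed by Haldane-model recombination
(Poisson crossovers at 1 cM/Mb) over uniquely labeled founder chromosomes.
The labels make truth exact: an autozygous tract is a run where both
labels match, and true F is tract length over covered length, at marker
resolution. Mating schemes: `random` (baseline relatedness),
`full_sib_loops` (deliberate inbreeding loops; offspring of the first sib
mating have expected F = 0.25), and `wright_fisher` (constant-size
monoecious drift, for LD-based Ne recovery). The default desk scale is 10
chromosomes x 2,000 SNPs x 200 individuals, which runs every stage in
minutes; the 1 cM/Mb map is fixed by default so the $100/(2L)$ dating rule
holds in simulation by construction.

`plant_island()` makes a chosen fraction of individuals homozygous for one
haplotype across a region. The shared haplotype is *delimited*: carriers
are set heterozygous at two flanking markers per side (they hold the
haplotype against a different background), because under the
window-tolerance semantics an undelimited homozygous block would smear
several markers past its edge and no sharp recovery criterion could be
stated. With the delimiter, detected region edges sit within one SNP of
the planted bounds, and that is what the tests assert.

What passing these tests shows: the detector equals an exhaustive scanner,
the coefficient identities hold, estimators recover known truth under the
generator's assumptions. What they do not show: robustness to genotyping
error (the generator emits error-free calls), to array ascertainment bias
(frequencies are drawn from a smooth spectrum), to non-uniform
recombination maps, or to pedigree errors — on real data those affect
ROH-based quantities in ways no simulation here exercises. Mutation and
selection are likewise absent by design.

## Numerical conventions and problem sizes

Positions are 1-based inclusive (PLINK `.bim` convention); BED exports are
0-based half-open. Run length is `end - start + 1` bp; Mb = bp/1e6.
Genotypes are dosages of the within-dataset minor allele, ties broken by
allele-symbol order. QC repeats its two rate filters to a fixed point, so
it is idempotent and every survivor meets its threshold on the final
matrix. Zero-variance SNPs are skipped in LD pairs; monomorphic SNPs are
excluded from the F-hat denominators.

The test suite sizes were chosen to keep the whole suite in single-digit
minutes on one core while leaving no stage untested at meaningful scale:
detector-vs-oracle on 200 random chromosomes of up to 500 SNPs; 50 random
six-generation pedigrees against path counting; gene drop at 1e5 rounds
against exhaustive enumeration on looped pedigrees; LD-Ne recovery on ten
seeded Wright–Fisher replicates (N = 100, 200 generations, 20 chromosomes
x 500 SNPs) with a ±25% band per replicate; island recovery on a 24,000-SNP
genome so a 7 Mb planted region stays under the 99th-percentile share.
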