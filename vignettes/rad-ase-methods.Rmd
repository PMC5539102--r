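---
title: "Discriminating imprinting, cis-genetic and random monoallelic expression with reciprocal allele descendants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating imprinting, cis-genetic and random monoallelic expression with reciprocal allele descendants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Allele-specific expression (ASE) — unequal RNA-seq read counts between
the two alleles of a heterozygous SNP — can arise from at least three
distinct mechanisms:

* **genomic imprinting**: one parentally inherited allele is silenced,
  so the expressed allele tracks parent of origin, not sequence;
* **genetic-variation-dependent (cis) ASE**: the expressed allele
  tracks sequence identity (reference versus alternative), typically
  through cis-regulatory variation;
* **random monoallelic expression (RME)**: one allele is silenced at
  random per individual or clone, as in random X-chromosome
  inactivation; in clonal cell lines such as LCLs this appears as a
  stable monoallelic bias whose direction is arbitrary.

In model organisms imprinting is established with reciprocal crosses:
the same bias direction relative to parent, with the strain (sequence)
identity of the biased allele swapped between the two cross
orientations. Humans cannot be crossed, but genotyped parent–offspring
trios provide a natural analogue: two unrelated children who are
heterozygous for the same SNP, where the paternal allele is the
*reference* base in one child and the *alternative* base in the other,
form a **reciprocal allele descendant (RAD)** pair. Consistent bias
toward the paternal (or maternal) allele across a RAD pair implicates
imprinting; consistent bias toward the reference (or alternative)
allele implicates cis-acting variation; bias that respects neither
coordinate implicates RME. `radase` implements this whole decision
procedure, plus the complementary population-scale test.

## From reads to pattern labels

**Applicable SNPs.** A site enters the analysis for a child only when
all five criteria hold: (1) the child is heterozygous and the site lies
in a genic region; (2) at least one parent is homozygous (which makes
the parental origin of both child alleles uniquely determined by
Mendelian transmission — `infer_origin()` raises an error on
Mendelian-impossible trios); (3) every heterozygous individual
examined shows the same dimorphic nucleotide pair; (4) more than 10
reads map to the site (11 passes, 10 fails — the bound is read
strictly); (5) any third allele accounts for less than 10% of the
mapped reads (exactly 10% fails). Third-allele reads that pass
criterion (5) are excluded from the test denominator, since the test
is defined on two alleles.

**ASE calling.** Each applicable (site, child) pair is tested with a
1-degree-of-freedom chi-square goodness of fit against a balanced
50:50 expectation,

$$\chi^2 = \frac{(n_\mathrm{ref} - n_\mathrm{alt})^2}{n_\mathrm{ref} + n_\mathrm{alt}},$$

without continuity correction by default (a Yates-corrected variant is
available by configuration). Loose ASE means $p < 0.05$; stringent ASE
additionally requires a higher/lower allele ratio above 2 and an *ASE
score* above 3. The score is defined here as $-\log_{10} p$, which
makes the score-3 and $p < 10^{-3}$ thresholds exactly equivalent (the
tests pin this equivalence on an exhaustive grid); with that
definition a zero lower count gives an infinite ratio, which passes
the ratio gate — complete monoallelic expression is the strongest
possible signal. No multiple-testing adjustment is applied anywhere in
the pipeline; the thresholds are fixed, field-standard cutoffs rather
than error-rate-calibrated decisions, and this is a documented
limitation. No reference-bias correction is applied either: the
package consumes counts downstream of alignment and assumes mapping
bias was handled there (e.g. by aligning to an N-masked genome).

**Labels.** A stringent call in an origin-determinable child gets one
of four labels: `P_r`, `P_a`, `M_r`, `M_a` — paternal/maternal origin
of the biased allele crossed with its reference/alternative identity.

## Pairwise groups and site categories

The 10 unordered pairs of labels partition into four groups:

| Group | Pairs | Reading |
|-------|-------|---------|
| G1 | `P_r P_a`, `M_r M_a` | same parent, reciprocal sequence — imprinting-type RAD |
| G2 | the 4 identical pairs | same everything — no RAD information |
| G3 | `P_r M_r`, `P_a M_a` | same sequence, reciprocal parent — cis-type RAD |
| G4 | `P_r M_a`, `P_a M_r` | reciprocal in both — RME signature |

A site with at least two applicable children, **all** of them showing
stringent ASE (a site with an applicable-but-biallelic child is
dropped before categorisation), is categorised from the set of groups
its label pairs generate:

* **Category 2-2** — any G4 pair present (RME-consistent);
* **Category 1-1** — G1 present, G3 absent (imprinting-consistent RAD);
* **Category 2-1** — G3 present, G1 absent (cis-consistent RAD);
* **Category 1-2** — only G2 (consistent bias, no RAD; the mechanism
  cannot be resolved from trios alone).

Two deliberate readings of the rule table: a label set generating both
G1 and G2 (e.g. `{P_r, P_r, P_a}`) is Category 1-1, and G2+G3 is
Category 2-1 — the definitions exclude only the groups they name. The
configuration "G1 and G3 both present without G4" cannot occur (any
set containing an imprinting-type and a cis-type pair necessarily
contains a both-reciprocal pair); rather than inventing a category for
it the implementation proves it unreachable by exhaustion over all 15
label subsets and asserts against it at run time, keeping
`unclassifiable` reserved but unused.

Finally, the **RME-gene exclusion**: a non-Category-2-2 site inside a
gene that also contains a Category-2-2 site is removed from the
retained set (flagged, never deleted from the audit table), because
gene-level RME can masquerade as imprinting at individual SNPs.
Assignment uses the full gene-body span, introns included — the most
inclusive defensible reading of "genic" — and a site in several genes
is excluded if any of them is RME-flagged. Sites in no gene are logged
and retained. The operation is idempotent.

## The population-scale r = a test

For each categorised site, every cohort individual is screened with
the per-individual criteria (heterozygous, depth > 10, third allele <
10%); on chromosome X only females are considered (requiring sex
metadata; pseudoautosomal regions are not special-cased). A site
needs strictly more than 10 applicable individuals, and at least 95%
of them must show ASE (the stringent definition by default;
configurable to loose — the appropriate choice for a given cohort is
genuinely open, so both are exposed). The ref-biased versus alt-biased
individual counts are then tested with the same 1-df chi-square:
balance (`p > 0.05`, verdict `r_eq_a`) is what imprinting and RME
produce, since the biased allele's sequence identity is arbitrary per
individual; skew (`r_ne_a`) marks genetic-variation-dependent ASE. A
p-value of exactly 0.05 falls on the `r_ne_a` side (the balance
verdict is defined by `p > 0.05`). Reconciliation with the trio-stage
categories yields the interpretive call (paternal/maternal imprinting,
RME, cis); combinations the two stages read differently are flagged
`discordant` rather than overwritten.

## What the generator emulates — and what it does not

`simulate_study()` draws parental genotypes at Hardy–Weinberg
proportions (alternative-allele frequency 0.5 by default), transmits
one allele per parent, and records the transmission as ground truth.
Depth is negative-binomial with mean 100 and size 25 (≈20%
coefficient of variation) so the depth filter is genuinely exercised;
the expressed-allele fraction is 0.95; third-allele error is off by
default but available up to 10%. Mechanisms are simulated per site:
imprinting expresses the parental allele, cis ASE the fixed sequence
allele, RME a uniformly random allele per individual (the clonal-LCL
picture — RME is *not* simulated per cell), and biallelic splits
50:50. Cohort individuals carry no pedigree, so at imprinting sites
their parental origin is drawn uniformly — which is exactly why
imprinting and RME are indistinguishable to the population test and
only the trio stage separates them.

The demonstration study uses 7 trios and a cohort of 100, with every
trio forced to an informative configuration and reciprocal (RAD)
configurations forced at imprinting sites by alternating the paternal
allele across trios. The site mix is 30 sites per mechanism except
RME, which gets 300: with seven children drawing labels essentially
uniformly at random, the chance that a site never produces a G4 pair
is $\frac{4\,(2^7-2)+4}{4^7} \approx 3.1\%$, so the expected
Category-2-2 recovery (~96.9%) sits close to the 95% bar and a larger
site count is needed for a stable rate estimate; the other mechanisms
recover nearly deterministically. These sizes keep the full
simulate–trio–population round trip around a minute.

What the generator does **not** emulate: read-level artefacts
(alignment bias, duplicates, overlapping mates), linkage between
sites, allele-frequency spectra, partial or tissue-heterogeneous
imprinting, clonality mixtures, and pseudoautosomal chromosome-X
behaviour. Passing recovery tests therefore demonstrates the
correctness of the decision logic under the stated generative model,
not robustness to real-data artefacts upstream of the counts.

## Numerical and degenerate-input choices

* Chi-square p-values come from the exact 1-df survival function; the
  test suite cross-checks them against an independent closed form
  (`erfc`), numerical integration of the density, and
  `stats::chisq.test`, to 6+ significant digits.
* A test on `(0, 0)` counts is an error, not a silent `NA`.
* Genotype phase separators in VCFs are ignored; parent-of-origin is
  always re-derived from parental homozygosity. Haploid GT calls are
  treated as homozygous.
* Multiallelic and non-SNP VCF records are dropped and counted; the
  method is defined on dimorphic sites.
* In the mpileup grammar, `*` (deleted base) and `<`/`>` (reference
  skips) count to no allele; how indel-adjacent reads should be
  treated at SNP sites is not standardised, so this convention is
  logged whenever such symbols are seen.
* Intervals are handled by `GRanges` in its native 1-based closed
  convention end to end (GTF and VCF are 1-based too, so no conversion
  ever happens); boundary behaviour is pinned by tests at gene start
  and end.
* Chromosome names are normalised (`chrX` ≡ `X`) at every reader.
* The dimorphic-pattern criterion compares heterozygous children of
  the loaded trios by default; an `extra_genotypes` argument widens
  the comparison to cohort individuals, since either scope is a
  defensible reading of "all heterozygous individuals examined".
* Output tables share one TSV dialect (tab, header, `.` for missing)
  and a fixed sort order (chrom, pos, individual), so identical
  configurations reproduce byte-identical files.

## Worked example

```{r, eval = FALSE}
library(radase)

dir <- tempfile()
sim <- simulate_study(sim_config(), dir, seed = 1)
cfg <- rad_config(ped = sim$paths$ped, vcf = sim$paths$vcf,
                  gtf = sim$paths$gtf,
                  counts = sim$paths$counts_children,
                  cohort_counts = sim$paths$counts_cohort,
                  sex = sim$paths$sex, out_dir = file.path(dir, "out"))
trio <- run_trio_stage(cfg)
trio$report$category_counts
pop <- run_population_stage(cfg, categories = trio$categories)
pop$report$verdict_counts
head(pop$reconciliation)
```

## Known limitations

* The trio stage can only see sites applicable in at least two
  children; imprinting detection is therefore limited by the supply of
  informative RAD genotype configurations, and sensitivity grows with
  the number of trios.
* Category 1-2 is irreducibly ambiguous without population data.
* The plain chi-square ignores overdispersion of allelic counts; a
  beta-binomial would be more conservative at high depth, but the
  method is defined by the plain test and the package implements it as
  defined.
* Clonal artefacts of LCLs (aberrant monoallelic or biallelic clones)
  are discussed in the field but not modelled or corrected here.
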