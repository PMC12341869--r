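---
title: "Screening SNP genotypes for sex-determining regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening SNP genotypes for sex-determining regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The model

`sdscan` looks for a genetic sex-determining (SD) locus by treating the two
sexes of a single population as two "populations" and asking where in the
genome they are differentiated. The logic rests on what a fully sex-linked
biallelic SNP must look like in an XX/XY system: every male is X/Y and
therefore heterozygous, every female X/X and homozygous. Partitioning total
genetic variance with the Weir–Cockerham (1984) variance components — `a`
among groups (sexes), `b` among individuals within groups, `c` within
individuals — this configuration gives, in a balanced sample of any size,

$$F_{ST} = \frac{a}{a+b+c} = 0.5,\qquad
  F_{IS} = 1 - \frac{c}{b+c} = -1,$$

and pooled allele frequencies of 0.75 for the shared X allele and 0.25 for
the male-limited Y allele. A ZW/ZZ system produces the mirror image with
females heterogametic; the magnitudes are identical, so the same scan
detects both and the heterozygosity pattern decides between them. The joint
requirement — high between-sex $F_{ST}$ *and* strongly negative $F_{IS}$ —
is what distinguishes an SD region from regions that merely differ in
allele frequency between sexes (e.g. under sexual conflict), which show the
first signal but not the heterozygote excess.

### Estimators

Per locus we compute the two-group Weir–Cockerham components from per-sex
sample sizes, alternate-allele frequencies and observed heterozygosity,
using per-locus complete cases within each sex. Choices that matter:

* **Missing data.** A locus needs at least two complete genotypes per sex;
  otherwise both statistics are `NA` (undefined), and undefined loci are
  excluded from window means but never silently dropped from output.
* **Undefined estimates.** $F_{ST}$ is undefined when $a+b+c = 0$ and
  $F_{IS}$ when $b+c = 0$ — monomorphic complete-case data, or the corner
  case of the two sexes fixed for opposite alleles (no within-sex
  variance). Because those cancellations are exact only in real
  arithmetic, denominators below $10^{-12}$ are treated as zero; genuine
  polymorphism keeps them orders of magnitude larger.
* **Negative estimates** are reported as computed, never clipped: slightly
  negative values are the expected behaviour of variance-component
  estimators near zero differentiation.
* **MAF filtering** uses the pooled (both sexes) minor-allele frequency.
  The default threshold 0.2 is chosen against the sex-linked expectation:
  a diagnostic SNP sits at 0.25 and passes comfortably, while a large
  fraction of uninformative low-frequency background is removed.
* The pooled $F_{IS} = 1 - c/(b+c)$ is used for the screen; per-sex
  observed heterozygosity is carried separately and drives the XY/ZW call.

### The window screen

Per-SNP values at 5+5 samples are noisy, so the screen averages them over
sliding windows of `window_k = 10` consecutive SNPs, shifted one SNP at a
time, never across chromosome boundaries. Thresholds are deliberately
relaxed relative to the analytic expectations — `fst_min = 0.3`,
`fis_max = -0.5` — because not every SNP inside a real SD region is fully
diagnostic. Windows passing both thresholds are merged whenever they share
SNPs (without merging, a contiguous signal emits one near-duplicate region
per shift), region means are recomputed over the union of member SNPs, and
a region must span **strictly more than** `min_span_bp = 1000` bp (first to
last SNP, inclusive: `end − start + 1`) to pass the span rule. Shorter
regions are retained with `passes_span = FALSE` for inspection rather than
discarded. Classification compares mean per-sex heterozygosity over the
region's SNPs: a male excess larger than `classify_delta = 0.2` calls XY,
the mirrored excess calls ZW, anything closer is ambiguous. The margin
replaces a qualitative "mostly heterozygous in males" judgement with a
fixed, configurable rule.

### Linkage disequilibrium

Young sex chromosomes typically stop recombining through an inversion, so a
genuine SD region should show strong LD over distances far beyond normal
background decay. Since X/Y phase is unknowable from genotypes alone, we
use the composite genotypic $r^2$: the squared Pearson correlation of
allele dosages, which requires no phasing and is invariant to allele
relabelling. Significance comes from a probability exact test of the
two-locus genotype contingency table, with the null generated by permuting
one locus's genotypes among individuals (this fixes both genotype margins;
the permutation distribution of tables is the generalized hypergeometric).
We estimate it by Monte Carlo with $\hat p = (1+k)/(B+1)$ and report the
Monte-Carlo standard error; `B = 10000` by default, and identical
genotype-pair patterns (ubiquitous inside a zero-error fully linked block)
share one evaluation. A Markov-chain sampler as used by classic exact-test
software would target the same null; the simple permutation sampler is
easier to verify — the test suite checks it against full enumeration of all
$n!$ permutations for $n \le 8$. Degenerate tables (either locus with a
single genotype class) get $p = 1$ by convention.

### Panel validation and depth check

Validation re-tests selected SNPs in a larger sexed sample: the same
Weir–Cockerham statistics plus a two-sided Fisher exact test on the 2×2
table of allele counts by sex. The exact p is implemented as the
conditional hypergeometric sum (same convention as `stats::fisher.test`,
against which it is anchored in tests) and no multiple-testing correction
is applied by default, with a Bonferroni option behind a flag. Panel SNPs
are chosen per region by Euclidean distance of $(F_{ST}, F_{IS})$ to the
ideal $(0.5, -1)$, excluding SNPs with another polymorphism within
±100 bp (assay design constraint). The distance metric is our concrete
rendering of "closest to the expected sex-linked pattern"; any monotone
alternative would rank these extremes the same way.

An SD gene can also arise by male-specific duplication rather than allelic
divergence; that hypothesis is tested separately by comparing
library-size-normalized read counts over the gene between sexes. The ratio
of male to female mean normalized depth (~2 under a male-specific
duplication, ~1 without) is reported with a two-sided permutation test of
sex labels — exact enumeration of all label assignments up to 12 samples,
seeded Monte Carlo beyond. Library-size normalization is an explicit
assumption: raw counts would confound duplication with sequencing effort.

## The synthetic-data generator

`simulate_population()` generates the statistical structure the screen
assumes, not a population-genetic history. One chromosome (default 10 Mb)
carries SNPs at 2.2/kb. Inside a 2 Mb SD block, a contiguous core of 50
SNPs is fully sex-linked: a single Y (or W) haplotype shared by all
heterogametic individuals carries the alternate allele — the strongest
form of recombination suppression, under which every core SNP is exactly
diagnostic. Remaining block SNPs are sex-linked with probability
`partial_linkage = 0.05`, background-like otherwise. Background SNPs draw
an allele frequency from Beta(0.5, 0.5) — a U-shaped, site-frequency-like
spectrum — and genotypes Binomial(2, q) independent of sex (Hardy–Weinberg,
no background LD). Genotyping error (default 0.01) flips a genotype to one
of the other two codes uniformly; missingness (default 0.02) is applied
last. Everything is deterministic under the configured seed.

Unstated parameters were fixed once, a priori: the core is *contiguous*
because a 10-SNP window mean cannot clear both thresholds unless diagnostic
SNPs are locally dense — empirically, SD regions show exactly such compact
fully diagnostic peaks inside a broader suppressed block — and
`partial_linkage` is low so that the default dataset carries one
well-defined candidate region; raising it produces the multi-peak pattern
of a larger, older suppressed region. Missingness at 2 % is typical of
short-read genotyping after standard filters.

What a green recovery test does **not** establish: robustness to background
LD (background loci are independent), to unequal sex ratios or sample
contamination, to sex-chromosome turnover polymorphism within a population,
or to reference-bias artefacts in real alignments. The generator tests the
screen's logic, not the upstream variant calling.

## Numerical and design notes

* Windows are SNP-count based, spans bp-based; `span_bp = end − start + 1`
  (inclusive). The `> 1 kb` rule is strict: a span of exactly 1000 bp
  fails it.
* Window and region means are arithmetic means over *defined* per-SNP
  values; windows with fewer than half their SNPs defined are flagged
  low-confidence.
* The per-locus $F_{ST}$ ratio estimator has a small positive
  finite-sample bias under the null at 5+5 samples (≈ +0.002); the
  variance component `a` itself is unbiased. Tests assert the zero-mean
  property on `a` and bound the ratio's mean, and the screen's 0.3
  threshold is two orders of magnitude above the bias.
* VCF QUAL filtering is exclusive-below: a record at exactly the threshold
  is retained. Multiallelic records and indels are dropped (and counted in
  the load report), not split; half-calls become missing; phase separators
  are ignored.
* Monte-Carlo tests (LD, depth) take explicit seeds and restore the
  caller's RNG state; `ld_matrix` derives per-pair seeds so results do not
  depend on pair order.
* `run_screen()` writes reports with stable columns and number formatting;
  reruns with identical inputs and seed are byte-identical (the manifest
  deliberately carries no timestamp).

## Limitations

The screen assumes a single, largely penetrant genetic SD locus; polygenic
or strongly environment-dependent sex determination dilutes the diagnostic
pattern below the thresholds. With 5+5 samples the false-negative risk is
carried by the window averaging, and the false-positive risk by the joint
$F_{ST}$/$F_{IS}$ requirement plus the span rule; neither is a substitute
for validation in a larger sample, which is why the panel stage exists.
LD analysis is region-restricted by design (quadratic pair cost), and the
depth check takes counts as input — read alignment and counting are out of
scope.
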