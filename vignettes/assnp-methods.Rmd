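---
title: "Detecting allele-specific transcription-factor binding: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting allele-specific transcription-factor binding: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assnp)
```

## The problem

At a heterozygous SNP, ChIP-seq reads can be assigned to the allele they
carry. If a transcription factor binds the two alleles equally well, reads
should split roughly 1:1 between them; a significant departure is evidence
of allele-specific (AS) binding — and such AS-SNPs are strong candidates for
the functional variants behind GWAS and eQTL association signals, most of
which fall in non-coding regulatory DNA. `assnp` implements the full
discovery chain from per-allele read counts to annotated, catalog-linked
AS-SNP collections, together with a truth-labelled synthetic-data generator
so the whole chain can be validated without any external download.

## The statistical core

### Exact binomial test with CNV-adjusted nulls

For a SNP with `g1` reads on the reference allele and `g2` on the
alternative, the test statistic is exact: under
`X ~ Binomial(n = g1 + g2, p0)` the two-sided p-value sums the probabilities
of every outcome at most as likely as the observed one (the
minimum-likelihood convention),

```
p = sum over k of Pr(X = k), for all k with Pr(X = k) <= Pr(X = g1) * (1 + 1e-12)
```

For the symmetric null `p0 = 1/2` this reduces to the familiar doubled tail
capped at 1; the construction matters for the asymmetric nulls below, where
"as extreme" has no mirror-image shortcut. The `1e-12` relative slack is a
floating-point guard for exact probability ties (e.g. the symmetric
outcome pair under `p0 = 1/2`); without it, ties resolved by rounding error
would make p-values irreproducible across platforms.

Records with zero reads on either allele are discarded before testing:
requiring at least one read per allele both supports the underlying
heterozygous genotype call and keeps the test's support away from the
degenerate boundary.

Copy-number variation distorts the expected ratio. The null is resolved per
SNP:

| location | null | action |
|---|---|---|
| outside CNVs, or 2-copy region | 1/2 | test |
| 3-copy region, duplicated haplotype known | 2/3 (reference duplicated) or 1/3 | test |
| 3-copy region, haplotype unknown | — | exclude |
| 4 or more copies | — | exclude |
| CNV with no genotyped copy number | — | exclude |

so that a pure dosage imbalance (two copies of one allele binding normally)
is not mistaken for differential binding affinity.

### Multiple testing

Benjamini–Hochberg correction is applied *within each dataset* (one ChIP-seq
experiment = one TF × cell line) by default. Each experiment is its own test
family: it has its own depth distribution, binding landscape and SNP subset,
and detection is reported per TF downstream (the top-k coverage analysis).
A `global` family across all SNP × dataset pairs is available as an option.
Consequently, the false discovery rate is controlled per family — the
calibration tests measure the false-discovery proportion within each family
and average across families, which is the quantity the step-up procedure
bounds. A SNP is an AS-SNP when its q-value falls strictly below `alpha`
(default 0.05) in at least one dataset; multiplicity across datasets is
reported as provenance but not re-corrected, since each supporting dataset
is independent evidence for the same molecular event. No consistency of
direction across datasets is imposed.

### Region filtering

Candidate AS-SNPs are pruned after testing (matching the discovery
flow: test first, then clean), removing SNPs in

* assembly gap regions expanded by ±1 Mb (centromeres/telomeres attract
  collapsed-repeat artifacts well beyond their annotated edges),
* blacklisted regions expanded by ±100 bp,
* excluded CNV classes (ungenotyped, unresolved 3-copy, ≥4 copies).

Intervals are 0-based half-open throughout (`pos` is removed iff
`start <= pos < end` of an expanded interval); a SNP exactly at
`end + flank` survives. Filters apply in the fixed order gap → blacklist →
CNV so that every removal has one deterministic attribution, and the report
satisfies `input = output + sum(removed)` exactly — this reconciliation is
asserted on every synthetic bundle in the test suite. A pre-filtering mode
(filtering the SNP universe before testing) would give the same final set
because the filters are point-in-region predicates independent of the test;
the post-test default preserves the audit trail of how many *candidates*
each mask absorbed.

### Annotation

A SNP with catalogued allele frequency ≥ 1% is *common*; below 1%, or
absent from the frequency panel altogether, it is *rare* — absence is
informative (never coded as frequency 0). The allele-specific effect size is
`max(g1, g2) / (g1 + g2)`, the fraction of reads on the stronger allele
(0.5 = balance, 1 = monoallelic). When a SNP is significant in several
datasets, its representative ratio comes from the dataset with the smallest
q-value (ties: larger depth, then lexicographic dataset id); a "deepest
dataset" alternative is selectable. Common and rare effect distributions are
compared with Welch's unequal-variance two-tailed t test — group sizes and
variances differ substantially (rare groups are small), making the pooled
test the wrong default.

### LD integration and enrichment

GWAS/eQTL index SNPs are expanded with proxies at `r2 > 0.8` (strict
inequality, the conventional high-LD cutoff); `r^2` can be supplied
precomputed or derived from phased haplotypes as `D^2/(pA pa pB pb)`.
AS-SNPs touching the expanded catalog are classified as direct hits (they
are index SNPs) or LD-linked, keeping the full edge list for many-to-many
topology. Index-SNP hits are grouped into loci by single-linkage chaining
within 1 Mb per trait and chromosome — single linkage is the natural
reading of "SNPs within 1 Mb regions" and is parameterized, since any
chaining rule is somewhat arbitrary.

Enrichment against any target set (expanded catalogs, super-enhancer-like
interval collections via `snps_in_intervals()`) uses matched random sets:
each permutation draws a non-AS heterozygous SNP set of the same size
(optionally within allele-frequency deciles) and records its target
overlap. The empirical p-value uses the add-one convention
`(1 + #{null >= observed}) / (1 + B)` so it is never zero, and fold
enrichment is `observed / mean(null)`; a zero null mean is reported as
infinite fold with an explicit flag. Count-only matching is the default;
AF-decile matching is offered because target membership often correlates
with frequency.

### Heterozygote-discovery power

Under Hardy–Weinberg equilibrium a site at allele frequency `p` is
heterozygous in a random individual with probability `2p(1-p)` (1/3 when
averaged over a uniform frequency spectrum), and in at least one of `n`
unrelated people with probability `1 - (1 - 2p(1-p))^n`. The expected
fraction of polymorphisms covered by a cohort of `n`,
`1 - ∫(1-2p(1-p))^n dp`, has the closed form
`1 - 2^(-n) * Σ_k C(n,k)/(2k+1)` (substituting `u = 2p - 1` makes every
term positive, so the sum is numerically stable; it is cross-checked
against adaptive quadrature to 1e-9 for n up to 50 in the tests). The
uniform spectrum is the measure that reproduces the canonical 1/3, 66%,
79%, 90% sequence for n = 1, 3, 5, 10; other densities can be plugged in.
Report percentages round half away from zero (0.875 → 88%).

## The synthetic-data generator

The generator is first-class, tested code: it produces truth-labelled
bundles with the statistical structure the analysis assumes, and its
defaults *are* the study conditions used throughout the tests:

* 14% of heterozygous sites have allele frequency < 1% (the observed rare
  fraction among heterozygous SNPs in a genome); half of the rare sites are
  additionally absent from the frequency table, exercising the
  "never catalogued" branch.
* Read depth per SNP-dataset pair is negative binomial with mean 30 and
  dispersion 5 — ChIP-seq coverage at tested SNPs is overdispersed relative
  to Poisson; a Poisson option exists for analytic checks. No public value
  pins the depth distribution at tested sites, so these are explicit,
  configurable stand-ins.
* Counts are `g1 ~ Binomial(depth, theta_eff)`, independent across
  datasets; nothing is pooled across TFs at the counting stage.
* A fraction `frac_as` (default 0.05) of SNPs is truly imbalanced; the
  deviation `|theta - 0.5|` is uniform on [0.15, 0.30] for common and
  [0.25, 0.45] for rare SNPs, so rare effects stochastically dominate —
  the qualitative pattern the effect-comparison stage must recover. The
  common allele-frequency spectrum is uniform on [0.01, 0.99] (a
  simplification; real spectra are skewed toward low frequencies, which
  only matters for AF-matched enrichment realism).
* Inside a haplotype-resolved 3-copy region the effective fraction is the
  odds-style transform `2θ/(1+θ)` (reference haplotype duplicated) or
  `θ/(2-θ)`, which maps a balanced SNP exactly onto 2/3 or 1/3. SNPs in
  unresolved or high-copy CNVs still receive counts — exclusion is the
  pipeline's job, and the tests verify it happens there.
* Reference-alignment bias is not simulated by default (a bias multiplier
  on `theta_eff` exists for robustness experiments).
* CNV, gap and blacklist regions are placed on a disjoint slot grid, so
  regions never overlap; over-capacity requests error rather than silently
  truncating.
* Catalog/proxy generation plants true links (`r2` uniform on
  (0.805, 0.999)) from imbalanced SNPs and decoys (`r2 ≤ 0.8`) from
  balanced ones, including one-to-many topologies.

Everything is a deterministic function of the config seed; stage-specific
sub-seeds (`seed`, `seed+1`, ...) keep each generator independently
reproducible, and `emit_fixture_bundle()` writes byte-identical files (MD5
manifest) for identical configs.

What the generator does *not* emulate — and therefore what green tests do
not establish about real data: read-level mappability and reference bias,
correlated binding across TFs at shared elements, realistic LD structure
(no coalescent simulation; proxies are planted edges), overdispersion of
allelic fractions beyond the binomial (no beta-binomial component), and the
skewed real allele-frequency spectrum. Tests on these bundles validate the
statistical machinery, not the upstream alignment pipeline.

## Numerical choices and degenerate inputs

* p-value tie tolerance `1e-12` (relative), as above; p-values are capped
  at 1.
* `binom_p_two_sided()` computes one pmf per unique (depth, null) pair and
  reads two-sided p-values off a sorted cumulative sum, so testing 10^4+
  pairs is effectively linear.
* Zero-variance groups abort the Welch comparison with an explicit error;
  identical groups return t = 0, p = 1.
* Monomorphic sites make `r^2` undefined and error; computed values are
  clamped to [0, 1] against rounding.
* Overlapping CNVs covering one SNP are tolerated when their copy numbers
  agree and are an error otherwise.
* An empty p-value vector adjusts to an empty vector; an empty proxy table
  expands every association to just its index SNP.

## Problem sizes in the validation suite

The simulation-based checks use 10^4 SNP-dataset pairs per null bundle
(100 seeded replicates) for FDR calibration, 2,000 SNPs at Poisson depth 50
inside a chromosome-wide resolved 3-copy region for the CNV-adjustment
contrast, 600-SNP bundles across 100 seeds for the rare-vs-common effect
direction, and 10^4 permutations for enrichment floors — sizes at which the
binomial Monte-Carlo error bands quoted in the tests are meaningful.

## Known limitations

* No beta-binomial / WASP-style modelling: overdispersed allelic noise in
  real ChIP-seq will inflate the false-positive rate relative to these
  calibrations.
* The pipeline consumes allelic counts; producing them (allele-aware
  alignment, variant calling) is upstream and out of scope.
* Indels and multiallelic sites are skipped at VCF ingestion; only
  biallelic SNVs are analyzed.
* Cross-dataset dependence (the same fragment pool immunoprecipitated with
  different antibodies) is neither modelled nor corrected; the ≥ 1-dataset
  AS-SNP rule inherits it.
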