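# assnp — allele-specific transcription-factor binding from ChIP-seq allelic read counts

At a heterozygous SNP, each ChIP-seq read carries one of the two alleles.
When a transcription factor binds the two alleles equally, reads split
roughly 1:1; a significant imbalance marks an **AS-SNP** — a variant that
changes TF binding and is therefore a prime candidate for the functional
variant behind a GWAS or eQTL signal sitting in non-coding DNA. `assnp` is
for regulatory-genomics analysts who already have per-allele read counts at
heterozygous sites (from any allele-aware alignment pipeline) and want a
tested, reproducible route from those counts to an annotated,
catalog-linked AS-SNP collection.

## The method

For counts *(g1, g2)* at a SNP with total depth *n = g1 + g2*, the test is
the exact two-sided binomial test under *X ~ Bin(n, p₀)* with the
minimum-likelihood convention:

> p = Σₖ Pr(X = k)  over all k with Pr(X = k) ≤ Pr(X = g1)

The null proportion *p₀* is copy-number aware: 1/2 outside CNVs and in
2-copy regions; 2/3 or 1/3 inside a haplotype-resolved 3-copy region
(whichever haplotype is duplicated); SNPs in unresolved 3-copy, ≥4-copy or
ungenotyped CNVs are excluded. Benjamini–Hochberg FDR control is applied
per ChIP-seq dataset, and a SNP is an AS-SNP when *q* < 0.05 in at least one
dataset. Candidates are then pruned around assembly gaps (±1 Mb) and
blacklisted regions (±100 bp), classified as common (AF ≥ 1%) or rare
(AF < 1% or absent from the frequency panel), scored with the effect ratio
max(g1, g2)/(g1 + g2), linked to GWAS/eQTL catalogs through LD proxies
(r² > 0.8) with 1 Mb locus grouping, and tested for enrichment against
matched random SNP sets. A separate module computes Hardy–Weinberg
heterozygote-discovery power: the chance that *n* unrelated individuals
expose a heterozygote at a site of frequency *p* is 1 − (1 − 2p(1−p))ⁿ,
with closed-form uniform-spectrum averages.

A truth-labelled synthetic-data generator (`simulation_config()`,
`generate_bundle()`, `emit_fixture_bundle()`) reproduces the statistical
structure the analysis assumes, so every stage is testable offline. See
`vignette("assnp-methods")` for the model, parameter and design details.

## Worked example

Simulate a bundle of 1,000 heterozygous SNPs × 4 ChIP-seq datasets — 10%
truly imbalanced, with CNV regions, gap/blacklist masks and a planted
GWAS/eQTL catalog — then run the full pipeline:

```r
library(assnp)

cfg <- simulation_config(
  seed = 42, n_snps = 1000, n_datasets = 4, frac_as = 0.1,
  cnv_config = list(n_regions = 3, copy_numbers = c(2L, 3L, NA),
                    frac_haplotype_resolved = 1, region_length = 2e5),
  mask_config = list(n_gap = 1, n_blacklist = 2, gap_length = 5e4,
                     blacklist_length = 1000),
  catalog_config = list(n_index = 8, n_linked_as = 6, n_decoy = 6)
)
bundle_dir <- file.path(tempdir(), "bundle")
emit_fixture_bundle(bundle_dir, cfg)

res <- run_pipeline(pipeline_config(
  counts = file.path(bundle_dir, "counts.tsv"),
  het_snps = file.path(bundle_dir, "het_snps.vcf"),
  out_dir = file.path(bundle_dir, "out"),
  cnvs = file.path(bundle_dir, "cnv_regions.tsv"),
  gaps = file.path(bundle_dir, "gaps.bed"),
  blacklist = file.path(bundle_dir, "blacklist.bed"),
  frequency = file.path(bundle_dir, "frequencies.tsv"),
  catalog = file.path(bundle_dir, "catalog.tsv"),
  proxies = file.path(bundle_dir, "proxies.tsv"),
  n_permutations = 1000, seed = 42
))
#> [assnp] loaded 4000 count records at 1000 het SNPs
#> [assnp] discarded 16 zero-allele records, 16 CNV-excluded records; tested 3968 pairs; 74 candidate AS-SNPs
#> [assnp] region filters: 74 -> 73 AS-SNPs
#> [assnp] catalog integration: 0 direct + 5 LD-linked AS-SNPs in 6 loci
#> [assnp] enrichment: fold 70.4, empirical p 0.000999
```

The stage log is the discovery funnel: 4,000 SNP-dataset count records
enter; 16 lose a zero-read allele and 16 sit in excluded CNV classes; the
exact tests plus per-dataset BH leave 74 candidate AS-SNPs; one falls in a
gap flank, leaving 73; 5 of these tag planted association signals through
high-LD proxies, grouped into 6 trait loci; and the AS set overlaps the
expanded catalog ~70-fold more than size-matched random non-AS SNP sets
(the add-one empirical p at 1,000 permutations bottoms out at 1/1001).

```r
head(res$annotated[, c("snp_id", "freq_class", "af", "effect_ratio",
                       "best_q", "best_dataset")], 4)
#>      snp_id freq_class          af effect_ratio       best_q best_dataset
#> 1 snp000008     common 0.724488276    0.8125000 0.0015145717     TF03_SIM
#> 2 snp000011     common 0.824194000    0.8695652 0.0230422247     TF01_SIM
#> 3 snp000012     common 0.437023556    0.8000000 0.0019477966     TF03_SIM
#> 4 snp000017       rare 0.008515439    0.9583333 0.0004219157     TF04_SIM
```

Each AS-SNP carries its frequency class, the effect ratio (fraction of
reads on the stronger allele, taken from the most significant dataset) and
per-dataset provenance — e.g. `snp000017` is a rare variant (AF 0.85%) with
near-monoallelic binding (96% of reads on one allele).

Cohort-design power under Hardy–Weinberg:

```r
het_power_table(c(1, 3, 5, 10))
#>    n expected_fraction percent
#> 1  1         0.3333333      33
#> 2  3         0.6571429      66
#> 3  5         0.7893218      79
#> 4 10         0.8983462      90
```

One individual exposes a third of common polymorphisms as heterozygotes;
ten individuals expose 90% — the quantitative basis for surveying AS
binding with cell lines from a handful of donors.

A thin command-line wrapper with `simulate`, `run-all` and `hetpower`
subcommands is installed at `inst/cli/assnp.R`.

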