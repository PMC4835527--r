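# Independent enumeration oracle for the exact two-sided binomial p-value:
# direct combinatorial point masses (no dbinom), straight sum over outcomes
# at most as likely as the observed one.
oracle_binom_p <- function(g1, g2, p0) {
  n <- g1 + g2
  k <- 0:n
  probs <- choose(n, k) * p0^k * (1 - p0)^(n - k)
  pobs <- probs[g1 + 1]
  min(sum(probs[probs <= pobs * (1 + 1e-12)]), 1)
}

# small null-only simulation config (no CNVs, no imbalance)
null_config <- function(seed, n_snps = 2500L, n_datasets = 4L,
                        depth_mean = 30, ...) {
  simulation_config(
    seed = seed, n_snps = n_snps, n_datasets = n_datasets,
    depth_model = list(distribution = "negative_binomial",
                       mean = depth_mean, dispersion = 5),
    frac_as = 0, ...
  )
}

# tiny het-SNP table builder
make_snps <- function(n, chrom = "chr1", pos = seq_len(n) * 1000L) {
  data.frame(
    snp_id = paste0("rs", seq_len(n)), chrom = chrom, pos = pos,
    ref_allele = "A", alt_allele = "G", cell_line = "CELL",
    stringsAsFactors = FALSE
  )
}

make_cnv <- function(chrom, start, end, copy_number, dup = "unknown") {
  data.frame(
    chrom = chrom, start = start, end = end,
    copy_number = copy_number,
    haplotype_resolved = dup %in% c("g1", "g2"),
    duplicated_haplotype = dup, stringsAsFactors = FALSE
  )
}
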