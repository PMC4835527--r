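test_that("bundles are deterministic under the config seed", {
  cfg <- simulation_config(seed = 5, n_snps = 300,
                           cnv_config = list(n_regions = 2, copy_numbers = 3L,
                                             frac_haplotype_resolved = 1,
                                             region_length = 1e5),
                           mask_config = list(n_gap = 1, n_blacklist = 1,
                                              gap_length = 5e4,
                                              blacklist_length = 1000),
                           catalog_config = list(n_index = 4, n_linked_as = 3,
                                                 n_decoy = 3))
  b1 <- generate_bundle(cfg)
  b2 <- generate_bundle(cfg)
  expect_identical(b1, b2)

  d1 <- tempfile(); d2 <- tempfile()
  m1 <- emit_fixture_bundle(d1, cfg)
  m2 <- emit_fixture_bundle(d2, cfg)
  expect_identical(m1$md5, m2$md5)

  # and the bundle loads back through the readers
  expect_equal(nrow(read_counts_table(file.path(d1, "counts.tsv"))),
               nrow(b1$counts))
  expect_equal(read_het_snps(file.path(d1, "het_snps.vcf")), b1$snps)
  expect_equal(read_cnv_table(file.path(d1, "cnv_regions.tsv"))$copy_number,
               b1$cnvs$copy_number)
})

test_that("rare fraction of generated SNPs matches the configured rate", {
  cfg <- simulation_config(seed = 21, n_snps = 10000L, frac_rare = 0.14)
  hs <- generate_het_snps(cfg)
  obs <- mean(hs$truth$af < 0.01)
  sd3 <- 3 * sqrt(0.14 * 0.86 / 10000)
  expect_lt(abs(obs - 0.14), sd3)

  # frac_rare = 0: every catalogued frequency is >= 1%
  hs0 <- generate_het_snps(simulation_config(seed = 3, n_snps = 500,
                                             frac_rare = 0))
  expect_true(all(hs0$frequency$af >= 0.01))
  expect_equal(nrow(hs0$frequency), 500L)

  expect_error(generate_het_snps(
    simulation_config(n_snps = 100, chrom_sizes = c(chr1 = 50))
  ), "exceeds total genome length")
})

test_that("null bundles give calibrated (conservative) binomial p-values", {
  cfg <- null_config(seed = 17, n_snps = 2500L, n_datasets = 4L)
  b <- generate_bundle(cfg)
  keep <- b$counts$g1_count > 0 & b$counts$g2_count > 0
  p <- binom_p_two_sided(b$counts$g1_count[keep], b$counts$g2_count[keep], 0.5)
  rate <- mean(p < 0.05)
  # exact test on discrete counts is conservative: at or below nominal + 3 SE
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / length(p)))
})

test_that("non-imbalanced SNPs in a resolved 3-copy region sit at the 2:1 ratio", {
  snps <- make_snps(1, pos = 500L)
  truth <- data.frame(snp_id = snps$snp_id, af = 0.3)
  cnvs <- make_cnv("chr1", 0, 1000, 3L, "g2")
  cfg <- simulation_config(seed = 9, n_snps = 1, n_datasets = 1000L,
                           frac_as = 0,
                           depth_model = list(distribution = "poisson",
                                              mean = 50, dispersion = 5))
  sim <- simulate_allelic_counts(snps, truth, cnvs, cfg)
  ratio <- with(sim$counts, sum(g1_count) / sum(g1_count + g2_count))
  expect_equal(ratio, 1 / 3, tolerance = 0.02)
  expect_true(all(sim$truth$in_cnv))
  expect_false(any(sim$truth$is_as))

  # g1-duplicated region lands at 2/3
  sim2 <- simulate_allelic_counts(snps, truth,
                                  make_cnv("chr1", 0, 1000, 3L, "g1"), cfg)
  ratio2 <- with(sim2$counts, sum(g1_count) / sum(g1_count + g2_count))
  expect_equal(ratio2, 2 / 3, tolerance = 0.02)
})

test_that("rare imbalanced SNPs draw larger deviations than common ones", {
  cfg <- simulation_config(seed = 12, n_snps = 4000L, frac_as = 1)
  b <- generate_bundle(cfg)
  dev <- abs(b$truth$true_theta - 0.5)
  rare <- b$truth$af < 0.01
  expect_gt(mean(dev[rare]), mean(dev[!rare]))
})

test_that("region generation respects geometry and capacity", {
  cfg0 <- simulation_config(seed = 2)
  reg0 <- generate_cnv_and_mask_regions(cfg0)
  expect_equal(nrow(reg0$cnvs), 0L)
  expect_equal(nrow(reg0$gaps), 0L)

  # over-capacity request errors
  cfg_big <- simulation_config(
    seed = 2, chrom_sizes = c(chr1 = 1e6),
    cnv_config = list(n_regions = 50, copy_numbers = 3L,
                      frac_haplotype_resolved = 1, region_length = 1e5)
  )
  expect_error(generate_cnv_and_mask_regions(cfg_big), "slots")

  # generated regions are mutually disjoint
  cfg <- simulation_config(
    seed = 4,
    cnv_config = list(n_regions = 10, copy_numbers = c(2L, 3L, 4L),
                      frac_haplotype_resolved = 0.5, region_length = 1e5),
    mask_config = list(n_gap = 5, n_blacklist = 5, gap_length = 5e4,
                       blacklist_length = 1000)
  )
  reg <- generate_cnv_and_mask_regions(cfg)
  all_iv <- rbind(reg$cnvs[c("chrom", "start", "end")],
                  reg$gaps[c("chrom", "start", "end")],
                  reg$blacklist[c("chrom", "start", "end")])
  merged <- merge_intervals(genomic_intervals(all_iv$chrom, all_iv$start,
                                              all_iv$end))
  expect_equal(sum(merged$end - merged$start),
               sum(all_iv$end - all_iv$start))

  # all-diploid CNVs leave every SNP on the standard null downstream
  cfg2 <- simulation_config(
    seed = 6, n_snps = 300,
    cnv_config = list(n_regions = 5, copy_numbers = 2L,
                      frac_haplotype_resolved = 1, region_length = 1e5)
  )
  b2 <- generate_bundle(cfg2)
  ns <- resolve_null(b2$snps, b2$cnvs)
  expect_true(all(ns$verdict == "testable"))
  expect_true(all(ns$null_p == 0.5))
})

test_that("planted proxy links respect the strict r2 > 0.8 boundary downstream", {
  catalog <- data.frame(snp_id = "cat1", trait = "t", source = "gwas",
                        chrom = "chr1", pos = 100L, stringsAsFactors = FALSE)
  proxies <- data.frame(index_snp_id = "cat1",
                        proxy_snp_id = c("rs_in", "rs_out"),
                        r2 = c(0.81, 0.80), stringsAsFactors = FALSE)
  exp <- expand_with_proxies(catalog, proxies, threshold = 0.8)
  expect_true("rs_in" %in% exp$snp_id)
  expect_false("rs_out" %in% exp$snp_id)
})
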