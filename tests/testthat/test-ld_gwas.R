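test_that("r-squared matches the direct contingency computation", {
  # perfect co-inheritance
  expect_equal(r_squared(c("A", "A", "a", "a"), c("B", "B", "b", "b")), 1.0)
  # independence at equal frequencies
  expect_equal(r_squared(c("A", "A", "a", "a"), c("B", "b", "B", "b")), 0.0)
  # 8 haplotypes {AB x3, Ab x1, aB x1, ab x3}: D = 0.125, r2 = 0.25
  ha <- rep(c("A", "A", "a", "a"), c(3, 1, 1, 3))
  hb <- rep(c("B", "b", "B", "b"), c(3, 1, 1, 3))
  expect_equal(r_squared(ha, hb), 0.25)
  # symmetry and allele-relabeling invariance
  expect_equal(r_squared(hb, ha), 0.25)
  expect_equal(r_squared(chartr("Aa", "Tt", ha), hb), 0.25)
  expect_error(r_squared(rep("A", 4), c("B", "b", "B", "b")), "monomorphic")
})

test_that("proxy expansion is strict at the threshold and keeps the index", {
  catalog <- data.frame(snp_id = c("g1", "g2"), trait = c("t1", "t2"),
                        source = "gwas", chrom = "chr1",
                        pos = c(100L, 5000L), stringsAsFactors = FALSE)
  proxies <- data.frame(
    index_snp_id = c("g1", "g1", "g2", "nope"),
    proxy_snp_id = c("p80", "p81", "p95", "px"),
    r2 = c(0.80, 0.81, 0.95, 0.9), stringsAsFactors = FALSE
  )
  expect_warning(exp <- expand_with_proxies(catalog, proxies), "unknown index")
  expect_true(all(c("g1", "g2") %in% exp$snp_id[exp$is_index]))
  expect_true("p81" %in% exp$snp_id)
  expect_false("p80" %in% exp$snp_id)
  expect_true(all(exp$r2 > 0.8))

  # no proxies: each association contains only its index
  solo <- expand_with_proxies(catalog, NULL)
  expect_equal(nrow(solo), 2L)
  expect_true(all(solo$is_index))
})

test_that("catalog intersection separates direct from LD-linked hits", {
  catalog <- data.frame(snp_id = c("g1", "g2"), trait = "t", source = "gwas",
                        chrom = "chr1", pos = c(100L, 900L),
                        stringsAsFactors = FALSE)
  proxies <- data.frame(index_snp_id = c("g1", "g2"),
                        proxy_snp_id = c("as1", "as1"),
                        r2 = c(0.9, 0.85), stringsAsFactors = FALSE)
  exp <- expand_with_proxies(catalog, proxies)
  net <- intersect_as_with_catalog(c("g1", "as1", "far"), exp)
  expect_equal(net$n_direct_hits, 1L)
  expect_equal(net$n_ld_hits, 1L)
  # as1 tags both association signals: degree 2
  expect_equal(unname(net$as_degree[["as1"]]), 2L)

  empty <- intersect_as_with_catalog("nothing", exp)
  expect_equal(empty$n_direct_hits + empty$n_ld_hits, 0L)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("locus grouping chains index SNPs within the window", {
  hits <- data.frame(
    snp_id = c("a", "b", "c", "d"),
    trait = "t", chrom = "chr1",
    pos = c(1000000L, 1900000L, 5000000L, 100L),
    stringsAsFactors = FALSE
  )
  loci <- group_into_loci(hits, window = 1e6)
  # d(100) + a(1 Mb) + b(1.9 Mb) chain (gaps <= 1 Mb); c is 3.1 Mb further
  expect_equal(nrow(loci), 2L)
  expect_equal(loci$n_members, c(3L, 1L))
  expect_equal(loci$end[2], 5000001)

  single <- group_into_loci(hits[1, ])
  expect_equal(single$end - single$start, 1)

  # invariant to input order; loci non-increasing with window size
  shuffled <- hits[c(3, 1, 4, 2), ]
  expect_equal(group_into_loci(shuffled), loci)
  expect_lte(nrow(group_into_loci(hits, window = 5e6)), nrow(loci))
})

test_that("permutation enrichment obeys the add-one floor and saturation", {
  # AS wholly inside target, pool wholly outside: exact floor
  as_ids <- paste0("as", 1:50)
  pool <- paste0("pool", 1:500)
  res <- permutation_enrichment(as_ids, pool, target_ids = as_ids,
                                n_permutations = 999, seed = 4)
  expect_equal(res$empirical_p, 1 / 1000)
  expect_true(res$zero_null)
  expect_equal(res$fold, Inf)

  # target containing everything: fold 1, p ~ 1
  all_ids <- c(as_ids, pool)
  sat <- permutation_enrichment(as_ids, pool, target_ids = all_ids,
                                n_permutations = 200, seed = 4)
  expect_equal(sat$fold, 1)
  expect_equal(sat$empirical_p, 1)

  # reproducible bit-for-bit under seed
  r1 <- permutation_enrichment(as_ids, pool, target_ids = pool[1:100],
                               n_permutations = 300, seed = 11)
  r2 <- permutation_enrichment(as_ids, pool, target_ids = pool[1:100],
                               n_permutations = 300, seed = 11)
  expect_identical(r1$null_overlaps, r2$null_overlaps)
  expect_gt(r1$empirical_p, 0)

  expect_error(permutation_enrichment(pool, as_ids, target_ids = pool,
                                      n_permutations = 10, seed = 1),
               "smaller than the AS set")
})

test_that("AF-matched permutation draws respect decile composition", {
  freq <- data.frame(snp_id = c(paste0("as", 1:20), paste0("p", 1:200)),
                     af = c(rep(0.005, 10), rep(0.55, 10),
                            rep(c(0.005, 0.55), 100)))
  as_ids <- paste0("as", 1:20)
  pool <- paste0("p", 1:200)
  res <- permutation_enrichment(as_ids, pool, target_ids = pool[1:50],
                                n_permutations = 50, seed = 2,
                                matching = "af_matched",
                                frequency_table = freq)
  expect_length(res$null_overlaps, 50L)
  expect_error(
    permutation_enrichment(as_ids, pool, target_ids = pool,
                           n_permutations = 10, seed = 1,
                           matching = "af_matched"),
    "frequency_table"
  )
})

test_that("interval targets map to contained SNP ids", {
  snps <- make_snps(3, pos = c(100L, 500L, 900L))
  iv <- genomic_intervals("chr1", 400, 600)
  expect_equal(snps_in_intervals(snps, iv), "rs2")
})
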