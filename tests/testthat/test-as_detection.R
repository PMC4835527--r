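test_that("exact two-sided p-value matches enumeration oracle on spot cases", {
  expect_equal(binom_p_two_sided(16, 16, 0.5), 1.0)
  # frozen from the enumeration oracle: 2 * sum_{k=20..24} C(24,k)/2^24
  # = 25902/16777216
  expect_equal(binom_p_two_sided(20, 4, 0.5), 0.001543879508972168,
               tolerance = 1e-12)
  expect_equal(binom_p_two_sided(20, 4, 0.5), oracle_binom_p(20, 4, 0.5))
  # 16:8 is exactly the 2:1 adjusted null; p near 1
  p_adj <- binom_p_two_sided(16, 8, 2 / 3)
  expect_equal(p_adj, oracle_binom_p(16, 8, 2 / 3))
  expect_gt(p_adj, 0.9)
})

test_that("p-values agree with stats::binom.test under the symmetric null", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    g1 <- sample(seq_len(n - 1), 1)
    expect_equal(binom_p_two_sided(g1, n - g1, 0.5),
                 stats::binom.test(g1, n, 0.5)$p.value, tolerance = 1e-12)
  }
})

test_that("p-value is invariant under allele relabeling and monotone in imbalance", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(3:120, 1)
    g1 <- sample(seq_len(n - 1), 1)
    p0 <- sample(c(1 / 3, 1 / 2, 2 / 3, 0.2), 1)
    expect_equal(binom_p_two_sided(g1, n - g1, p0),
                 binom_p_two_sided(n - g1, g1, 1 - p0), tolerance = 1e-12)
  }
  # fixed depth, symmetric null: p non-increasing in |g1 - g2|
  n <- 40L
  g1 <- 20:39
  p <- binom_p_two_sided(g1, n - g1, 0.5)
  expect_true(all(diff(p) <= 1e-12))
})

test_that("testing rejects zero-allele records and invalid nulls", {
  expect_error(binom_p_two_sided(0, 25, 0.5), "discarded")
  expect_error(binom_p_two_sided(5, 5, 1), "null_p")
  expect_error(binom_p_two_sided(-1, 5, 0.5), "non-negative")
})

test_that("CNV null resolution covers every verdict class", {
  snps <- make_snps(6, pos = c(100L, 1100L, 2100L, 3100L, 4100L, 5100L))
  cnvs <- rbind(
    make_cnv("chr1", 1000, 2000, 2L),              # diploid region
    make_cnv("chr1", 2000, 3000, 3L, "g2"),        # resolved, g2 duplicated
    make_cnv("chr1", 3000, 4000, 3L),              # unresolved 3-copy
    make_cnv("chr1", 4000, 5000, 4L),              # high copy
    make_cnv("chr1", 5000, 6000, NA_integer_)      # ungenotyped
  )
  ns <- resolve_null(snps, cnvs)
  expect_equal(ns$verdict,
               c("testable", "testable", "testable",
                 "excluded_unresolved_cnv", "excluded_high_copy",
                 "excluded_ungenotyped_cnv"))
  expect_equal(ns$null_p, c(0.5, 0.5, 1 / 3, NA, NA, NA))

  # g1-duplicated region flips the null to 2/3
  ns2 <- resolve_null(make_snps(1, pos = 1500L),
                      make_cnv("chr1", 1000, 2000, 3L, "g1"))
  expect_equal(ns2$null_p, 2 / 3)

  # conflicting overlapping copy numbers are an error
  over <- rbind(make_cnv("chr1", 0, 1000, 2L), make_cnv("chr1", 0, 1000, 4L))
  expect_error(resolve_null(make_snps(1, pos = 10L), over), "conflicting")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("AS calling discards zero-allele records and finds a strong planted signal", {
  set.seed(3)
  # one strongly imbalanced SNP (theta = 0.9, depth 50) in 3 datasets,
  # against a background of balanced SNPs
  n_bg <- 200L
  counts <- data.frame(
    snp_id = rep(c("hit", paste0("bg", seq_len(n_bg))), each = 3),
    dataset_id = rep(paste0("TF", 1:3), n_bg + 1L),
    stringsAsFactors = FALSE
  )
  depth <- 50L
  is_hit <- counts$snp_id == "hit"
  counts$g1_count <- rbinom(nrow(counts), depth, ifelse(is_hit, 0.9, 0.5))
  counts$g2_count <- depth - counts$g1_count
  counts$g2_count[counts$g1_count == depth] <- 0L
  zero_row <- data.frame(snp_id = "zz", dataset_id = "TF1",
                         g1_count = 0L, g2_count = 25L)
  counts <- rbind(counts, zero_row)
  ns <- data.frame(snp_id = unique(counts$snp_id), null_p = 0.5,
                   verdict = "testable", stringsAsFactors = FALSE)
  res <- call_as_snps(counts, ns, alpha = 0.05)
  expect_equal(res$n_zero_discarded, 1L)
  expect_false("zz" %in% res$results$snp_id)
  expect_true("hit" %in% res$as_snps)

  expect_error(call_as_snps(counts, ns, alpha = 0), "alpha")
  expect_error(call_as_snps(counts, ns[-1, ]), "without a null specification")
})

test_that("per-dataset and global BH families are both available and differ", {
  set.seed(8)
  counts <- data.frame(
    snp_id = rep(paste0("s", 1:50), 2),
    dataset_id = rep(c("TFa", "TFb"), each = 50),
    g1_count = rbinom(100, 30, 0.5) + 1L,
    g2_count = 0L, stringsAsFactors = FALSE
  )
  counts$g2_count <- pmax(31L - counts$g1_count, 1L)
  ns <- data.frame(snp_id = unique(counts$snp_id), null_p = 0.5,
                   verdict = "testable", stringsAsFactors = FALSE)
  per <- call_as_snps(counts, ns, bh_family = "per_dataset")$results
  glob <- call_as_snps(counts, ns, bh_family = "global")$results
  expect_equal(per$p_value, glob$p_value)
  expect_false(isTRUE(all.equal(per$q_value, glob$q_value)))
})
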