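#' Exact two-sided binomial p-value (minimum-likelihood method)
#'
#' For observed allelic counts `(g1, g2)` with `n = g1 + g2` and a null
#' proportion `null_p` for the G1 allele, the two-sided p-value sums the
#' probabilities of every outcome at most as likely as the observed one:
#' `p = sum over k of Pr(X = k)` for all `k` with
#' `Pr(X = k) <= Pr(X = g1) * (1 + 1e-12)`, `X ~ Binomial(n, null_p)`.
#' The `1e-12` relative slack guards floating-point ties. For the symmetric
#' null `null_p = 0.5` this equals the doubled smaller tail, capped at 1;
#' for the copy-number-adjusted nulls 1/3 and 2/3 it is the standard exact
#' two-sided construction for asymmetric binomials.
#'
#' @param g1,g2 Non-negative integer read counts on the reference (G1) and
#'   alternative (G2) allele. Vectorized; recycled against each other.
#' @param null_p Null proportion(s) for the G1 allele, strictly inside (0, 1).
#' @return Numeric vector of p-values in (0, 1].
#' @export
binom_p_two_sided <- function(g1, g2, null_p = 0.5) {
  m <- max(length(g1), length(g2), length(null_p))
  g1 <- rep_len(as.numeric(g1), m)
  g2 <- rep_len(as.numeric(g2), m)
  null_p <- rep_len(as.numeric(null_p), m)
  if (any(g1 < 0 | g2 < 0 | g1 != floor(g1) | g2 != floor(g2))) {
    stop("g1 and g2 must be non-negative integers")
  }
  if (any(null_p <= 0 | null_p >= 1)) stop("null_p must be strictly inside (0, 1)")
  n <- g1 + g2
  if (any(n < 2 | g1 < 1 | g2 < 1)) {
    stop("records with g1 = 0 or g2 = 0 must be discarded before testing")
  }

  out <- numeric(m)
  key <- paste(n, signif(null_p, 15))
  for (k in unique(key)) {
    idx <- which(key == k)
    nn <- n[idx[1L]]
    p0 <- null_p[idx[1L]]
    pmf <- stats::dbinom(0:nn, nn, p0)
    ord <- order(pmf)
    sorted <- pmf[ord]
    cs <- cumsum(sorted)
    # per observed g1: include all outcomes with pmf <= pmf(obs) * (1 + eps)
    pobs <- pmf[g1[idx] + 1L]
    ranks <- findInterval(pobs * (1 + 1e-12), sorted)
    out[idx] <- pmin(cs[ranks], 1)
  }
  out
}

#' Resolve the binomial null proportion per SNP from CNV annotation
#'
#' A SNP outside every CNV, or inside a 2-copy region, keeps the diploid null
#' `p = 1/2`. Inside a haplotype-resolved 3-copy region the duplicated allele
#' sits in a 2:1 ratio, so the null shifts to `2/3` (G1 duplicated) or `1/3`
#' (G2 duplicated). A SNP inside an unresolved 3-copy region, a region of 4 or
#' more copies, or a CNV whose copy number was never genotyped is excluded
#' from testing; the verdict records why.
#'
#' @param snps Heterozygous-SNP `data.frame` (see [read_het_snps()]).
#' @param cnvs CNV `data.frame` (see [read_cnv_table()]), or `NULL` for none.
#'   Regions must not overlap each other with conflicting copy numbers.
#' @return `data.frame` with columns `snp_id`, `null_p` (`NA` when excluded)
#'   and `verdict` (one of `testable`, `excluded_unresolved_cnv`,
#'   `excluded_high_copy`, `excluded_ungenotyped_cnv`).
#' @export
resolve_null <- function(snps, cnvs = NULL) {
  out <- data.frame(
    snp_id = snps$snp_id,
    null_p = 0.5,
    verdict = "testable",
    stringsAsFactors = FALSE
  )
  if (is.null(cnvs) || nrow(cnvs) == 0L) return(out)

  hits <- GenomicRanges::findOverlaps(
    positions_to_granges(snps$chrom, snps$pos),
    intervals_to_granges(cnvs)
  )
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    dup <- unique(qh[duplicated(qh)])
    for (q in dup) {
      cns <- cnvs$copy_number[sh[qh == q]]
      if (length(unique(cns[!is.na(cns)])) > 1L || anyNA(cns)) {
        stop("SNP ", snps$snp_id[q],
             " overlaps CNV regions with conflicting copy numbers")
      }
    }
  }
  first <- !duplicated(qh)
  qi <- qh[first]
  ci <- sh[first]
  cn <- cnvs$copy_number[ci]
  resolved <- cnvs$haplotype_resolved[ci]
  dup_hap <- cnvs$duplicated_haplotype[ci]

  verdict <- rep("testable", length(qi))
  null_p <- rep(0.5, length(qi))
  verdict[is.na(cn)] <- "excluded_ungenotyped_cnv"
  high <- !is.na(cn) & cn >= 4L
  verdict[high] <- "excluded_high_copy"
  three <- !is.na(cn) & cn == 3L
  verdict[three & !resolved] <- "excluded_unresolved_cnv"
  null_p[three & resolved] <- ifelse(dup_hap[three & resolved] == "g1", 2 / 3, 1 / 3)
  null_p[verdict != "testable"] <- NA_real_

  out$null_p[qi] <- null_p
  out$verdict[qi] <- verdict
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment
#' (`stats::p.adjust(method = "BH")`), exposed under the pipeline's own name.
#'
#' @param p_values Numeric vector of p-values in \\[0, 1\\].
#' @return Adjusted q-values in input order; empty input gives empty output.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call allele-specific SNPs from allelic counts
#'
#' The statistical core of the pipeline. Records with zero reads on either
#' allele are discarded (uninformative for allelic analysis), records whose
#' SNP fell in an excluded CNV class are dropped, and every surviving
#' (SNP, dataset) pair is tested with [binom_p_two_sided()] against its
#' CNV-adjusted null. Benjamini-Hochberg correction is applied within each
#' dataset family by default (each ChIP-seq experiment is its own test
#' family), or globally across all pairs. A SNP is an AS-SNP when its
#' q-value is strictly below `alpha` in at least one dataset.
#'
#' @param counts Allelic counts `data.frame` (see [read_counts_table()]).
#' @param nullspecs Null-specification `data.frame` from [resolve_null()].
#'   Every counted SNP must be present.
#' @param alpha Significance level on the q-value scale, in (0, 1).
#' @param bh_family `"per_dataset"` (default) or `"global"` correction family.
#' @return A list with elements:
#'   \describe{
#'     \item{results}{per-test `data.frame`: `snp_id`, `dataset_id`,
#'       `g1_count`, `g2_count`, `null_p`, `p_value`, `q_value`,
#'       `significant`.}
#'     \item{as_snps}{character vector of AS-SNP ids (significant in >= 1
#'       dataset).}
#'     \item{n_zero_discarded}{records dropped for a zero-count allele.}
#'     \item{n_cnv_excluded}{records dropped for a non-testable CNV verdict.}
#'   }
#' @export
call_as_snps <- function(counts, nullspecs, alpha = 0.05,
                         bh_family = c("per_dataset", "global")) {
  bh_family <- match.arg(bh_family)
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value strictly inside (0, 1)")
  }
  miss <- setdiff(counts$snp_id, nullspecs$snp_id)
  if (length(miss) > 0L) {
    stop("counted SNP(s) without a null specification: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }

  zero <- counts$g1_count == 0L | counts$g2_count == 0L
  n_zero <- sum(zero)
  x <- counts[!zero, , drop = FALSE]

  i <- match(x$snp_id, nullspecs$snp_id)
  testable <- nullspecs$verdict[i] == "testable"
  n_cnv <- sum(!testable)
  x <- x[testable, , drop = FALSE]
  x$null_p <- nullspecs$null_p[i][testable]

  if (nrow(x) > 0L) {
    x$p_value <- binom_p_two_sided(x$g1_count, x$g2_count, x$null_p)
    if (bh_family == "per_dataset") {
      x$q_value <- stats::ave(x$p_value, x$dataset_id, FUN = bh_adjust)
    } else {
      x$q_value <- bh_adjust(x$p_value)
    }
    x$significant <- x$q_value < alpha
  } else {
    x$p_value <- numeric(0)
    x$q_value <- numeric(0)
    x$significant <- logical(0)
  }
  rownames(x) <- NULL
  list(
    results = x,
    as_snps = sort(unique(x$snp_id[x$significant])),
    n_zero_discarded = n_zero,
    n_cnv_excluded = n_cnv
  )
}
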