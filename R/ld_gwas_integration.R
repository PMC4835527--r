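#' Squared linkage-disequilibrium correlation between two sites
#'
#' `r^2 = D^2 / (p_A p_a p_B p_b)` with `D = p_AB - p_A p_B`, computed from
#' phased haplotypes. Symmetric in the two sites and invariant under allele
#' relabeling.
#'
#' @param hap_a,hap_b Vectors of equal length giving, per haplotype, the
#'   allele carried at site A and site B. Any two distinct values per site;
#'   both sites must be polymorphic in the sample.
#' @return `r^2` in \\[0, 1\\].
#' @export
r_squared <- function(hap_a, hap_b) {
  if (length(hap_a) != length(hap_b)) stop("haplotype vectors differ in length")
  if (length(hap_a) < 2L) stop("need at least 2 haplotypes")
  ua <- unique(hap_a)
  ub <- unique(hap_b)
  if (length(ua) != 2L || length(ub) != 2L) {
    stop("r^2 is undefined for a monomorphic (or multi-allelic) site")
  }
  pa <- mean(hap_a == ua[1L])
  pb <- mean(hap_b == ub[1L])
  pab <- mean(hap_a == ua[1L] & hap_b == ub[1L])
  d <- pab - pa * pb
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  min(max(r2, 0), 1)
}

#' Expand a GWAS/eQTL catalog with LD proxies
#'
#' Each catalog (index) SNP is expanded into the set of SNPs statistically
#' interchangeable with it: proxies with `r2` strictly above `threshold`,
#' plus the index SNP itself (by convention `r2 = 1`). Proxy records whose
#' index SNP is not in the catalog are dropped with a warning.
#'
#' @param catalog Catalog `data.frame` (see [read_catalog_table()]).
#' @param proxy_table Proxy `data.frame` (see [read_proxy_table()]), or
#'   `NULL` for none.
#' @param threshold LD threshold in \\[0, 1); membership requires
#'   `r2 > threshold` (strict).
#' @return Long-format `data.frame` of expanded associations: one row per
#'   (index, member) pair with columns `index_snp_id`, `trait`, `source`,
#'   `snp_id`, `r2`, `is_index`.
#' @export
expand_with_proxies <- function(catalog, proxy_table = NULL, threshold = 0.8) {
  if (length(threshold) != 1L || threshold < 0 || threshold >= 1) {
    stop("threshold must be a single value in [0, 1)")
  }
  self_rows <- data.frame(
    index_snp_id = catalog$snp_id,
    trait = catalog$trait,
    source = catalog$source,
    snp_id = catalog$snp_id,
    r2 = 1,
    is_index = TRUE,
    stringsAsFactors = FALSE
  )
  if (is.null(proxy_table) || nrow(proxy_table) == 0L) return(self_rows)

  known <- proxy_table$index_snp_id %in% catalog$snp_id
  if (any(!known)) {
    warning("dropped ", sum(!known),
            " proxy record(s) referencing unknown index SNP(s)")
    proxy_table <- proxy_table[known, , drop = FALSE]
  }
  keep <- proxy_table$r2 > threshold &
    proxy_table$proxy_snp_id != proxy_table$index_snp_id
  px <- proxy_table[keep, , drop = FALSE]
  i <- match(px$index_snp_id, catalog$snp_id)
  proxy_rows <- data.frame(
    index_snp_id = px$index_snp_id,
    trait = catalog$trait[i],
    source = catalog$source[i],
    snp_id = px$proxy_snp_id,
    r2 = px$r2,
    is_index = FALSE,
    stringsAsFactors = FALSE
  )
  out <- rbind(self_rows, proxy_rows)
  rownames(out) <- NULL
  out
}

#' Intersect AS-SNPs with proxy-expanded associations
#'
#' Classifies every AS-SNP touching the expanded catalog as a direct hit
#' (it *is* an index SNP) or an LD-linked hit (member of at least one
#' expansion without being an index SNP), and keeps the full edge list so
#' many-to-many topologies (one AS-SNP tagging several association signals,
#' or one signal tagged by several AS-SNPs) stay visible.
#'
#' @param as_snp_ids Character vector of AS-SNP ids.
#' @param expanded Expanded associations from [expand_with_proxies()].
#' @return A list with `n_direct_hits`, `n_ld_hits`, `edges` (`data.frame`:
#'   `as_snp`, `index_snp`, `r2`, `trait`, `source`), `as_degree` and
#'   `index_degree` (named integer vectors: edges per AS-SNP / per index
#'   SNP).
#' @export
intersect_as_with_catalog <- function(as_snp_ids, expanded) {
  hit <- expanded[expanded$snp_id %in% as_snp_ids, , drop = FALSE]
  edges <- data.frame(
    as_snp = hit$snp_id,
    index_snp = hit$index_snp_id,
    r2 = hit$r2,
    trait = hit$trait,
    source = hit$source,
    stringsAsFactors = FALSE
  )
  rownames(edges) <- NULL
  index_ids <- unique(expanded$index_snp_id)
  touched <- unique(edges$as_snp)
  direct <- intersect(touched, index_ids)
  ld_only <- setdiff(touched, index_ids)
  list(
    n_direct_hits = length(direct),
    n_ld_hits = length(ld_only),
    direct_hits = sort(direct),
    ld_hits = sort(ld_only),
    edges = edges,
    as_degree = if (nrow(edges)) table(edges$as_snp) else table(character(0)),
    index_degree = if (nrow(edges)) table(edges$index_snp) else table(character(0))
  )
}

#' Group catalog hits into loci by positional chaining
#'
#' Single-linkage chaining per trait and chromosome: consecutive index SNPs
#' at most `window` bp apart join the same locus; the locus span runs from
#' the first to one past the last member position.
#'
#' @param hits `data.frame` with columns `snp_id`, `trait`, `chrom`, `pos`
#'   (0-based).
#' @param window Maximum gap between consecutive members, in bp (default
#'   1 Mb).
#' @return `data.frame` with columns `trait`, `chrom`, `start`, `end`,
#'   `n_members`, `member_snp_ids` (comma-separated). Invariant to input
#'   order.
#' @export
group_into_loci <- function(hits, window = 1e6) {
  if (nrow(hits) == 0L) {
    return(data.frame(trait = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_members = integer(0), member_snp_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$trait, hits$chrom, hits$pos, hits$snp_id), , drop = FALSE]
  hits <- hits[!duplicated(hits[c("trait", "snp_id")]), , drop = FALSE]
  out <- list()
  for (grp in split(hits, list(hits$trait, hits$chrom), drop = TRUE)) {
    gap <- c(Inf, diff(grp$pos))
    locus <- cumsum(gap > window)
    for (l in split(grp, locus)) {
      out[[length(out) + 1L]] <- data.frame(
        trait = l$trait[1L], chrom = l$chrom[1L],
        start = min(l$pos), end = max(l$pos) + 1,
        n_members = nrow(l),
        member_snp_ids = paste(l$snp_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$trait, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation enrichment of AS-SNPs in a target set
#'
#' Draws matched random sets of non-AS heterozygous SNPs of the same size as
#' the AS set (optionally matched on allele-frequency decile) and compares
#' their overlap with the target to the observed AS overlap. The empirical
#' p-value uses the add-one convention
#' `(1 + #permutations with overlap >= observed) / (1 + n_permutations)`,
#' so it can never be exactly zero; fold enrichment is
#' `observed / mean(null overlaps)`.
#'
#' @param as_snp_ids Character vector of AS-SNP ids.
#' @param pool Character vector of candidate (non-AS heterozygous) SNP ids;
#'   must be at least as large as the AS set.
#' @param target_ids Character vector defining the target set membership
#'   (e.g. SNPs inside a proxy-expanded catalog, or inside an interval set —
#'   see [snps_in_intervals()]).
#' @param n_permutations Number of random sets (>= 1).
#' @param seed Integer RNG seed; results are reproducible bit-for-bit.
#' @param matching `"count_only"` (default) or `"af_matched"` (draws respect
#'   the AF-decile composition of the AS set; requires `frequency_table`).
#' @param frequency_table Allele-frequency `data.frame`; needed for
#'   `af_matched` (SNPs without a catalogued AF form their own stratum).
#' @return A list of class `enrichment_result`: `observed_overlap`,
#'   `null_overlaps` (integer vector of length `n_permutations`), `fold`
#'   (`Inf` with `zero_null` flag when the null mean is 0), `empirical_p`,
#'   `n_permutations`, `seed`.
#' @export
permutation_enrichment <- function(as_snp_ids, pool, target_ids,
                                   n_permutations = 1000L, seed = 1L,
                                   matching = c("count_only", "af_matched"),
                                   frequency_table = NULL) {
  matching <- match.arg(matching)
  as_snp_ids <- unique(as_snp_ids)
  pool <- unique(pool)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  if (length(pool) < length(as_snp_ids)) {
    stop("candidate pool (", length(pool),
         ") is smaller than the AS set (", length(as_snp_ids), ")")
  }
  in_target <- function(ids) sum(ids %in% target_ids)
  observed <- in_target(as_snp_ids)
  k <- length(as_snp_ids)

  if (matching == "af_matched") {
    if (is.null(frequency_table)) {
      stop("af_matched matching requires a frequency_table")
    }
    stratum <- function(ids) {
      af <- frequency_table$af[match(ids, frequency_table$snp_id)]
      dec <- findInterval(af, seq(0, 1, by = 0.1), rightmost.closed = TRUE)
      dec[is.na(af)] <- 0L  # no catalogued AF: own stratum
      dec
    }
    as_strata <- stratum(as_snp_ids)
    pool_strata <- stratum(pool)
    need <- table(as_strata)
    have <- table(factor(pool_strata, levels = names(need)))
    if (any(have < need)) {
      stop("pool too small within AF stratum(ia): ",
           paste(names(need)[have < need], collapse = ", "))
    }
    pool_by <- split(pool, pool_strata)
  }

  null_overlaps <- integer(n_permutations)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (b in seq_len(n_permutations)) {
    draw <- if (matching == "count_only") {
      sample(pool, k, replace = FALSE)
    } else {
      unlist(lapply(names(need), function(s) {
        sample(pool_by[[s]], need[[s]], replace = FALSE)
      }), use.names = FALSE)
    }
    null_overlaps[b] <- in_target(draw)
  }
  null_mean <- mean(null_overlaps)
  zero_null <- null_mean == 0
  structure(
    list(
      observed_overlap = observed,
      null_overlaps = null_overlaps,
      fold = if (zero_null) Inf else observed / null_mean,
      zero_null = zero_null,
      empirical_p = (1 + sum(null_overlaps >= observed)) / (1 + n_permutations),
      n_permutations = as.integer(n_permutations),
      seed = as.integer(seed)
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Permutation enrichment (", x$n_permutations, " permutations, seed ",
      x$seed, ")\n", sep = "")
  cat("  observed overlap:", x$observed_overlap, "\n")
  cat("  null mean overlap:", format(mean(x$null_overlaps), digits = 4), "\n")
  cat("  fold enrichment:", format(x$fold, digits = 4),
      if (x$zero_null) "(zero null mean)" else "", "\n")
  cat("  empirical p:", format(x$empirical_p, digits = 4), "\n")
  invisible(x)
}

#' SNP ids whose position falls inside an interval set
#'
#' Convenience bridge for interval-valued enrichment targets (e.g.
#' super-enhancer collections).
#'
#' @param snps Heterozygous-SNP `data.frame` (`snp_id`, `chrom`, `pos`).
#' @param intervals Interval `data.frame`.
#' @return Character vector of contained SNP ids.
#' @export
snps_in_intervals <- function(snps, intervals) {
  snps$snp_id[points_in_intervals(snps$chrom, snps$pos, intervals)]
}
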