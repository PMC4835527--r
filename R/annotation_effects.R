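#' Classify SNPs as common or rare by allele frequency
#'
#' A SNP is `common` when its population allele frequency is at least 1%
#' (`af >= 0.01`); it is `rare` when `af < 0.01` *or* when it is absent from
#' the frequency table altogether — a variant never catalogued in the
#' reference panel is treated as rare, not as frequency zero.
#'
#' @param snp_ids Character vector of SNP ids.
#' @param frequency_table `data.frame` with columns `snp_id`, `af`
#'   (see [read_frequency_table()]).
#' @param common_threshold Frequency at and above which a SNP is common.
#' @return Character vector (`"common"`/`"rare"`), one per input id.
#' @export
classify_frequency <- function(snp_ids, frequency_table,
                               common_threshold = 0.01) {
  af <- frequency_table$af[match(snp_ids, frequency_table$snp_id)]
  ifelse(!is.na(af) & af >= common_threshold, "common", "rare")
}

#' Allele-specific effect ratio
#'
#' The fraction of reads supporting the stronger allele,
#' `max(g1, g2) / (g1 + g2)`: 0.5 means perfect balance, values near 1 mean
#' near-complete allelic imbalance.
#'
#' @param g1,g2 Integer read counts, both at least 1 (zero-allele records
#'   never reach this stage). Vectorized.
#' @return Numeric ratios in \\[0.5, 1\\].
#' @export
as_effect_ratio <- function(g1, g2) {
  if (any(g1 < 1 | g2 < 1)) {
    stop("effect ratio requires at least one read on each allele")
  }
  pmax(g1, g2) / (g1 + g2)
}

#' Compare allele-specific effects between common and rare AS-SNPs
#'
#' Welch's unequal-variance two-tailed t test on per-SNP effect ratios
#' (one ratio per AS-SNP). A positive t statistic means the rare group has
#' the larger mean imbalance.
#'
#' @param common_ratios,rare_ratios Numeric vectors of effect ratios, each
#'   with at least 2 values.
#' @return A list with `t_statistic`, `p_value`, `mean_common`, `mean_rare`,
#'   `df`.
#' @export
compare_common_rare_effects <- function(common_ratios, rare_ratios) {
  if (length(common_ratios) < 2L || length(rare_ratios) < 2L) {
    stop("each group needs at least 2 effect ratios")
  }
  if (stats::sd(common_ratios) == 0 && stats::sd(rare_ratios) == 0) {
    stop("both groups have zero variance; t test is undefined")
  }
  tt <- stats::t.test(rare_ratios, common_ratios, var.equal = FALSE)
  list(
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    mean_common = mean(common_ratios),
    mean_rare = mean(rare_ratios),
    df = unname(tt$parameter)
  )
}

#' Cross-cell-line sharing of heterozygous and AS-SNPs
#'
#' Counts, for each universe (all heterozygous SNPs; AS-SNPs), how many SNPs
#' occur in exactly 1, 2, ..., k of the k cell lines, and contrasts the two
#' multiplicity distributions with a Pearson chi-square test. Functional
#' (AS) sites being mostly private to one cell line while heterozygosity is
#' widely shared shows up as a large statistic.
#'
#' @param het_sets Named list (one element per cell line) of heterozygous
#'   SNP-id character vectors.
#' @param as_sets Named list with the same names, AS-SNP ids; each must be a
#'   subset of the corresponding heterozygous set.
#' @return A list with `het_histogram` and `as_histogram` (counts indexed by
#'   multiplicity 1..k), `chisq_statistic`, `p_value`.
#' @export
cross_cell_sharing <- function(het_sets, as_sets) {
  if (!identical(sort(names(het_sets)), sort(names(as_sets)))) {
    stop("het_sets and as_sets must cover the same cell lines")
  }
  for (cell in names(as_sets)) {
    extra <- setdiff(as_sets[[cell]], het_sets[[cell]])
    if (length(extra) > 0L) {
      stop("AS-SNP(s) not heterozygous in cell ", cell, ": ",
           paste(utils::head(extra, 5L), collapse = ", "))
    }
  }
  k <- length(het_sets)
  multiplicity_hist <- function(sets) {
    mult <- table(unlist(lapply(sets, unique), use.names = FALSE))
    tab <- table(factor(as.integer(mult), levels = seq_len(k)))
    stats::setNames(as.integer(tab), seq_len(k))
  }
  het_hist <- multiplicity_hist(het_sets)
  as_hist <- multiplicity_hist(as_sets)
  keep <- het_hist + as_hist > 0L
  ct <- suppressWarnings(stats::chisq.test(rbind(het_hist[keep], as_hist[keep])))
  list(het_histogram = het_hist, as_histogram = as_hist,
       chisq_statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Cumulative AS-SNP coverage of the top-k datasets
#'
#' Ranks ChIP-seq datasets (TFs, polymerases, coactivators) by the number of
#' AS-SNPs each detects, and reports the fraction of all AS-SNPs covered by
#' the union of the top k datasets for every k. Ties in detection count are
#' broken lexicographically by dataset id.
#'
#' @param results Per-test `data.frame` from [call_as_snps()]; at least one
#'   row must be significant.
#' @return `data.frame` with columns `rank`, `dataset_id`, `n_detected`,
#'   `n_cumulative` and `coverage` (non-decreasing, reaching 1 at the last
#'   rank).
#' @export
tf_detection_coverage <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant results to rank")
  per <- split(sig$snp_id, sig$dataset_id)
  per <- lapply(per, unique)
  counts <- vapply(per, length, integer(1))
  ord <- order(-counts, names(per))
  per <- per[ord]
  total <- length(unique(sig$snp_id))
  seen <- character(0)
  cum <- integer(length(per))
  for (i in seq_along(per)) {
    seen <- union(seen, per[[i]])
    cum[i] <- length(seen)
  }
  data.frame(
    rank = seq_along(per),
    dataset_id = names(per),
    n_detected = unname(counts[ord]),
    n_cumulative = cum,
    coverage = cum / total,
    stringsAsFactors = FALSE
  )
}

#' Annotate called AS-SNPs
#'
#' One row per AS-SNP: its frequency class, its allele-specific effect ratio
#' taken from the supporting dataset with the smallest q-value (ties broken
#' by total read depth, then dataset id), and per-dataset provenance.
#'
#' @param results Per-test `data.frame` from [call_as_snps()].
#' @param frequency_table Allele-frequency `data.frame`; `NULL` marks every
#'   SNP rare (no catalogued frequency).
#' @param cell_line Cell-line label for the output rows.
#' @param common_threshold Passed to [classify_frequency()].
#' @param best_by `"min_q"` (default) or `"max_depth"`: how the
#'   representative dataset per SNP is chosen.
#' @return `data.frame` with columns `snp_id`, `cell_line`, `freq_class`,
#'   `af`, `effect_ratio`, `best_q`, `best_dataset`,
#'   `n_supporting_datasets`, `dataset_ids` (comma-separated).
#' @export
annotate_as_snps <- function(results, frequency_table = NULL,
                             cell_line = NA_character_,
                             common_threshold = 0.01,
                             best_by = c("min_q", "max_depth")) {
  best_by <- match.arg(best_by)
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(snp_id = character(0), cell_line = character(0),
                      freq_class = character(0), af = numeric(0),
                      effect_ratio = numeric(0), best_q = numeric(0),
                      best_dataset = character(0),
                      n_supporting_datasets = integer(0),
                      dataset_ids = character(0), stringsAsFactors = FALSE))
  }
  depth <- sig$g1_count + sig$g2_count
  ord <- if (best_by == "min_q") {
    order(sig$snp_id, sig$q_value, -depth, sig$dataset_id)
  } else {
    order(sig$snp_id, -depth, sig$q_value, sig$dataset_id)
  }
  sig <- sig[ord, , drop = FALSE]
  first <- !duplicated(sig$snp_id)
  best <- sig[first, , drop = FALSE]

  support <- vapply(split(sig$dataset_id, sig$snp_id), function(d) {
    paste(sort(unique(d)), collapse = ",")
  }, character(1))
  n_support <- vapply(split(sig$dataset_id, sig$snp_id), function(d) {
    length(unique(d))
  }, integer(1))

  af <- if (is.null(frequency_table)) {
    rep(NA_real_, nrow(best))
  } else {
    frequency_table$af[match(best$snp_id, frequency_table$snp_id)]
  }
  freq_class <- if (is.null(frequency_table)) {
    rep("rare", nrow(best))
  } else {
    classify_frequency(best$snp_id, frequency_table, common_threshold)
  }
  out <- data.frame(
    snp_id = best$snp_id,
    cell_line = cell_line,
    freq_class = freq_class,
    af = af,
    effect_ratio = as_effect_ratio(best$g1_count, best$g2_count),
    best_q = best$q_value,
    best_dataset = best$dataset_id,
    n_supporting_datasets = unname(n_support[best$snp_id]),
    dataset_ids = unname(support[best$snp_id]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$snp_id), , drop = FALSE]
}
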