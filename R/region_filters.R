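#' Expand intervals by a symmetric flank and merge overlaps
#'
#' Each interval `[s, e)` becomes `[max(0, s - flank), min(L, e + flank))`
#' where `L` is the chromosome length; overlapping results are merged. This
#' implements the candidate-removal geometry around assembly gaps
#' (conventionally flanked by 1 Mb) and blacklisted regions (flanked by
#' 100 bp).
#'
#' @param intervals Interval `data.frame` (see [genomic_intervals()]).
#' @param flank Non-negative flank size in bp.
#' @param chrom_sizes Named numeric vector of chromosome lengths; every
#'   interval must fit inside its chromosome.
#' @return Merged, expanded interval `data.frame` (labels are dropped by the
#'   merge).
#' @export
expand_intervals <- function(intervals, flank, chrom_sizes) {
  if (length(flank) != 1L || flank < 0) stop("flank must be a single value >= 0")
  if (nrow(intervals) == 0L) return(intervals)
  unknown <- setdiff(intervals$chrom, names(chrom_sizes))
  if (length(unknown) > 0L) {
    stop("interval chromosome(s) missing from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  L <- chrom_sizes[intervals$chrom]
  if (any(intervals$end > L)) {
    stop("interval(s) extend beyond chromosome length")
  }
  expanded <- genomic_intervals(
    chrom = intervals$chrom,
    start = pmax(0, intervals$start - flank),
    end = pmin(L, intervals$end + flank)
  )
  merge_intervals(expanded)
}

#' Merge overlapping or adjacent intervals
#'
#' @param intervals Interval `data.frame`.
#' @return Reduced interval `data.frame` sorted by chromosome and start.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals)
  red <- GenomicRanges::reduce(intervals_to_granges(intervals))
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red)
  )
}

# which SNP positions fall inside any interval (half-open containment)
points_in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0L) return(rep(FALSE, length(chrom)))
  hits <- GenomicRanges::findOverlaps(
    positions_to_granges(chrom, pos),
    intervals_to_granges(intervals)
  )
  seq_along(chrom) %in% S4Vectors::queryHits(hits)
}

#' Apply geometric and CNV region filters to candidate AS-SNPs
#'
#' A SNP is removed by the first matching reason, in the fixed order
#' gap flank, blacklist flank, then CNV exclusion class (ungenotyped,
#' unresolved 3-copy, 4-or-more copies), so that removal attribution is
#' deterministic. Containment uses half-open semantics: a SNP at position
#' `e + flank` of an interval expanded by `flank` is retained. Gap and
#' blacklist intervals must already be expanded by their flanks (see
#' [expand_intervals()]).
#'
#' @param snps Candidate AS-SNP `data.frame` (heterozygous-SNP shape).
#' @param gap_intervals,blacklist_intervals Pre-expanded interval
#'   `data.frame`s; `NULL` means no mask of that kind.
#' @param nullspecs Null-specification `data.frame` from [resolve_null()];
#'   its non-`testable` verdicts drive the CNV removals. `NULL` skips CNV
#'   filtering.
#' @return A list with `retained` (the filtered SNP `data.frame`) and
#'   `report` (a `filter_report`: `input_count`, named `removed_by_reason`
#'   vector, `output_count`; counts always reconcile exactly).
#' @export
apply_region_filters <- function(snps, gap_intervals = NULL,
                                 blacklist_intervals = NULL,
                                 nullspecs = NULL) {
  n_in <- nrow(snps)
  reasons <- c("gap_flank", "blacklist_flank", "ungenotyped_cnv",
               "unresolved_cnv", "high_copy_cnv")
  removed <- stats::setNames(integer(length(reasons)), reasons)

  reason_of <- rep(NA_character_, n_in)
  if (!is.null(gap_intervals)) {
    hit <- points_in_intervals(snps$chrom, snps$pos, gap_intervals)
    reason_of[is.na(reason_of) & hit] <- "gap_flank"
  }
  if (!is.null(blacklist_intervals)) {
    hit <- points_in_intervals(snps$chrom, snps$pos, blacklist_intervals)
    reason_of[is.na(reason_of) & hit] <- "blacklist_flank"
  }
  if (!is.null(nullspecs)) {
    i <- match(snps$snp_id, nullspecs$snp_id)
    verdict <- nullspecs$verdict[i]
    map <- c(excluded_ungenotyped_cnv = "ungenotyped_cnv",
             excluded_unresolved_cnv = "unresolved_cnv",
             excluded_high_copy = "high_copy_cnv")
    cnv_reason <- map[verdict]
    reason_of[is.na(reason_of) & !is.na(cnv_reason)] <-
      cnv_reason[is.na(reason_of) & !is.na(cnv_reason)]
  }

  tab <- table(factor(reason_of, levels = reasons))
  removed[names(tab)] <- as.integer(tab)
  retained <- snps[is.na(reason_of), , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(
    list(input_count = n_in, removed_by_reason = removed,
         output_count = nrow(retained)),
    class = "filter_report"
  )
  stopifnot(report$input_count == report$output_count + sum(removed))
  list(retained = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Region filter report:", x$input_count, "in ->", x$output_count, "out\n")
  for (r in names(x$removed_by_reason)) {
    if (x$removed_by_reason[[r]] > 0L) {
      cat("  removed (", r, "): ", x$removed_by_reason[[r]], "\n", sep = "")
    }
  }
  invisible(x)
}

#' @rdname apply_region_filters
#' @param report A `filter_report`.
#' @export
filter_report_as_data_frame <- function(report) {
  data.frame(
    reason = c("input", names(report$removed_by_reason), "output"),
    count = c(report$input_count, unname(report$removed_by_reason),
              report$output_count)
  )
}
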