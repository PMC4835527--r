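#' Pipeline configuration
#'
#' Bundles every input path and tunable parameter of the AS-SNP discovery
#' pipeline. Paths other than `counts` and `het_snps` are optional (`NULL`
#' disables the corresponding stage input).
#'
#' @param counts Path to the allelic counts TSV (required).
#' @param het_snps Path to the heterozygous-SNP VCF (required).
#' @param out_dir Output directory (created on run).
#' @param cnvs,gaps,blacklist,frequency,catalog,proxies Optional input paths
#'   (CNV TSV, BED masks, frequency/catalog/proxy TSVs).
#' @param alpha q-value significance cutoff, in (0, 1).
#' @param common_af_threshold Allele frequency at/above which a SNP is
#'   common.
#' @param r2_threshold LD threshold for proxy expansion (strict `>`).
#' @param locus_window Locus-chaining window in bp.
#' @param gap_flank,blacklist_flank Flank sizes (bp) applied to gap and
#'   blacklist intervals before filtering.
#' @param n_permutations Permutations for catalog enrichment; 0 disables.
#' @param seed RNG seed for the permutation stage.
#' @param bh_family Multiple-testing family: `"per_dataset"` or `"global"`.
#' @param cell_line Label used on annotation rows; defaults to the VCF
#'   sample.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, het_snps, out_dir,
                            cnvs = NULL, gaps = NULL, blacklist = NULL,
                            frequency = NULL, catalog = NULL, proxies = NULL,
                            alpha = 0.05, common_af_threshold = 0.01,
                            r2_threshold = 0.8, locus_window = 1e6,
                            gap_flank = 1e6, blacklist_flank = 100,
                            n_permutations = 0L, seed = 1L,
                            bh_family = c("per_dataset", "global"),
                            cell_line = NULL) {
  structure(
    list(counts = counts, het_snps = het_snps, out_dir = out_dir,
         cnvs = cnvs, gaps = gaps, blacklist = blacklist,
         frequency = frequency, catalog = catalog, proxies = proxies,
         alpha = alpha, common_af_threshold = common_af_threshold,
         r2_threshold = r2_threshold, locus_window = locus_window,
         gap_flank = gap_flank, blacklist_flank = blacklist_flank,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         bh_family = match.arg(bh_family), cell_line = cell_line),
    class = "pipeline_config"
  )
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges, enum values and input-path existence without
#' running anything.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(is.numeric(config$alpha) && config$alpha > 0 && config$alpha < 1,
      "alpha must be strictly inside (0, 1)")
  chk(config$common_af_threshold > 0 && config$common_af_threshold < 1,
      "common_af_threshold must be in (0, 1)")
  chk(config$r2_threshold >= 0 && config$r2_threshold < 1,
      "r2_threshold must be in [0, 1)")
  chk(config$locus_window > 0, "locus_window must be positive")
  chk(config$gap_flank >= 0, "gap_flank must be >= 0")
  chk(config$blacklist_flank >= 0, "blacklist_flank must be >= 0")
  chk(config$n_permutations >= 0, "n_permutations must be >= 0")
  chk(config$bh_family %in% c("per_dataset", "global"),
      "bh_family must be 'per_dataset' or 'global'")
  for (p in c("counts", "het_snps")) {
    chk(!is.null(config[[p]]) && file.exists(config[[p]]),
        paste0("required input path missing: ", p))
  }
  for (p in c("cnvs", "gaps", "blacklist", "frequency", "catalog", "proxies")) {
    if (!is.null(config[[p]])) {
      chk(file.exists(config[[p]]), paste0("input path does not exist: ", p,
                                           " (", config[[p]], ")"))
    }
  }
  v
}

#' Run the full AS-SNP discovery pipeline
#'
#' Executes, in order: input loading, zero-allele discard, CNV null
#' resolution, exact binomial tests with Benjamini-Hochberg correction,
#' gap/blacklist/CNV region filtering of the candidate AS-SNPs, frequency
#' classification and effect annotation, LD/GWAS-catalog integration and
#' (optionally) permutation enrichment. Every stage logs its input/output
#' record counts; all result tables plus a run manifest are written under
#' `config$out_dir`.
#'
#' @param config A valid [pipeline_config()].
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with all in-memory stage results (`results`,
#'   `as_snps`, `filter_report`, `annotated`, `network`, `loci`,
#'   `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  violations <- validate_config(config)
  if (length(violations) > 0L) {
    stop("invalid pipeline config:\n  - ", paste(violations, collapse = "\n  - "))
  }
  say <- function(...) if (!quiet) message("[assnp] ", ...)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  counts <- read_counts_table(config$counts)
  snps <- read_het_snps(config$het_snps, cell_line = config$cell_line)
  cell_line <- snps$cell_line[1L]
  say("loaded ", nrow(counts), " count records at ", nrow(snps), " het SNPs")
  cnvs <- if (!is.null(config$cnvs)) read_cnv_table(config$cnvs) else NULL
  gaps <- if (!is.null(config$gaps)) read_bed(config$gaps) else NULL
  blacklist <- if (!is.null(config$blacklist)) read_bed(config$blacklist) else NULL
  freq <- if (!is.null(config$frequency)) read_frequency_table(config$frequency) else NULL
  catalog <- if (!is.null(config$catalog)) read_catalog_table(config$catalog) else NULL
  proxies <- if (!is.null(config$proxies)) read_proxy_table(config$proxies) else NULL

  nullspecs <- resolve_null(snps, cnvs)
  called <- call_as_snps(counts, nullspecs, alpha = config$alpha,
                         bh_family = config$bh_family)
  say("discarded ", called$n_zero_discarded, " zero-allele records, ",
      called$n_cnv_excluded, " CNV-excluded records; tested ",
      nrow(called$results), " pairs; ", length(called$as_snps),
      " candidate AS-SNPs")

  chrom_sizes <- tapply(c(snps$pos + 1, if (!is.null(cnvs)) cnvs$end,
                          if (!is.null(gaps)) gaps$end,
                          if (!is.null(blacklist)) blacklist$end),
                        c(snps$chrom, if (!is.null(cnvs)) cnvs$chrom,
                          if (!is.null(gaps)) gaps$chrom,
                          if (!is.null(blacklist)) blacklist$chrom),
                        max)
  gap_x <- if (!is.null(gaps)) {
    expand_intervals(gaps, config$gap_flank, chrom_sizes)
  }
  bl_x <- if (!is.null(blacklist)) {
    expand_intervals(blacklist, config$blacklist_flank, chrom_sizes)
  }
  candidates <- snps[snps$snp_id %in% called$as_snps, , drop = FALSE]
  filt <- apply_region_filters(candidates, gap_x, bl_x, nullspecs)
  say("region filters: ", filt$report$input_count, " -> ",
      filt$report$output_count, " AS-SNPs")
  as_ids <- filt$retained$snp_id
  results <- called$results
  results$significant <- results$significant & results$snp_id %in% as_ids

  annotated <- annotate_as_snps(results, freq, cell_line = cell_line,
                                common_threshold = config$common_af_threshold)

  network <- NULL; loci <- NULL; enrichment <- NULL
  if (!is.null(catalog)) {
    expanded <- expand_with_proxies(catalog, proxies, config$r2_threshold)
    network <- intersect_as_with_catalog(as_ids, expanded)
    hit_idx <- catalog[catalog$snp_id %in% unique(network$edges$index_snp), ,
                       drop = FALSE]
    loci <- group_into_loci(hit_idx, window = config$locus_window)
    say("catalog integration: ", network$n_direct_hits, " direct + ",
        network$n_ld_hits, " LD-linked AS-SNPs in ", nrow(loci), " loci")
    if (config$n_permutations > 0L) {
      pool <- setdiff(unique(counts$snp_id[counts$g1_count > 0 &
                                             counts$g2_count > 0]), as_ids)
      enrichment <- permutation_enrichment(
        as_ids, pool, target_ids = unique(expanded$snp_id),
        n_permutations = config$n_permutations, seed = config$seed
      )
      say("enrichment: fold ", format(enrichment$fold, digits = 3),
          ", empirical p ", format(enrichment$empirical_p, digits = 3))
    }
  }

  # write result tables
  tables <- list(
    as_tests.tsv = results,
    as_snps.tsv = data.frame(snp_id = as_ids, stringsAsFactors = FALSE),
    filter_report.tsv = filter_report_as_data_frame(filt$report),
    annotated_as_snps.tsv = annotated
  )
  if (!is.null(network)) {
    tables$network_edges.tsv <- network$edges
    tables$loci.tsv <- loci
  }
  if (!is.null(enrichment)) {
    tables$enrichment.tsv <- data.frame(
      observed_overlap = enrichment$observed_overlap,
      null_mean = mean(enrichment$null_overlaps),
      fold = enrichment$fold,
      empirical_p = enrichment$empirical_p,
      n_permutations = enrichment$n_permutations,
      seed = enrichment$seed
    )
  }
  for (nm in names(tables)) write_tsv(tables[[nm]], file.path(out_dir, nm))

  input_paths <- Filter(Negate(is.null),
                        config[c("counts", "het_snps", "cnvs", "gaps",
                                 "blacklist", "frequency", "catalog",
                                 "proxies")])
  manifest <- list(
    tool = paste0("assnp ", as.character(utils::packageVersion("assnp"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = lapply(unclass(config), function(x) if (is.null(x)) NA else x),
    input_checksums = as.list(tools::md5sum(unlist(input_paths))),
    stage_counts = list(
      count_records = nrow(counts),
      het_snps = nrow(snps),
      zero_allele_discarded = called$n_zero_discarded,
      cnv_excluded = called$n_cnv_excluded,
      tested_pairs = nrow(called$results),
      candidate_as_snps = filt$report$input_count,
      removed_by_reason = as.list(filt$report$removed_by_reason),
      final_as_snps = filt$report$output_count
    )
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))

  invisible(list(results = results, as_snps = as_ids,
                 filter_report = filt$report, annotated = annotated,
                 network = network, loci = loci, enrichment = enrichment,
                 manifest = manifest))
}
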