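# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration for synthetic allelic-count bundles
#'
#' Defines every generative assumption of the synthetic data: heterozygous
#' sites placed uniformly on a toy genome, a rare fraction of the allele
#' frequency spectrum (14% of heterozygous sites below 1% AF, half of which
#' are additionally missing from the frequency table), per-(SNP, dataset)
#' read depths drawn from an overdispersed negative binomial (mean 30,
#' dispersion 5), truly imbalanced SNPs whose allelic fraction deviates from
#' 1/2 — rare imbalanced SNPs drawing stochastically larger deviations than
#' common ones — and haplotype-resolved copy-number regions that shift the
#' null allelic ratio to 2:1.
#'
#' @param seed Integer RNG seed; the whole bundle is a deterministic function
#'   of the config including this seed.
#' @param n_snps Number of heterozygous SNPs.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param n_datasets Number of ChIP-seq datasets (TFs).
#' @param depth_model List: `distribution` (`"negative_binomial"` or
#'   `"poisson"`), `mean` (> 0), `dispersion` (NB size parameter).
#' @param frac_as Fraction of SNPs with true allelic imbalance.
#' @param common_effect,rare_effect Length-2 vectors `(lo, hi)`: the absolute
#'   deviation `|theta - 0.5|` of a truly imbalanced SNP is uniform on
#'   `[lo, hi]`; the rare range should stochastically dominate the common
#'   one.
#' @param frac_rare Fraction of SNPs with allele frequency below 1%.
#' @param frac_af_missing_rare Probability that a rare SNP is absent from the
#'   emitted frequency table (exercising the "never catalogued" branch).
#' @param cnv_config List: `n_regions`, `copy_numbers` (sampled with
#'   replacement; `NA` = ungenotyped), `frac_haplotype_resolved` (applies to
#'   3-copy regions), `region_length` (bp).
#' @param mask_config List: `n_gap`, `n_blacklist`, `gap_length`,
#'   `blacklist_length` (bp).
#' @param catalog_config List: `n_index` catalog SNPs, `n_linked_as`
#'   truly-imbalanced SNPs planted as high-LD proxies (`r2 > 0.8`),
#'   `n_decoy` low-LD decoy links (`r2 <= 0.8`).
#' @param reference_bias Multiplier on the effective G1 fraction (1 = no
#'   bias, the default: reference-alignment bias is assumed controlled).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_snps = 2000L,
                              chrom_sizes = c(chr1 = 5e7, chr2 = 4e7),
                              n_datasets = 4L,
                              depth_model = list(distribution = "negative_binomial",
                                                 mean = 30, dispersion = 5),
                              frac_as = 0.05,
                              common_effect = c(0.15, 0.30),
                              rare_effect = c(0.25, 0.45),
                              frac_rare = 0.14,
                              frac_af_missing_rare = 0.5,
                              cnv_config = list(n_regions = 0L,
                                                copy_numbers = 3L,
                                                frac_haplotype_resolved = 1,
                                                region_length = 2e5),
                              mask_config = list(n_gap = 0L, n_blacklist = 0L,
                                                 gap_length = 5e4,
                                                 blacklist_length = 1000),
                              catalog_config = list(n_index = 0L,
                                                    n_linked_as = 0L,
                                                    n_decoy = 0L),
                              reference_bias = 1) {
  fracs <- c(frac_as = frac_as, frac_rare = frac_rare,
             frac_af_missing_rare = frac_af_missing_rare,
             frac_haplotype_resolved = cnv_config$frac_haplotype_resolved)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  }
  if (depth_model$mean <= 0) stop("depth mean must be positive")
  if (!depth_model$distribution %in% c("negative_binomial", "poisson")) {
    stop("depth distribution must be 'negative_binomial' or 'poisson'")
  }
  if (n_snps < 1L) stop("n_snps must be >= 1")
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes))) {
    stop("chrom_sizes must be a non-empty named vector")
  }
  structure(
    list(seed = as.integer(seed), n_snps = as.integer(n_snps),
         chrom_sizes = chrom_sizes, n_datasets = as.integer(n_datasets),
         depth_model = depth_model, frac_as = frac_as,
         common_effect = common_effect, rare_effect = rare_effect,
         frac_rare = frac_rare, frac_af_missing_rare = frac_af_missing_rare,
         cnv_config = cnv_config, mask_config = mask_config,
         catalog_config = catalog_config, reference_bias = reference_bias),
    class = "simulation_config"
  )
}

#' Generate heterozygous SNPs with an allele-frequency split
#'
#' Places `n_snps` heterozygous sites uniformly (unique positions per
#' chromosome, chromosomes weighted by length). A `frac_rare` subset draws
#' allele frequency below 0.01, the remainder at or above 0.01; rare SNPs
#' are dropped from the frequency table with probability
#' `frac_af_missing_rare` (their true AF stays on the truth record).
#'
#' @param config A [simulation_config()].
#' @return A list with `snps` (heterozygous-SNP `data.frame`), `frequency`
#'   (frequency `data.frame`, possibly missing some rare SNPs) and `truth`
#'   (skeleton: `snp_id`, `af`; completed by [simulate_allelic_counts()]).
#' @export
generate_het_snps <- function(config) {
  sizes <- config$chrom_sizes
  if (config$n_snps > sum(sizes)) {
    stop("n_snps (", config$n_snps, ") exceeds total genome length (",
         sum(sizes), ")")
  }
  with_seed(config$seed, {
    n <- config$n_snps
    chrom <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
    counts <- table(factor(chrom, levels = names(sizes)))
    if (any(counts > sizes)) {
      stop("more SNPs assigned to a chromosome than it has positions")
    }
    pos <- integer(n)
    for (cn in names(sizes)) {
      idx <- which(chrom == cn)
      pos[idx] <- sort(sample.int(sizes[[cn]], length(idx))) - 1L
    }
    ord <- order(chrom, pos)  # genomic order, so ids follow the VCF layout
    chrom <- chrom[ord]
    pos <- pos[ord]
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    snp_id <- sprintf("snp%06d", seq_len(n))

    is_rare <- stats::runif(n) < config$frac_rare
    af <- ifelse(is_rare,
                 stats::runif(n, 5e-4, 0.0099),
                 stats::runif(n, 0.01, 0.99))
    missing_af <- is_rare & stats::runif(n) < config$frac_af_missing_rare

    snps <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                       ref_allele = ref, alt_allele = unname(alt),
                       cell_line = "SIM", stringsAsFactors = FALSE)
    list(
      snps = snps,
      frequency = data.frame(snp_id = snp_id[!missing_af],
                             af = af[!missing_af],
                             stringsAsFactors = FALSE),
      truth = data.frame(snp_id = snp_id, af = af, stringsAsFactors = FALSE)
    )
  })
}

#' Generate non-overlapping CNV, gap and blacklist regions
#'
#' Regions of all three kinds are placed on a disjoint slot grid (slot size =
#' the largest requested region length), so no two generated regions overlap.
#' Requesting more regions than the genome has slots is an error. Copy
#' numbers are sampled from `cnv_config$copy_numbers` (`NA` = ungenotyped);
#' each 3-copy region is haplotype-resolved with probability
#' `frac_haplotype_resolved`, in which case the duplicated haplotype is drawn
#' uniformly from g1/g2.
#'
#' @param config A [simulation_config()].
#' @return A list with `cnvs` (CNV `data.frame`), `gaps` and `blacklist`
#'   (interval `data.frame`s).
#' @export
generate_cnv_and_mask_regions <- function(config) {
  cc <- config$cnv_config
  mc <- config$mask_config
  n_total <- cc$n_regions + mc$n_gap + mc$n_blacklist
  empty_cnv <- data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), copy_number = integer(0),
                          haplotype_resolved = logical(0),
                          duplicated_haplotype = character(0),
                          stringsAsFactors = FALSE)
  empty_iv <- genomic_intervals(character(0), numeric(0), numeric(0))
  if (n_total == 0L) {
    return(list(cnvs = empty_cnv, gaps = empty_iv, blacklist = empty_iv))
  }
  slot <- max(cc$region_length * (cc$n_regions > 0),
              mc$gap_length * (mc$n_gap > 0),
              mc$blacklist_length * (mc$n_blacklist > 0))
  sizes <- config$chrom_sizes
  slots_per_chrom <- floor(sizes / slot)
  if (n_total > sum(slots_per_chrom)) {
    stop("requested ", n_total, " regions but the genome only fits ",
         sum(slots_per_chrom), " disjoint slots of ", slot, " bp")
  }
  with_seed(config$seed + 1L, {
    slot_chrom <- rep(names(sizes), slots_per_chrom)
    slot_start <- unlist(lapply(slots_per_chrom,
                                function(k) (seq_len(k) - 1) * slot),
                         use.names = FALSE)
    pick <- sample(length(slot_chrom), n_total)
    kind <- rep(c("cnv", "gap", "blacklist"),
                c(cc$n_regions, mc$n_gap, mc$n_blacklist))
    lens <- rep(c(cc$region_length, mc$gap_length, mc$blacklist_length),
                c(cc$n_regions, mc$n_gap, mc$n_blacklist))
    chrom <- slot_chrom[pick]
    start <- slot_start[pick]
    end <- start + lens

    cnvs <- empty_cnv
    if (cc$n_regions > 0L) {
      i <- kind == "cnv"
      cn_pool <- as.integer(cc$copy_numbers)
      cn <- cn_pool[sample.int(length(cn_pool), sum(i), replace = TRUE)]
      resolved <- !is.na(cn) & cn == 3L &
        stats::runif(sum(i)) < cc$frac_haplotype_resolved
      dup <- ifelse(resolved, sample(c("g1", "g2"), sum(i), replace = TRUE),
                    "unknown")
      cnvs <- data.frame(chrom = chrom[i], start = start[i], end = end[i],
                         copy_number = cn, haplotype_resolved = resolved,
                         duplicated_haplotype = dup, stringsAsFactors = FALSE)
      cnvs <- cnvs[order(cnvs$chrom, cnvs$start), , drop = FALSE]
      rownames(cnvs) <- NULL
    }
    mk_iv <- function(sel, lab) {
      if (!any(sel)) return(empty_iv)
      iv <- genomic_intervals(chrom[sel], start[sel], end[sel], lab)
      iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
      rownames(iv) <- NULL
      iv
    }
    list(cnvs = cnvs, gaps = mk_iv(kind == "gap", "gap"),
         blacklist = mk_iv(kind == "blacklist", "blacklist"))
  })
}

# odds-style transform: a non-imbalanced theta = 0.5 maps exactly onto the
# 2:1 copy-number null (2/3 when g1 is duplicated, 1/3 when g2 is)
cnv_transform_theta <- function(theta, duplicated_haplotype) {
  ifelse(duplicated_haplotype == "g1",
         2 * theta / (1 + theta),
         theta / (2 - theta))
}

#' Simulate per-(SNP, dataset) allelic read counts with truth labels
#'
#' For each SNP-dataset pair, the total depth is drawn from the configured
#' depth model and the G1 count from `Binomial(depth, theta_eff)`. A SNP
#' without true imbalance has `theta = 0.5`; a truly imbalanced one draws
#' `theta = 0.5 +/- dev` with `dev` uniform on the common or rare effect
#' range according to its allele frequency. Inside a haplotype-resolved
#' 3-copy region the effective fraction is transformed so that a
#' non-imbalanced SNP sits exactly at 1/3 or 2/3. SNPs inside unresolved or
#' high-copy CNVs still receive counts — excluding them is the pipeline's
#' job, not the simulator's.
#'
#' @param snps Heterozygous-SNP `data.frame` from [generate_het_snps()].
#' @param truth Truth skeleton from [generate_het_snps()].
#' @param cnvs CNV `data.frame` (or `NULL`).
#' @param config A [simulation_config()].
#' @return A list with `counts` (allelic-count `data.frame`) and `truth`
#'   (completed: `snp_id`, `true_theta`, `is_as`, `af`, `in_cnv`).
#' @export
simulate_allelic_counts <- function(snps, truth, cnvs, config) {
  n <- nrow(snps)
  with_seed(config$seed + 2L, {
    is_as <- stats::runif(n) < config$frac_as
    rare <- truth$af < 0.01
    dev_rng <- ifelse(rare,
                      stats::runif(n, config$rare_effect[1], config$rare_effect[2]),
                      stats::runif(n, config$common_effect[1], config$common_effect[2]))
    sign <- sample(c(-1, 1), n, replace = TRUE)
    theta <- ifelse(is_as, pmin(pmax(0.5 + sign * dev_rng, 0.001), 0.999), 0.5)

    in_cnv <- rep(FALSE, n)
    theta_eff <- theta
    if (!is.null(cnvs) && nrow(cnvs) > 0L) {
      in_cnv <- points_in_intervals(snps$chrom, snps$pos, cnvs)
      hits <- GenomicRanges::findOverlaps(
        positions_to_granges(snps$chrom, snps$pos),
        intervals_to_granges(cnvs)
      )
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      keep <- !duplicated(qh)
      qh <- qh[keep]; sh <- sh[keep]
      res3 <- !is.na(cnvs$copy_number[sh]) & cnvs$copy_number[sh] == 3L &
        cnvs$haplotype_resolved[sh]
      theta_eff[qh[res3]] <- cnv_transform_theta(
        theta[qh[res3]], cnvs$duplicated_haplotype[sh[res3]]
      )
    }
    theta_eff <- pmin(theta_eff * config$reference_bias, 1)

    m <- n * config$n_datasets
    dataset_id <- rep(paste0("TF", sprintf("%02d", seq_len(config$n_datasets)),
                             "_SIM"), each = n)
    dm <- config$depth_model
    depth <- if (dm$distribution == "poisson") {
      stats::rpois(m, dm$mean)
    } else {
      stats::rnbinom(m, size = dm$dispersion, mu = dm$mean)
    }
    g1 <- stats::rbinom(m, depth, rep(theta_eff, config$n_datasets))
    counts <- data.frame(
      snp_id = rep(snps$snp_id, config$n_datasets),
      dataset_id = dataset_id,
      g1_count = g1,
      g2_count = depth - g1,
      stringsAsFactors = FALSE
    )
    completed <- data.frame(
      snp_id = truth$snp_id, true_theta = theta, is_as = is_as,
      af = truth$af, in_cnv = in_cnv, stringsAsFactors = FALSE
    )
    list(counts = counts, truth = completed)
  })
}

#' Generate a GWAS/eQTL catalog with planted LD proxy structure
#'
#' Plants `n_index` catalog SNPs at fresh genomic positions, links a subset
#' of truly imbalanced SNPs to them with `r2 > 0.8` (each linked SNP to one
#' or two index SNPs, producing many-to-many topologies) and adds decoy
#' links at `r2 <= 0.8` from non-imbalanced SNPs.
#'
#' @param snps Heterozygous-SNP `data.frame`.
#' @param truth Completed truth `data.frame` (needs `is_as`).
#' @param config A [simulation_config()].
#' @return A list with `catalog` and `proxies` `data.frame`s.
#' @export
generate_catalog_and_proxies <- function(snps, truth, config) {
  kc <- config$catalog_config
  empty_cat <- data.frame(snp_id = character(0), trait = character(0),
                          source = character(0), chrom = character(0),
                          pos = integer(0), stringsAsFactors = FALSE)
  empty_px <- data.frame(index_snp_id = character(0),
                         proxy_snp_id = character(0), r2 = numeric(0),
                         stringsAsFactors = FALSE)
  if (kc$n_index == 0L) return(list(catalog = empty_cat, proxies = empty_px))
  with_seed(config$seed + 3L, {
    sizes <- config$chrom_sizes
    traits <- paste0("trait_", LETTERS[1:5])
    chrom <- sample(names(sizes), kc$n_index, replace = TRUE)
    pos <- vapply(chrom, function(cn) sample.int(sizes[[cn]], 1L) - 1L,
                  integer(1))
    catalog <- data.frame(
      snp_id = sprintf("cat%03d", seq_len(kc$n_index)),
      trait = sample(traits, kc$n_index, replace = TRUE),
      source = sample(c("gwas", "eqtl"), kc$n_index, replace = TRUE,
                      prob = c(0.7, 0.3)),
      chrom = unname(chrom), pos = unname(pos), stringsAsFactors = FALSE
    )
    as_ids <- truth$snp_id[truth$is_as]
    non_as_ids <- truth$snp_id[!truth$is_as]
    proxies <- empty_px
    n_link <- min(kc$n_linked_as, length(as_ids))
    if (n_link > 0L) {
      linked <- sample(as_ids, n_link)
      rows <- lapply(linked, function(s) {
        idx <- sample(catalog$snp_id, sample(1:2, 1L))
        data.frame(index_snp_id = idx, proxy_snp_id = s,
                   r2 = stats::runif(length(idx), 0.805, 0.999),
                   stringsAsFactors = FALSE)
      })
      proxies <- do.call(rbind, rows)
    }
    n_decoy <- min(kc$n_decoy, length(non_as_ids))
    if (n_decoy > 0L) {
      decoy <- sample(non_as_ids, n_decoy)
      proxies <- rbind(proxies, data.frame(
        index_snp_id = sample(catalog$snp_id, n_decoy, replace = TRUE),
        proxy_snp_id = decoy,
        r2 = stats::runif(n_decoy, 0, 0.8),
        stringsAsFactors = FALSE
      ))
    }
    rownames(proxies) <- NULL
    list(catalog = catalog, proxies = proxies)
  })
}

#' Generate a complete in-memory synthetic bundle
#'
#' Runs the whole generator chain — heterozygous SNPs and frequencies, CNV
#' and mask regions, allelic counts with completed truth labels, catalog and
#' proxies — as a deterministic function of the config.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `config`, `snps`, `frequency`, `truth`,
#'   `cnvs`, `gaps`, `blacklist`, `counts`, `catalog`, `proxies`.
#' @export
generate_bundle <- function(config) {
  hs <- generate_het_snps(config)
  reg <- generate_cnv_and_mask_regions(config)
  sim <- simulate_allelic_counts(hs$snps, hs$truth, reg$cnvs, config)
  cat <- generate_catalog_and_proxies(hs$snps, sim$truth, config)
  list(config = config, snps = hs$snps, frequency = hs$frequency,
       truth = sim$truth, cnvs = reg$cnvs, gaps = reg$gaps,
       blacklist = reg$blacklist, counts = sim$counts,
       catalog = cat$catalog, proxies = cat$proxies)
}

#' Write a synthetic bundle to disk in the pipeline's external formats
#'
#' Emits the VCF, TSV and BED files the readers in this package consume,
#' plus the truth table, the config (YAML) and a manifest listing every file
#' with an MD5 content checksum. Identical configs produce byte-identical
#' bundles.
#'
#' @param output_dir Writable output directory (created if absent).
#' @param config A [simulation_config()].
#' @return The manifest `data.frame` (`file`, `md5`), invisibly; files are
#'   written under `output_dir`.
#' @export
emit_fixture_bundle <- function(output_dir, config) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", output_dir)
  }
  if (file.access(output_dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", output_dir)
  }
  b <- generate_bundle(config)
  paths <- c(
    het_snps = "het_snps.vcf", counts = "counts.tsv",
    frequency = "frequencies.tsv", cnvs = "cnv_regions.tsv",
    gaps = "gaps.bed", blacklist = "blacklist.bed",
    catalog = "catalog.tsv", proxies = "proxies.tsv",
    truth = "truth.tsv", config = "config.yaml"
  )
  full <- file.path(output_dir, paths)
  names(full) <- names(paths)
  write_het_snps(b$snps, full[["het_snps"]])
  write_counts_table(b$counts, full[["counts"]])
  write_frequency_table(b$frequency, full[["frequency"]])
  write_cnv_table(b$cnvs, full[["cnvs"]])
  write_bed(b$gaps, full[["gaps"]])
  write_bed(b$blacklist, full[["blacklist"]])
  write_catalog_table(b$catalog, full[["catalog"]])
  write_proxy_table(b$proxies, full[["proxies"]])
  write_tsv(b$truth, full[["truth"]])
  cfg <- b$config
  cfg$chrom_sizes <- as.list(cfg$chrom_sizes)
  yaml::write_yaml(unclass(cfg), full[["config"]])

  manifest <- data.frame(
    file = unname(paths),
    md5 = unname(tools::md5sum(full)),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, file.path(output_dir, "manifest.tsv"))
  invisible(manifest)
}
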