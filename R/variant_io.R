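#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# Internal coordinate convention: 0-based, half-open [start, end) everywhere.
# VCF is the only 1-based boundary; POS is converted on read/write.

#' Construct a table of genomic intervals
#'
#' Intervals use 0-based half-open coordinates `[start, end)`, the BED
#' convention, which is also the package-internal convention.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start positions.
#' @param end Integer vector, 0-based exclusive end positions (`end > start`).
#' @param label Optional character vector of labels.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `label`.
#' @export
genomic_intervals <- function(chrom, start, end, label = NA_character_) {
  x <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    label = rep_len(as.character(label), length(chrom)),
    stringsAsFactors = FALSE
  )
  bad <- which(!nzchar(x$chrom) | x$start < 0 | x$end <= x$start)
  if (length(bad) > 0L) {
    stop("invalid interval(s) at record(s): ", paste(bad, collapse = ", "),
         " (need chrom non-empty, start >= 0, end > start)")
  }
  x
}

# GRanges bridge: internal 0-based half-open -> 1-based closed
intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# SNP positions as width-1 GRanges
positions_to_granges <- function(chrom, pos) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = pos + 1L, width = 1L)
  )
}

#' Read heterozygous SNPs from a VCF file
#'
#' Keeps biallelic SNVs whose genotype is heterozygous (`0/1`, `0|1`, `1/0`,
#' `1|0`) for the first sample. Multiallelic records and non-SNV records are
#' skipped with a message reporting their count. VCF 1-based `POS` is converted
#' to the internal 0-based `pos` (`pos = POS - 1`).
#'
#' @param path Path to an (uncompressed or gzipped) VCF with GT fields.
#' @param cell_line Cell-line label stored on each record; defaults to the
#'   sample name in the VCF.
#' @return `data.frame` with columns `snp_id`, `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `cell_line`.
#' @export
read_het_snps <- function(path, cell_line = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) < 1L) stop("VCF has no genotype (GT) data: ", path)
  if (is.null(cell_line)) cell_line <- colnames(gt)[1L]
  gt1 <- gt[, 1L]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0L) message("read_het_snps: skipped ", n_multi, " multiallelic record(s)")
  snv <- !multi & ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_nonsnv <- sum(!snv & !multi)
  if (n_nonsnv > 0L) message("read_het_snps: skipped ", n_nonsnv, " non-SNV record(s)")
  het <- gt1 %in% c("0/1", "0|1", "1/0", "1|0")
  keep <- snv & het
  keep[is.na(keep)] <- FALSE

  id <- fix[keep, "ID"]
  chrom <- fix[keep, "CHROM"]
  pos1 <- as.integer(fix[keep, "POS"])
  miss <- is.na(id) | id == "."
  id[miss] <- paste0(chrom[miss], "_", pos1[miss])
  data.frame(
    snp_id = unname(id),
    chrom = unname(chrom),
    pos = unname(pos1) - 1L,
    ref_allele = unname(ref[keep]),
    alt_allele = unname(alt[keep]),
    cell_line = cell_line,
    stringsAsFactors = FALSE
  )
}

#' Write heterozygous SNPs to a minimal VCF
#'
#' Emits a VCFv4.2 file with one sample (named after `cell_line` of the first
#' record) and genotype `0|1` on every record; the inverse of
#' [read_het_snps()] on its own output. Internal 0-based `pos` becomes
#' 1-based `POS`.
#'
#' @param snps `data.frame` as returned by [read_het_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_het_snps <- function(snps, path) {
  sample_name <- if (nrow(snps) > 0L) snps$cell_line[1L] else "sample"
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- if (nrow(snps) > 0L) {
    ord <- order(snps$chrom, snps$pos)
    s <- snps[ord, , drop = FALSE]
    paste(s$chrom, s$pos + 1L, s$snp_id, s$ref_allele, s$alt_allele,
          ".", "PASS", ".", "GT", "0|1", sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' BED's 0-based half-open coordinates are kept unchanged. `#`-prefixed
#' comment lines are allowed. Records with `end <= start` are rejected with
#' an error naming the offending line number(s).
#'
#' @param path Path to a BED3+ file.
#' @return Interval `data.frame` (see [genomic_intervals()]); column 4, when
#'   present, becomes `label`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  if (!any(keep)) {
    return(genomic_intervals(character(0), integer(0), integer(0)))
  }
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED record with fewer than 3 columns at line(s): ",
         paste(lineno[nf < 3L], collapse = ", "))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-numeric BED coordinates at line(s): ",
         paste(lineno[is.na(start) | is.na(end)], collapse = ", "))
  }
  bad <- end <= start | start < 0
  if (any(bad)) {
    stop("invalid BED interval (end <= start or start < 0) at line(s): ",
         paste(lineno[bad], collapse = ", "))
  }
  label <- ifelse(nf >= 4L,
                  vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                         character(1)),
                  NA_character_)
  genomic_intervals(chrom, start, end, label)
}

#' Write intervals to BED
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  has_label <- !all(is.na(x$label))
  cols <- if (has_label) {
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
               ifelse(is.na(x$label), ".", x$label))
  } else {
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

# shared checked TSV reader: tab-delimited, header, '#' comments allowed
read_tsv_checked <- function(path, required_cols) {
  x <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_cols, names(x))
  if (length(missing) > 0L) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  x
}

check_counts_column <- function(x, col, path) {
  v <- x[[col]]
  if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != floor(v))) {
    stop("column '", col, "' in ", path,
         " must contain non-negative integers")
  }
  as.integer(v)
}

#' Read a per-(SNP, dataset) allelic counts table
#'
#' Tab-delimited with header columns `snp_id`, `dataset_id`, `g1_count`
#' (reads supporting the reference allele) and `g2_count` (alternative
#' allele). Duplicate `(snp_id, dataset_id)` keys and non-integer or negative
#' counts are errors.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with the four columns above.
#' @export
read_counts_table <- function(path) {
  x <- read_tsv_checked(path, c("snp_id", "dataset_id", "g1_count", "g2_count"))
  x$g1_count <- check_counts_column(x, "g1_count", path)
  x$g2_count <- check_counts_column(x, "g2_count", path)
  key <- paste(x$snp_id, x$dataset_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (snp_id, dataset_id) pair(s) in ", path, ": ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  x[c("snp_id", "dataset_id", "g1_count", "g2_count")]
}

#' @rdname read_counts_table
#' @param counts Counts `data.frame` to write.
#' @export
write_counts_table <- function(counts, path) {
  write_tsv(counts[c("snp_id", "dataset_id", "g1_count", "g2_count")], path)
}

#' Read an allele-frequency table
#'
#' Columns `snp_id`, `af` (alternative-allele frequency in `[0, 1]`). SNPs
#' absent from the table are treated downstream as having no known frequency,
#' which classifies them as rare; absence is therefore meaningful and is never
#' encoded as `af = 0`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `snp_id`, `af`.
#' @export
read_frequency_table <- function(path) {
  x <- read_tsv_checked(path, c("snp_id", "af"))
  if (!is.numeric(x$af) || anyNA(x$af) || any(x$af < 0 | x$af > 1)) {
    stop("column 'af' in ", path, " must be numeric in [0, 1]")
  }
  x[c("snp_id", "af")]
}

#' @rdname read_frequency_table
#' @param freq Frequency `data.frame` to write.
#' @export
write_frequency_table <- function(freq, path) {
  write_tsv(freq[c("snp_id", "af")], path)
}

#' Read a GWAS/eQTL catalog table
#'
#' Columns `snp_id`, `trait`, `source` (`gwas` or `eqtl`), `chrom`, `pos`
#' (0-based).
#'
#' @param path Path to the TSV.
#' @return Catalog `data.frame`.
#' @export
read_catalog_table <- function(path) {
  x <- read_tsv_checked(path, c("snp_id", "trait", "source", "chrom", "pos"))
  bad <- !x$source %in% c("gwas", "eqtl")
  if (any(bad)) {
    stop("invalid 'source' value(s) in ", path, ": ",
         paste(unique(x$source[bad]), collapse = ", "),
         " (must be 'gwas' or 'eqtl')")
  }
  x$pos <- as.integer(x$pos)
  x[c("snp_id", "trait", "source", "chrom", "pos")]
}

#' @rdname read_catalog_table
#' @param catalog Catalog `data.frame` to write.
#' @export
write_catalog_table <- function(catalog, path) {
  write_tsv(catalog[c("snp_id", "trait", "source", "chrom", "pos")], path)
}

#' Read a linkage-disequilibrium proxy table
#'
#' Columns `index_snp_id`, `proxy_snp_id`, `r2` (squared LD correlation in
#' `[0, 1]`). A self-referencing record (`index == proxy`) is only valid as
#' the identity record with `r2 = 1`.
#'
#' @param path Path to the TSV.
#' @return Proxy `data.frame`.
#' @export
read_proxy_table <- function(path) {
  x <- read_tsv_checked(path, c("index_snp_id", "proxy_snp_id", "r2"))
  if (!is.numeric(x$r2) || anyNA(x$r2) || any(x$r2 < 0 | x$r2 > 1)) {
    stop("column 'r2' in ", path, " must be numeric in [0, 1]")
  }
  self <- x$index_snp_id == x$proxy_snp_id
  if (any(self & x$r2 != 1)) {
    stop("self-referencing proxy record(s) with r2 != 1 in ", path)
  }
  x[c("index_snp_id", "proxy_snp_id", "r2")]
}

#' @rdname read_proxy_table
#' @param proxies Proxy `data.frame` to write.
#' @export
write_proxy_table <- function(proxies, path) {
  write_tsv(proxies[c("index_snp_id", "proxy_snp_id", "r2")], path)
}

#' Read a CNV region table (BED + 2 extra columns)
#'
#' Tab-delimited with header: `chrom`, `start`, `end` (0-based half-open),
#' `copy_number` (integer; `NA` or `.` marks a CNV whose copy number was not
#' genotyped) and `duplicated_haplotype` (`g1`, `g2` or `unknown`). A region
#' is haplotype-resolved when `duplicated_haplotype` is `g1` or `g2`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `copy_number`,
#'   `haplotype_resolved`, `duplicated_haplotype`.
#' @export
read_cnv_table <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "start", "end", "copy_number",
                                "duplicated_haplotype"))
  cn <- x$copy_number
  if (is.character(cn)) cn[cn == "."] <- NA
  cn <- suppressWarnings(as.numeric(cn))
  if (any(!is.na(cn) & (cn < 0 | cn != floor(cn)))) {
    stop("column 'copy_number' in ", path,
         " must contain non-negative integers or NA")
  }
  dh <- as.character(x$duplicated_haplotype)
  dh[is.na(dh) | dh == "" | dh == "."] <- "unknown"
  if (!all(dh %in% c("g1", "g2", "unknown"))) {
    stop("invalid 'duplicated_haplotype' value(s) in ", path)
  }
  out <- genomic_intervals(x$chrom, x$start, x$end)
  out$label <- NULL
  out$copy_number <- as.integer(cn)
  out$haplotype_resolved <- dh %in% c("g1", "g2")
  out$duplicated_haplotype <- dh
  out
}

#' @rdname read_cnv_table
#' @param cnvs CNV `data.frame` to write.
#' @export
write_cnv_table <- function(cnvs, path) {
  out <- data.frame(
    chrom = cnvs$chrom,
    start = cnvs$start,
    end = cnvs$end,
    copy_number = ifelse(is.na(cnvs$copy_number), ".",
                         as.character(cnvs$copy_number)),
    duplicated_haplotype = cnvs$duplicated_haplotype,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
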