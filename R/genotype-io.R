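#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (plain or bgzipped) and converts per-sample GT fields
#' to alternate-allele dosages. Phased (`|`) and unphased (`/`) genotypes are
#' treated identically. Half-called genotypes (e.g. `0/.`) and fully missing
#' genotypes (`./.`) are coded missing. For multi-allelic records the dosage is
#' the count of non-reference alleles; such records carry `vtype = "other"` and
#' are removed by the default biallelic-SNV filter.
#'
#' @param path Path to a VCF file.
#' @param sample_subset Optional character vector of sample names to retain.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_block <- v@gt
  if (is.null(gt_block) || ncol(gt_block) < 2L ||
      !all(grepl("(^|:)GT(:|$)", gt_block[, "FORMAT"]))) {
    rlang::abort("VCF has no GT format field")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s) > 0) {
      rlang::abort(paste0("samples not in VCF: ", paste(missing_s, collapse = ", ")))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  filt <- fix[, "FILTER", drop = TRUE]
  filt[is.na(filt)] <- "."
  sites <- tibble::tibble(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    filter = filt
  )
  sites$vtype <- classify_vtype(sites$ref, sites$alt)
  calls <- t(gt_to_dosage(gt))
  geno_matrix(samples, sites, calls)
}

# GT strings -> dosage; any missing allele makes the call missing
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a)) return(NA_integer_)
    sum(a > 0L)
  }, integer(1))
  out <- code[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Site-quality filter policy
#'
#' Encodes the study-style site filters: PASS status, biallelic SNVs only,
#' autosomes only, and per-site call rate strictly greater than
#' `min_call_rate` (a ">90%" rule keeps a site called in 30 of 33 samples,
#' 30/33 = 0.909, and drops one called in 29, 29/33 = 0.879).
#'
#' @param require_pass Keep only sites with FILTER equal to `PASS` (or `.`,
#'   the VCF convention for "no filter applied", when `pass_includes_dot`).
#' @param min_call_rate Minimum fraction of non-missing genotypes, exclusive.
#' @param biallelic_snv_only Keep only single-alternate single-nucleotide sites.
#' @param allowed_chroms Optional character vector of chromosome labels
#'   (e.g. the autosomes). `NULL` keeps all chromosomes. Labels are opaque
#'   strings; no naming scheme is inferred.
#' @param pass_includes_dot Treat FILTER `.` as passing. Default `TRUE`.
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(require_pass = TRUE, min_call_rate = 0.90,
                          biallelic_snv_only = TRUE, allowed_chroms = NULL,
                          pass_includes_dot = TRUE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1)
  structure(
    list(require_pass = require_pass, min_call_rate = min_call_rate,
         biallelic_snv_only = biallelic_snv_only,
         allowed_chroms = allowed_chroms,
         pass_includes_dot = pass_includes_dot),
    class = "filter_policy"
  )
}

#' Apply site-quality filters to a genotype matrix
#'
#' Retention is order-preserving and sample order is unchanged. Filtering is
#' idempotent: applying the same policy twice changes nothing.
#'
#' @param m A [geno_matrix()].
#' @param policy A [filter_policy()].
#' @return A filtered `geno_matrix`. If no site survives, an empty matrix is
#'   returned with a warning.
#' @export
apply_filters <- function(m, policy = filter_policy()) {
  stopifnot(inherits(m, "geno_matrix"), inherits(policy, "filter_policy"))
  if (nrow(m$sites) == 0) rlang::abort("empty genotype matrix")
  keep <- rep(TRUE, nrow(m$sites))
  if (policy$require_pass) {
    ok <- m$sites$filter == "PASS"
    if (policy$pass_includes_dot) ok <- ok | m$sites$filter == "."
    keep <- keep & ok
  }
  if (policy$biallelic_snv_only) {
    keep <- keep & m$sites$vtype == "SNV"
  }
  if (!is.null(policy$allowed_chroms)) {
    keep <- keep & m$sites$chrom %in% policy$allowed_chroms
  }
  call_rate <- colMeans(!is.na(m$calls))
  keep <- keep & call_rate > policy$min_call_rate
  if (!any(keep)) {
    rlang::warn("no sites survive filtering; returning empty matrix")
  }
  subset_geno(m, sites = which(keep))
}

#' Write ROH segments to a BED file
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start_bed = start - 1` and `end_bed = end`. The BED name column holds the
#' sample identifier and the score column the segment SNV count. Unsorted
#' input is sorted by (sample, chrom, start) before writing.
#'
#' @param segments Tibble of ROH segments with columns `sample`, `chrom`,
#'   `start`, `end`, `n_snvs`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  segments <- dplyr::arrange(tibble::as_tibble(segments),
                             .data$sample, .data$chrom, .data$start)
  lines <- character(0)
  if (nrow(segments) > 0) {
    lines <- sprintf("%s\t%d\t%d\t%s\t%d",
                     segments$chrom,
                     as.integer(segments$start) - 1L,
                     as.integer(segments$end),
                     segments$sample,
                     as.integer(segments$n_snvs))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ROH segments from a BED file written by [write_segments_bed()]
#'
#' @param path BED file path.
#' @return Tibble with columns `sample`, `chrom`, `start`, `end`, `n_snvs`
#'   (1-based inclusive coordinates).
#' @export
read_segments_bed <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_snvs = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    sample = vapply(parts, `[`, "", 4),
    chrom = vapply(parts, `[`, "", 1),
    start = as.numeric(vapply(parts, `[`, "", 2)) + 1,
    end = as.numeric(vapply(parts, `[`, "", 3)),
    n_snvs = as.integer(vapply(parts, `[`, "", 5))
  )
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits one GT-only record per site. Dosages map back to unphased genotypes
#' (`0 -> 0/0`, `1 -> 0/1`, `2 -> 1/1`, `NA -> ./.`). Used by the cohort
#' simulator and for round-trip testing; not a general-purpose VCF writer.
#'
#' @param m A [geno_matrix()].
#' @param path Output path (plain text).
#' @param contig_lengths Optional named vector of chromosome lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, contig_lengths = NULL) {
  stopifnot(inherits(m, "geno_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rohdiversity",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    header <- c(header, sprintf("##contig=<ID=%s,length=%d>",
                                names(contig_lengths),
                                as.integer(contig_lengths)))
  }
  header <- c(header, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", m$samples),
                            collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(m$calls), ncol = ncol(m$calls))
  ok <- !is.na(m$calls)
  gt[ok] <- gt_map[m$calls[ok] + 1L]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s",
                  m$sites$chrom, as.integer(m$sites$pos),
                  m$sites$ref, m$sites$alt, m$sites$filter,
                  apply(gt, 2, paste, collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
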