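#' Genotype matrix container
#'
#' A `geno_matrix` holds an ordered cohort of diploid samples genotyped at an
#' ordered set of variant sites. Genotypes are stored as alternate-allele
#' dosages: `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate), `NA` (missing or half-called). Sites are 1-based (VCF
#' convention) and strictly increasing in position within each chromosome.
#'
#' @param samples Character vector of sample identifiers.
#' @param sites Tibble with columns `chrom`, `pos`, `ref`, `alt`, `filter`,
#'   `vtype`. `alt` holds comma-separated alternate alleles; `vtype` is one of
#'   `"SNV"`, `"indel"`, `"other"`.
#' @param calls Integer matrix, `length(samples)` rows by `nrow(sites)`
#'   columns, with values in `{0, 1, 2, NA}`.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(samples, sites, calls) {
  samples <- as.character(samples)
  sites <- tibble::as_tibble(sites)
  needed <- c("chrom", "pos", "ref", "alt", "filter", "vtype")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("sites is missing columns: ",
                        paste(missing_cols, collapse = ", ")))
  }
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(sites)) {
    rlang::abort("calls must be length(samples) x nrow(sites)")
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) > 0 && (min(bad) < 0L || max(bad) > 2L)) {
    rlang::abort("dosage codes must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    rlang::abort("duplicate (chrom, pos) in sites")
  }
  incr <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
  if (length(incr) > 0 && !all(unlist(incr))) {
    rlang::abort("site positions must be strictly increasing within chromosome")
  }
  rownames(calls) <- samples
  structure(
    list(samples = samples, sites = sites, calls = calls),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ",
      nrow(x$sites), " sites on ",
      length(unique(x$sites$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing genotypes: ", sprintf("%.2f%%", 100 * miss), "\n", sep = "")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Subset a genotype matrix by site index and/or sample
#'
#' @param m A `geno_matrix`.
#' @param sites Integer site indices to retain (in order given).
#' @param samples Character sample names or integer indices to retain.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(m, sites = NULL, samples = NULL) {
  stopifnot(inherits(m, "geno_matrix"))
  if (is.null(sites)) sites <- seq_len(nrow(m$sites))
  if (is.null(samples)) samples <- seq_along(m$samples)
  if (is.character(samples)) samples <- match(samples, m$samples)
  geno_matrix(m$samples[samples],
              m$sites[sites, , drop = FALSE],
              m$calls[samples, sites, drop = FALSE])
}

# classify a site by its alleles; multi-allelic records are "other" until
# filtering resolves them
classify_vtype <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  vapply(seq_along(ref), function(i) {
    a <- alts[[i]]
    if (length(a) == 1L && nchar(ref[i]) == 1L && nchar(a) == 1L &&
        a %in% c("A", "C", "G", "T")) {
      "SNV"
    } else if (any(nchar(a) != nchar(ref[i]))) {
      "indel"
    } else {
      "other"
    }
  }, character(1))
}
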