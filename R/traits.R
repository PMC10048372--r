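#' Load the shipped breed-relevant trait-variant definition table
#'
#' One row per variant: trait, OMIA identifier, gene, chromosome, position,
#' reference and alternate alleles. Positions refer to the working assembly
#' of the input VCF. Structural alleles (deletions, duplications) are matched
#' by exact record coordinates and alleles; no local realignment is
#' attempted.
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return Tibble of trait-variant definitions.
#' @export
trait_variant_defs <- function(path = system.file("extdata",
                                                  "trait_variants.tsv",
                                                  package = "rohdiversity")) {
  utils::read.delim(path, sep = "\t", colClasses = "character") |>
    tibble::as_tibble() |>
    dplyr::mutate(pos = as.numeric(.data$pos))
}

#' Load the shipped risk-locus definitions (defining SNV positions)
#'
#' Each locus is defined by a list of SNV positions whose genotypes determine
#' the risk haplotype dose.
#'
#' @param path TSV path (columns `locus`, `chrom`, `pos`); defaults to the
#'   shipped table.
#' @return Tibble with one row per defining SNV.
#' @export
risk_locus_defs <- function(path = system.file("extdata", "risk_loci.tsv",
                                               package = "rohdiversity")) {
  utils::read.delim(path, sep = "\t", colClasses = "character") |>
    tibble::as_tibble() |>
    dplyr::mutate(pos = as.numeric(.data$pos))
}

#' Genotype-class counts for defined trait variants
#'
#' For each definition, counts homozygous-reference, heterozygous,
#' homozygous-alternate and missing genotypes across all samples. A variant
#' absent from the matrix is reported explicitly (`present = FALSE`, `NA`
#' counts), never as zeros.
#'
#' @param m A [geno_matrix()].
#' @param defs Trait-variant definitions ([trait_variant_defs()] or a
#'   compatible tibble with `label`, `chrom`, `pos`).
#' @return Tibble: `label`, `gene`, `chrom`, `pos`, `present`, `n_refref`,
#'   `n_refalt`, `n_altalt`, `n_missing`. Counts plus missing always sum to
#'   the sample count.
#' @export
genotype_counts <- function(m, defs) {
  stopifnot(inherits(m, "geno_matrix"))
  defs <- tibble::as_tibble(defs)
  if (!"gene" %in% names(defs)) defs$gene <- NA_character_
  purrr::pmap_dfr(defs[, c("label", "gene", "chrom", "pos")],
                  function(label, gene, chrom, pos) {
    i <- which(m$sites$chrom == chrom & m$sites$pos == pos)
    if (length(i) == 0) {
      return(tibble::tibble(label = label, gene = gene, chrom = chrom,
                            pos = pos, present = FALSE,
                            n_refref = NA_integer_, n_refalt = NA_integer_,
                            n_altalt = NA_integer_, n_missing = NA_integer_))
    }
    g <- m$calls[, i[1]]
    tibble::tibble(label = label, gene = gene, chrom = chrom, pos = pos,
                   present = TRUE,
                   n_refref = sum(g == 0L, na.rm = TRUE),
                   n_refalt = sum(g == 1L, na.rm = TRUE),
                   n_altalt = sum(g == 2L, na.rm = TRUE),
                   n_missing = sum(is.na(g)))
  })
}

#' Alternate-allele frequency from genotype-class counts
#'
#' `(n_refalt + 2 n_altalt) / (2 * called samples)`, rounded to `digits`
#' decimals for reporting. Accepts a counts tibble (row-wise) or three bare
#' counts.
#'
#' @param counts Tibble from [genotype_counts()] (or any tibble with
#'   `n_refref`, `n_refalt`, `n_altalt`).
#' @param digits Decimal places for the reported frequency (default 3).
#' @return Input tibble with an `af` column added; `NA` where no sample is
#'   called.
#' @export
allele_frequency <- function(counts, digits = 3) {
  counts <- tibble::as_tibble(counts)
  called <- counts$n_refref + counts$n_refalt + counts$n_altalt
  af <- ifelse(called > 0,
               (counts$n_refalt + 2 * counts$n_altalt) / (2 * called),
               NA_real_)
  counts$af <- round(af, digits)
  counts
}

#' Per-sample risk-haplotype dose at a multi-SNV locus
#'
#' The dose (0, 1 or 2 copies of the risk haplotype) is the consensus of the
#' dosages at the locus's defining SNVs: the median, rounded half-up. This
#' consensus rule is an explicit configuration point (`rule`), and the
#' fraction of defining SNVs disagreeing with the consensus is always
#' reported so the call can be audited. A sample with fewer than half of the
#' defining SNVs genotyped gets a missing dose.
#'
#' @param m A [geno_matrix()].
#' @param locus_defs Defining SNVs for the loci ([risk_locus_defs()] format:
#'   `locus`, `chrom`, `pos`).
#' @param rule Function mapping a vector of defining-SNV dosages to a dose in
#'   0..2; default `median` rounded half-up.
#' @return Tibble: `sample`, `locus`, `n_defined`, `n_genotyped`, `dose`,
#'   `discordance`.
#' @export
haplotype_dose <- function(m, locus_defs, rule = NULL) {
  stopifnot(inherits(m, "geno_matrix"))
  locus_defs <- tibble::as_tibble(locus_defs)
  if (is.null(rule)) rule <- function(g) floor(stats::median(g) + 0.5)
  out <- list()
  for (loc in unique(locus_defs$locus)) {
    def <- locus_defs[locus_defs$locus == loc, ]
    i <- match(paste(def$chrom, def$pos),
               paste(m$sites$chrom, m$sites$pos))
    i <- i[!is.na(i)]
    g_all <- m$calls[, i, drop = FALSE]
    for (s in seq_along(m$samples)) {
      g <- g_all[s, ]
      g <- g[!is.na(g)]
      n_geno <- length(g)
      if (n_geno < nrow(def) / 2) {
        dose <- NA_integer_
        disc <- NA_real_
      } else {
        dose <- as.integer(rule(g))
        disc <- mean(g != dose)
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        sample = m$samples[s], locus = loc,
        n_defined = nrow(def), n_genotyped = n_geno,
        dose = dose, discordance = disc
      )
    }
  }
  dplyr::bind_rows(out)
}

#' A/B/C risk index from per-locus haplotype doses
#'
#' Maps the total risk-allele count over the four loci (0-8) to the index
#' categories A (lowest risk), B, C (greatest risk) through a monotone
#' step rule given as cut points: totals up to `cuts[1]` are A, up to
#' `cuts[2]` are B, above that C. The default `cuts = c(2, 5)` is a
#' non-authoritative placeholder; the real laboratory rule is proprietary
#' and should be supplied by the user when known. Monotonicity of the rule is
#' validated. Any missing dose yields a missing index.
#'
#' @param doses Tibble from [haplotype_dose()] (columns `sample`, `locus`,
#'   `dose`), or a named numeric vector of doses for a single sample.
#' @param cuts Two ascending integers in 0..8.
#' @return Tibble `sample`, `total_dose`, `index` (factor A/B/C); for a bare
#'   dose vector, a single character value.
#' @export
risk_index <- function(doses, cuts = c(2, 5)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2],
            cuts[1] >= 0, cuts[2] <= 8)
  map_total <- function(total) {
    if (is.na(total)) return(NA_character_)
    if (total <= cuts[1]) "A" else if (total <= cuts[2]) "B" else "C"
  }
  if (is.numeric(doses)) {
    if (anyNA(doses)) return(NA_character_)
    return(map_total(sum(doses)))
  }
  doses <- tibble::as_tibble(doses)
  doses |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      total_dose = if (anyNA(.data$dose)) NA_integer_
                   else as.integer(sum(.data$dose)),
      .groups = "drop"
    ) |>
    dplyr::mutate(index = factor(vapply(.data$total_dose, map_total,
                                        character(1)),
                                 levels = c("A", "B", "C")))
}

#' Compare an allele/haplotype frequency between two groups
#'
#' Builds the 2x2 table of risk vs non-risk allele counts and applies
#' Fisher's exact test (two-sided). Frequencies per group are reported. An
#' empty margin yields p = 1 with a warning.
#'
#' @param k1,n1 Risk-allele count and total allele count in group 1.
#' @param k2,n2 Same for group 2.
#' @return Tibble: `freq1`, `freq2`, `odds_ratio`, `p_value`.
#' @export
compare_group_frequencies <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    rlang::warn("degenerate 2x2 table (empty margin); p = 1")
    return(tibble::tibble(freq1 = ifelse(n1 > 0, k1 / n1, NA_real_),
                          freq2 = ifelse(n2 > 0, k2 / n2, NA_real_),
                          odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab)
  tibble::tibble(freq1 = k1 / n1, freq2 = k2 / n2,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Load the shipped synthetic mtDNA haplotype-defining variant table
#'
#' The haplotype nomenclature follows the D-loop-based standard (e.g. A2,
#' A22 within haplogroup A), but the defining variants shipped here are a
#' synthetic stand-in for testing: the authoritative per-haplotype variant
#' definitions are published elsewhere and should be supplied by the user
#' for real assignments.
#'
#' @param path TSV path (columns `haplotype`, `pos`, `allele`).
#' @return Tibble of defining variants.
#' @export
mtdna_haplotype_table <- function(path = system.file(
                                    "extdata",
                                    "mtdna_haplotypes_synthetic.tsv",
                                    package = "rohdiversity")) {
  utils::read.delim(path, sep = "\t", colClasses = "character") |>
    tibble::as_tibble() |>
    dplyr::mutate(pos = as.numeric(.data$pos))
}

#' Assign a mitochondrial haplotype from a sample's variant profile
#'
#' A haplotype is assigned when every one of its defining variants
#' (position + allele) is present in the sample's profile; ties report all
#' fully matched labels. Variants outside all definitions are listed as
#' unexplained (e.g. private synonymous coding variants). If no haplotype
#' fully matches, the result is `"unassigned"` with the best partial match
#' reported.
#'
#' @param sample_variants Tibble of the sample's variants (`pos`, `allele`).
#' @param table Haplotype definitions ([mtdna_haplotype_table()] format).
#' @return List: `haplotype` (character vector of matched labels, or
#'   `"unassigned"`), `best_partial` (label, when unassigned), `match_fraction`
#'   (named), `unexplained` (tibble of variants outside all definitions).
#' @export
mtdna_haplotype <- function(sample_variants, table) {
  sample_variants <- tibble::as_tibble(sample_variants)
  table <- tibble::as_tibble(table)
  if (nrow(table) == 0) rlang::abort("empty haplotype table")
  key <- paste(sample_variants$pos, sample_variants$allele)
  frac <- vapply(split(table, table$haplotype), function(def) {
    mean(paste(def$pos, def$allele) %in% key)
  }, numeric(1))
  full <- names(frac)[frac == 1]
  def_key <- paste(table$pos, table$allele)
  unexplained <- sample_variants[!(key %in% def_key), , drop = FALSE]
  if (length(full) > 0) {
    list(haplotype = full, best_partial = NULL, match_fraction = frac,
         unexplained = unexplained)
  } else {
    best <- names(frac)[which.max(frac)]
    list(haplotype = "unassigned", best_partial = best,
         match_fraction = frac, unexplained = unexplained)
  }
}
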