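# Programmatic fixtures shared across test files.

# Minimal geno_matrix from a dosage matrix (samples x sites) on one or more
# chromosomes; positions default to a 10 kb grid.
make_geno <- function(calls, pos = NULL, chrom = NULL, filter = "PASS") {
  calls <- as.matrix(calls)
  ns <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(ns) * 1e4
  if (is.null(chrom)) chrom <- rep("chr1", ns)
  sites <- tibble::tibble(chrom = chrom, pos = pos,
                          ref = "A", alt = "C",
                          filter = rep(filter, length.out = ns),
                          vtype = "SNV")
  samples <- sprintf("S%02d", seq_len(nrow(calls)))
  geno_matrix(samples, sites, calls)
}

quiet_detect <- function(m, params = roh_params(), ...) {
  suppressMessages(detect_roh(m, params, ...))
}

# Cohort genotype matrix reconstructed from the published genotype-class
# counts: for each simple variant, n_refref samples get 0, then n_refalt get
# 1, then n_altalt get 2; for each risk locus every defining SNV carries the
# sample's haplotype dose. Exercised through the VCF writer/reader.
table2_fixture <- function(n_samples = 33) {
  defs <- trait_variant_defs()
  loci <- risk_locus_defs()
  # published per-locus haplotype genotype-class counts
  locus_counts <- tibble::tibble(
    locus = c("chr5:33Mb", "chr11:41Mb", "chr11:44Mb", "chr14:11Mb"),
    n_refref = c(5, 2, 4, 3),
    n_refalt = c(12, 14, 17, 19),
    n_altalt = c(16, 17, 12, 11)
  )
  counts_to_doses <- function(n0, n1, n2) {
    rep(c(0L, 1L, 2L), times = c(n0, n1, n2))
  }
  sites <- list()
  calls <- list()
  for (i in seq_len(nrow(defs))) {
    sites[[length(sites) + 1L]] <- tibble::tibble(
      chrom = defs$chrom[i], pos = defs$pos[i],
      ref = defs$ref[i], alt = defs$alt[i], filter = "PASS",
      vtype = NA_character_)
    calls[[length(calls) + 1L]] <- counts_to_doses(
      as.integer(defs$n_refref[i]), as.integer(defs$n_refalt[i]),
      as.integer(defs$n_altalt[i]))
  }
  for (l in seq_len(nrow(locus_counts))) {
    doses <- counts_to_doses(locus_counts$n_refref[l],
                             locus_counts$n_refalt[l],
                             locus_counts$n_altalt[l])
    def <- loci[loci$locus == locus_counts$locus[l], ]
    for (i in seq_len(nrow(def))) {
      sites[[length(sites) + 1L]] <- tibble::tibble(
        chrom = def$chrom[i], pos = def$pos[i],
        ref = "G", alt = "A", filter = "PASS", vtype = NA_character_)
      calls[[length(calls) + 1L]] <- doses
    }
  }
  sites <- dplyr::bind_rows(sites)
  cm <- do.call(cbind, calls)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, ]
  cm <- cm[, ord, drop = FALSE]
  sites$vtype <- NULL
  sites$vtype <- rohdiversity:::classify_vtype(sites$ref, sites$alt)
  m0 <- geno_matrix(sprintf("S%02d", seq_len(n_samples)), sites, cm)
  # round-trip through VCF to exercise the reader on realistic records
  f <- tempfile(fileext = ".vcf")
  write_vcf(m0, f)
  on.exit(unlink(f))
  read_vcf(f)
}

# LD-block genotype data: `n_blocks` blocks of `block_size` markers, each
# block derived from one latent dosage vector with per-marker flip noise, so
# that within-block r-squared is high and between-block r-squared is ~0.
make_ld_blocks <- function(n_samples = 33, n_blocks = 120, block_size = 25,
                           flip = 0.02, seed = 7) {
  set.seed(seed)
  cols <- list()
  for (b in seq_len(n_blocks)) {
    p <- runif(1, 0.2, 0.8)
    latent <- rbinom(n_samples, 2, p)
    for (k in seq_len(block_size)) {
      g <- latent
      nflip <- rbinom(1, n_samples, flip)
      if (nflip > 0) {
        i <- sample.int(n_samples, nflip)
        g[i] <- sample(0:2, nflip, replace = TRUE)
      }
      cols[[length(cols) + 1L]] <- g
    }
  }
  make_geno(do.call(cbind, cols))
}
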