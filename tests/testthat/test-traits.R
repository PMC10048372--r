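fixture <- table2_fixture()

test_that("genotype-class counts reproduce the published cohort table", {
  defs <- trait_variant_defs()
  counts <- genotype_counts(fixture, defs)
  expect_true(all(counts$present))
  sod1 <- counts[counts$label == "SOD1_c118", ]
  expect_equal(c(sod1$n_refref, sod1$n_refalt, sod1$n_altalt), c(10L, 21L, 2L))
  # counts plus missing always total the cohort size
  expect_true(all(counts$n_refref + counts$n_refalt + counts$n_altalt +
                    counts$n_missing == 33L))
  # per-sample loop oracle equals the vectorized tally
  for (k in c(1, 5, 10)) {
    i <- which(fixture$sites$chrom == defs$chrom[k] &
                 fixture$sites$pos == defs$pos[k])
    tally <- c(0L, 0L, 0L)
    for (s in seq_along(fixture$samples)) {
      g <- fixture$calls[s, i]
      if (!is.na(g)) tally[g + 1L] <- tally[g + 1L] + 1L
    }
    expect_equal(unlist(counts[k, c("n_refref", "n_refalt", "n_altalt")],
                        use.names = FALSE), tally)
  }
})

test_that("absent variants are reported as not genotyped, never as zeros", {
  defs <- tibble::tibble(label = "ghost", chrom = "chr1", pos = 123)
  res <- genotype_counts(fixture, defs)
  expect_false(res$present)
  expect_true(is.na(res$n_refref))
})

test_that("allele frequencies match the published values at 3 decimals", {
  defs <- trait_variant_defs()
  af <- allele_frequency(genotype_counts(fixture, defs))
  expect_equal(af$af, as.numeric(defs$freq_published))

  # worked examples: 25/66 and 64/66
  expect_equal(allele_frequency(tibble::tibble(
    n_refref = 10, n_refalt = 21, n_altalt = 2))$af, 0.379)
  expect_equal(allele_frequency(tibble::tibble(
    n_refref = 1, n_refalt = 0, n_altalt = 32))$af, 0.970)
  expect_equal(allele_frequency(tibble::tibble(
    n_refref = 0, n_refalt = 0, n_altalt = 21))$af, 1.000)
  expect_true(is.na(allele_frequency(tibble::tibble(
    n_refref = 0, n_refalt = 0, n_altalt = 0))$af))

  # frequency from counts equals the direct per-allele tally
  monomorphic <- make_geno(matrix(0L, 10, 1))
  cnt <- genotype_counts(monomorphic,
                         tibble::tibble(label = "m", chrom = "chr1",
                                        pos = 1e4))
  expect_equal(c(cnt$n_refref, cnt$n_refalt, cnt$n_altalt), c(10L, 0L, 0L))
  expect_equal(allele_frequency(cnt)$af, 0)
})

test_that("haplotype doses follow the consensus rule and missing-data policy", {
  loci <- risk_locus_defs()
  doses <- haplotype_dose(fixture, loci)

  chr11_41 <- doses[doses$locus == "chr11:41Mb", ]
  expect_equal(as.integer(table(factor(chr11_41$dose, levels = 0:2))),
               c(2L, 14L, 17L))
  hap_af <- allele_frequency(tibble::tibble(
    n_refref = sum(chr11_41$dose == 0), n_refalt = sum(chr11_41$dose == 1),
    n_altalt = sum(chr11_41$dose == 2)))
  expect_equal(hap_af$af, 0.727)

  expect_equal(sort(unique(doses$discordance)), 0)  # unanimous fixture

  # unanimity and half-genotyped rule on a hand-built locus
  m <- make_geno(rbind(c(2L, 2L, 2L, 2L),
                       c(1L, 1L, 1L, 1L),
                       c(0L, NA, NA, NA)))
  defs <- tibble::tibble(locus = "L", chrom = "chr1",
                         pos = c(1e4, 2e4, 3e4, 4e4))
  d <- haplotype_dose(m, defs)
  expect_equal(d$dose, c(2L, 1L, NA))
})

test_that("risk index is monotone for every dose vector", {
  expect_equal(risk_index(c(0, 0, 0, 0)), "A")
  expect_equal(risk_index(c(2, 2, 2, 2)), "C")
  expect_true(is.na(risk_index(c(2, NA, 0, 1))))

  grid <- expand.grid(0:2, 0:2, 0:2, 0:2)
  lvl <- function(x) match(x, c("A", "B", "C"))
  for (r in seq_len(nrow(grid))) {
    doses <- as.numeric(grid[r, ])
    here <- lvl(risk_index(doses))
    for (k in 1:4) {
      if (doses[k] < 2) {
        up <- doses
        up[k] <- up[k] + 1
        expect_gte(lvl(risk_index(up)), here)
      }
    }
  }

  tbl <- tibble::tibble(sample = rep(c("a", "b"), each = 2),
                        locus = rep(c("l1", "l2"), 2),
                        dose = c(0L, 1L, 2L, 2L))
  res <- risk_index(tbl, cuts = c(2, 5))
  expect_equal(as.character(res$index), c("A", "B"))
})

test_that("group frequency comparison reproduces the continental contrast", {
  res <- compare_group_frequencies(35, 42, 13, 24)
  expect_equal(round(res$freq1, 3), 0.833)
  expect_equal(round(res$freq2, 3), 0.542)
  expect_equal(res$p_value, oracle_fisher_p(35, 42, 13, 24),
               tolerance = 1e-9)
  expect_lt(res$p_value, 0.05)

  bal <- compare_group_frequencies(5, 10, 5, 10)
  expect_equal(bal$p_value, 1)

  expect_warning(deg <- compare_group_frequencies(0, 0, 3, 10), "margin")
  expect_equal(deg$p_value, 1)
})

test_that("Fisher p equals exhaustive enumeration on small tables", {
  set.seed(62)
  for (rep in 1:10) {
    n1 <- sample(4:12, 1)
    n2 <- sample(4:12, 1)
    k1 <- sample(0:n1, 1)
    k2 <- sample(0:n2, 1)
    if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2)) next
    res <- compare_group_frequencies(k1, n1, k2, n2)
    expect_equal(res$p_value, oracle_fisher_p(k1, n1, k2, n2),
                 tolerance = 1e-9,
                 info = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2))
  }
})

test_that("mtDNA haplotypes are assigned by full definition match", {
  tbl <- mtdna_haplotype_table()
  a22 <- tbl[tbl$haplotype == "A22", c("pos", "allele")]

  res <- mtdna_haplotype(a22, tbl)
  expect_equal(res$haplotype, "A22")
  expect_equal(nrow(res$unexplained), 0)

  # a private coding variant rides along unexplained
  plus <- dplyr::bind_rows(a22, tibble::tibble(pos = 4378, allele = "G"))
  res2 <- mtdna_haplotype(plus, tbl)
  expect_equal(res2$haplotype, "A22")
  expect_equal(res2$unexplained$pos, 4378)

  # profile matching both definitions reports both labels
  both <- unique(tbl[, c("pos", "allele")])
  res3 <- mtdna_haplotype(both, tbl)
  expect_setequal(res3$haplotype, c("A2", "A22"))

  # empty profile: unassigned with the best partial match reported
  res4 <- mtdna_haplotype(tibble::tibble(pos = numeric(),
                                         allele = character()), tbl)
  expect_equal(res4$haplotype, "unassigned")
  expect_false(is.null(res4$best_partial))
})
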