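test_that("observed heterozygosity counts hets among called genotypes", {
  m <- make_geno(rbind(c(1L, 1L, 1L, 1L),
                       c(0L, 1L, 2L, NA),
                       c(NA, NA, NA, NA)))
  het <- observed_heterozygosity(m)
  expect_equal(het$obs_het[1], 1.0)
  expect_equal(het$obs_het[2], 1 / 3)
  expect_true(is.na(het$obs_het[3]))
  expect_equal(attr(het, "cohort_mean"), mean(c(1, 1 / 3)))
})

test_that("denominator sums per-chromosome SNV spans, or takes an override", {
  m <- make_geno(matrix(0L, 1, 4),
                 chrom = c("c1", "c1", "c2", "c2"),
                 pos = c(100, 1099, 500, 2499))
  expect_equal(compute_denominator(m), 1000 + 2000)
  expect_equal(compute_denominator(m, override = 2225350880), 2225350880)
})

test_that("F_ROH reproduces the published worked example and edge cases", {
  d <- 2225350880
  one <- tibble::tibble(sample = "dog", chrom = "1",
                        start = 1, end = 878100000, length_bp = 878100000)
  expect_equal(round(froh(one, d)$froh, 3), 0.395)

  expect_equal(froh(one[0, ], d, all_samples = "dog")$froh, 0)
  whole <- tibble::tibble(sample = "dog", chrom = "1",
                          start = 1, end = d, length_bp = d)
  expect_equal(froh(whole, d)$froh, 1)

  ovl <- tibble::tibble(sample = "dog", chrom = c("1", "1"),
                        start = c(100, 500), end = c(1000, 900),
                        length_bp = c(901, 401))
  expect_error(froh(ovl, d), "overlap")
})

test_that("length classes partition F_ROH exactly and bin half-open", {
  d <- 1e9
  scheme <- length_class_scheme()
  seg <- tibble::tibble(sample = "s", chrom = "1",
                        start = 1, end = 2.5e6, length_bp = 2.5e6)
  byc <- froh_by_class(seg, scheme, d)
  expect_equal(byc$froh_class[byc$class == "2-4 Mb"], 2.5e6 / d)
  expect_equal(sum(byc$froh_class), froh(seg, d)$froh)

  # boundary lengths go to the upper class: [lower, upper)
  expect_equal(as.character(length_class(1e6, scheme)), "1-2 Mb")
  expect_equal(as.character(length_class(1e6 - 1, scheme)), "<1 Mb")
  expect_equal(as.character(length_class(1e7, scheme)), ">10 Mb")

  # random cohort: partition property and invariance to ordering/relabeling
  set.seed(14)
  segs <- tibble::tibble(
    sample = sample(c("a", "b"), 40, TRUE),
    chrom = sample(c("c1", "c2", "c3", "c4"), 40, TRUE),
    start = round(runif(40, 1, 1e8))
  )
  segs$end <- segs$start + round(stats::rexp(40, 1 / 3e6)) + 1e5
  segs$length_bp <- segs$end - segs$start + 1
  segs <- segs[!duplicated(segs[, c("sample", "chrom")]), ]  # avoid overlap
  total <- froh(segs, d)
  parts <- froh_by_class(segs, scheme, d) |>
    dplyr::group_by(sample) |>
    dplyr::summarise(froh = sum(froh_class))
  expect_equal(parts$froh[order(parts$sample)],
               total$froh[order(total$sample)], tolerance = 1e-12)

  shuffled <- segs[sample.int(nrow(segs)), ]
  shuffled$chrom <- paste0("renamed_", shuffled$chrom)
  expect_equal(sort(froh(shuffled, d)$froh), sort(total$froh))
})

test_that("one-way ANOVA matches the textbook oracle and degenerate cases", {
  # identical group means with spread: F = 0, p = 1
  res0 <- group_anova(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  res <- group_anova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  orc <- oracle_anova(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)

  expect_error(group_anova(1:5, c("a", "a", "a", "a", "b")), "2 samples")
  expect_error(group_anova(1:4, rep("a", 4)), "two groups")

  g <- glance(res)
  expect_equal(g$statistic, res$statistic)
  expect_equal(nrow(tidy(res)), 2)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(77)
  ps <- replicate(1000, {
    v <- stats::rnorm(20)
    g <- rep(c("fr", "se", "ch", "us"), each = 5)
    group_anova(v, g)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort heterozygosity tracks h*(1-F) on simulated data", {
  h <- 0.268
  cfg <- sim_config(n_samples = 20, chrom_lengths = c(c1 = 2e7, c2 = 2e7),
                    snv_density = 150, het_outside = h, target_froh = 0.4,
                    n_pops = 1, divergence = 0, missing_rate = 0.02,
                    error_rate = 1e-3, seed = 55)
  sim <- simulate_cohort(cfg)
  het <- observed_heterozygosity(sim$geno)
  f_bar <- mean(sim$truth$samples$true_froh)
  expected <- h * (1 - f_bar) + 1e-3 * f_bar
  # dominant Monte Carlo error: the finite-site average of 2p(1-p)
  q <- sim$truth$site_freqs$freq
  se_site <- stats::sd(2 * q * (1 - q)) / sqrt(length(q)) * (1 - f_bar)
  se_samp <- stats::sd(het$obs_het) / sqrt(nrow(het))
  se <- sqrt(se_site^2 + se_samp^2)
  expect_lt(abs(attr(het, "cohort_mean") - expected), 3 * se + 1e-4)
})

test_that("sample_diversity assembles a coherent per-sample table", {
  cfg <- sim_config(n_samples = 6, chrom_lengths = c(c1 = 1e7),
                    snv_density = 300, target_froh = 0.3, seed = 8)
  sim <- simulate_cohort(cfg)
  segs <- quiet_detect(sim$geno, roh_params(min_snv = 60))
  groups <- tibble::tibble(sample = sim$geno$samples,
                           group = rep(c("EU", "US"), 3))
  sd_tbl <- sample_diversity(sim$geno, segs, groups = groups)
  expect_equal(nrow(sd_tbl), 6)
  expect_true(all(c("group", "froh", "obs_het") %in% names(sd_tbl)))
  class_cols <- grep("^froh_", names(sd_tbl), value = TRUE)
  expect_equal(rowSums(sd_tbl[, class_cols]), sd_tbl$froh, tolerance = 1e-12,
               ignore_attr = TRUE)
})
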