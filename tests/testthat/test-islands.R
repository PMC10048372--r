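test_that("incidence is the per-SNV fraction of samples in ROH", {
  pos <- seq(1e5, 1e6, by = 1e5)  # 10 SNVs
  m <- make_geno(matrix(0L, 33, 10), pos = pos)
  # 30 of 33 samples covered at SNVs 3..6
  segs <- tibble::tibble(sample = m$samples[1:30], chrom = "chr1",
                         start = pos[3], end = pos[6])
  track <- snv_incidence(segs, m)
  expect_equal(track$incidence[3], 30 / 33)
  expect_equal(round(track$incidence[3], 4), 0.9091)
  expect_equal(track$incidence[1], 0)
  expect_equal(track$incidence[7], 0)
})

test_that("incidence matches the interval-stabbing oracle and the coverage matrix", {
  set.seed(40)
  pos <- sort(sample.int(5e6, 50))
  m <- make_geno(matrix(0L, 12, 50), pos = pos)
  segs <- tibble::tibble(
    sample = sample(m$samples, 30, TRUE),
    chrom = "chr1",
    start = sort(sample.int(4e6, 30))
  )
  segs$end <- segs$start + sample.int(8e5, 30)
  # enforce non-overlap within sample by keeping first per sample region
  segs <- segs[!duplicated(segs$sample), ]
  track <- snv_incidence(segs, m)
  expect_equal(track$incidence, oracle_incidence(segs, m))

  # independent construction: boolean coverage matrix
  cov <- matrix(FALSE, length(m$samples), 50)
  for (i in seq_len(nrow(segs))) {
    s <- match(segs$sample[i], m$samples)
    cov[s, ] <- cov[s, ] | (pos >= segs$start[i] & pos <= segs$end[i])
  }
  expect_equal(track$incidence, colMeans(cov))
})

test_that("islands are maximal threshold runs with no minimum size", {
  pos <- seq_len(20) * 1e5
  mk_track <- function(counts, n = 33) {
    tibble::tibble(chrom = "chr1", pos = pos[seq_along(counts)],
                   n_covered = counts, incidence = counts / n)
  }
  # uniformly above threshold: one island spanning first to last SNV
  tr <- mk_track(rep(32L, 20))
  isl <- call_islands(tr, 0.90, n_samples = 33)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start, pos[1])
  expect_equal(isl$end, pos[20])
  expect_equal(isl$n_snvs, 20L)

  # single qualifying SNV flanked by low incidence is still an island
  tr2 <- mk_track(c(16L, 30L, 16L))
  isl2 <- call_islands(tr2, 0.90, n_samples = 33)
  expect_equal(nrow(isl2), 1L)
  expect_equal(isl2$n_snvs, 1L)
  expect_equal(isl2$start, isl2$end)

  # >= 90% of 33 requires exactly 30 samples (ceiling of 29.7)
  expect_equal(nrow(call_islands(mk_track(rep(30L, 5)), 0.90,
                                 n_samples = 33)), 1L)
  expect_equal(nrow(call_islands(mk_track(rep(29L, 5)), 0.90,
                                 n_samples = 33)), 0L)
})

test_that("island membership is exact and non-increasing in the threshold", {
  set.seed(71)
  counts <- sample(0:33, 200, replace = TRUE)
  track <- tibble::tibble(chrom = "chr1", pos = seq_len(200) * 1e4,
                          n_covered = counts, incidence = counts / 33)
  for (thr in c(0.5, 0.8, 0.9)) {
    isl <- call_islands(track, thr, n_samples = 33)
    member <- rep(FALSE, 200)
    for (i in seq_len(nrow(isl))) {
      member <- member | (track$pos >= isl$start[i] & track$pos <= isl$end[i])
    }
    expect_identical(member, counts >= ceiling(thr * 33 - 1e-9))
  }
  snvs_at <- vapply(c(0.5, 0.7, 0.9, 0.95),
                    function(t) sum(call_islands(track, t,
                                                 n_samples = 33)$n_snvs),
                    numeric(1))
  expect_true(all(diff(snvs_at) <= 0))
})

test_that("gene annotation uses any-overlap semantics", {
  gff <- system.file("extdata", "genes_synthetic.gff3",
                     package = "rohdiversity")
  isl <- tibble::tibble(chrom = c("2", "2", "2"),
                        start = c(71838359, 60000000, 71935000),
                        end = c(71946097, 60001000, 72120000),
                        n_snvs = c(100L, 2L, 50L),
                        min_incidence = 1, max_gap_bp = 0)
  ann <- annotate_islands(isl, gff)
  expect_setequal(ann$genes[[1]],
                  c("SMPDL3B", "RPA2", "THEMIS2", "LOC119870383",
                    "PPP1R8", "LOC119870569"))
  expect_length(ann$genes[[2]], 0)
  # gene overlapping two islands is listed in both
  expect_true("LOC119870569" %in% ann$genes[[3]])
  expect_true("LOC119870569" %in% ann$genes[[1]])

  expect_warning(
    annotate_islands(tibble::tibble(chrom = "chr99", start = 1, end = 10,
                                    n_snvs = 1L, min_incidence = 1,
                                    max_gap_bp = 0), gff),
    "absent"
  )
})

test_that("haplotype audit detects identity and heterozygous breaks", {
  pos <- seq_len(30) * 1e4
  region <- list(chrom = "chr1", start = pos[1], end = pos[30])

  hom <- make_geno(matrix(2L, 33, 30), pos = pos)
  aud <- haplotype_audit(region, hom)
  expect_equal(aud$verdict, "identical")
  expect_equal(nrow(aud$het_breaks), 0)

  # five dogs with the same two internal heterozygous stretches
  calls <- matrix(2L, 33, 30)
  calls[1:5, 8:10] <- 1L
  calls[1:5, 20:22] <- 1L
  m <- make_geno(calls, pos = pos)
  aud2 <- haplotype_audit(region, m, min_run = 2)
  expect_equal(aud2$verdict, "not_identical")
  expect_equal(nrow(aud2$het_breaks), 2)
  expect_equal(aud2$het_breaks$n_samples, c(5L, 5L))
  expect_equal(aud2$het_breaks$start, c(pos[8], pos[20]))

  # a single discordant homozygote flips the verdict without a het break
  calls3 <- matrix(2L, 33, 30)
  calls3[7, 15] <- 0L
  aud3 <- haplotype_audit(region, make_geno(calls3, pos = pos))
  expect_equal(aud3$verdict, "not_identical")
  expect_equal(nrow(aud3$het_breaks), 0)

  # isolated single het below min_run is not a break
  calls4 <- matrix(2L, 33, 30)
  calls4[3, 12] <- 1L
  aud4 <- haplotype_audit(region, make_geno(calls4, pos = pos), min_run = 2)
  expect_equal(nrow(aud4$het_breaks), 0)
})
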