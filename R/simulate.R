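#' Configuration for the synthetic cohort simulator
#'
#' Defaults emulate the study cohort at desk scale: 33 diploid samples on a
#' few chromosomes of tens of Mb, non-ROH observed heterozygosity 0.268,
#' per-sample autozygosity targets drawn in 0.32-0.52, planted autozygous
#' segments spanning the six ROH length classes, sporadic heterozygous calls
#' inside true ROH at `error_rate`, under-10% missingness, and two
#' subpopulations with modest allele-frequency divergence.
#'
#' @param n_samples Number of diploid samples.
#' @param chrom_lengths Named or unnamed vector of chromosome lengths in bp.
#' @param snv_density SNVs per Mb.
#' @param het_outside Expected observed heterozygosity outside ROH; site
#'   frequencies are drawn from a symmetric Beta whose variance is solved to
#'   match this expectation under Hardy-Weinberg.
#' @param target_froh Per-sample autozygous fraction: a single value, a
#'   vector of length `n_samples`, or `NULL` to draw uniformly in
#'   0.32-0.52.
#' @param length_mixture Tibble with columns `lo`, `hi`, `weight`, `mean`
#'   (bp) defining a truncated-exponential mixture of planted segment
#'   lengths; default populates the six <1 to >10 Mb classes with most mass
#'   below 4 Mb.
#' @param error_rate Probability that a genotype inside a true autozygous
#'   segment is mis-called heterozygous.
#' @param missing_rate Per-genotype missingness probability.
#' @param n_pops Number of subpopulations (samples assigned round-robin).
#' @param divergence Standard deviation of the logit-normal perturbation of
#'   shared ancestral allele frequencies per subpopulation; 0 disables
#'   structure.
#' @param shared_region Optional list (`chrom`, `start`, `end`,
#'   `carrier_frac`) planting one fixed autozygous region in a fraction of
#'   samples (the first `ceiling(carrier_frac * n_samples)` samples), to
#'   emulate an ROH island.
#' @param seed Mandatory integer seed; the simulator is fully deterministic
#'   given the config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_samples = 33,
                       chrom_lengths = c(chr1 = 8e7, chr2 = 8e7, chr3 = 8e7),
                       snv_density = 500,
                       het_outside = 0.268,
                       target_froh = NULL,
                       length_mixture = default_length_mixture(),
                       error_rate = 1e-3,
                       missing_rate = 0.05,
                       n_pops = 2,
                       divergence = 0.3,
                       shared_region = NULL,
                       seed) {
  if (missing(seed)) rlang::abort("seed is mandatory")
  stopifnot(n_samples >= 1, all(chrom_lengths > 0), snv_density > 0,
            het_outside > 0, het_outside < 0.5,
            error_rate >= 0, error_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            n_pops >= 1, divergence >= 0)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  if (is.null(target_froh)) {
    target_froh <- NA_real_  # drawn uniformly in 0.32-0.52 at simulate time
  } else {
    stopifnot(all(target_froh >= 0), all(target_froh < 1),
              length(target_froh) %in% c(1L, n_samples))
    if (length(target_froh) == 1L) {
      target_froh <- rep(target_froh, n_samples)
    }
  }
  structure(
    list(n_samples = n_samples, chrom_lengths = chrom_lengths,
         snv_density = snv_density, het_outside = het_outside,
         target_froh = target_froh, length_mixture = length_mixture,
         error_rate = error_rate, missing_rate = missing_rate,
         n_pops = n_pops, divergence = divergence,
         shared_region = shared_region, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default planted-segment length mixture
#'
#' Six truncated-exponential components covering the <1 to >10 Mb ROH length
#' classes. The weights put most of the mass below 4 Mb and a few percent
#' above 10 Mb, the qualitative shape seen in inbred breed cohorts. The
#' first component starts at 300 kb, the study-style minimum reportable ROH
#' length, so every planted segment is in principle callable.
#'
#' @return Tibble with columns `lo`, `hi`, `weight`, `mean` (bp).
#' @export
default_length_mixture <- function() {
  tibble::tibble(
    lo = c(0.3, 1, 2, 4, 8, 10) * 1e6,
    hi = c(1, 2, 4, 8, 10, 25) * 1e6,
    weight = c(0.35, 0.28, 0.20, 0.10, 0.028, 0.042),
    mean = c(0.6, 1.4, 2.8, 5.5, 9, 13) * 1e6
  )
}

# truncated exponential on [lo, hi) with scale m, via inverse CDF
rtruncexp <- function(n, lo, hi, m) {
  u <- stats::runif(n)
  lo - m * log(1 - u * (1 - exp(-(hi - lo) / m)))
}

#' Simulate a genotyped cohort with planted autozygosity
#'
#' Sites are placed uniformly at the configured density; ancestral site
#' frequencies come from a symmetric Beta solved to give the configured
#' outside-ROH heterozygosity; subpopulation frequencies are logit-normal
#' perturbations of the ancestral ones. Per sample, autozygous segments are
#' drawn from the length mixture and placed uniformly without overlap until
#' the target autozygous fraction is reached (the last segment is trimmed to
#' land on the target). Genotypes inside segments are homozygous for an
#' allele drawn at the site frequency, flipped to heterozygous with
#' `error_rate`; outside, they are Hardy-Weinberg draws at the subpopulation
#' frequency. A missingness mask is applied last. Fully deterministic for a
#' fixed config.
#'
#' @param config A [sim_config()].
#' @return List with elements `geno` (a [geno_matrix()]) and `truth` (list:
#'   `segments` tibble of planted segments with length class, `samples`
#'   tibble with population label, target and realized autozygous fraction,
#'   `site_freqs` tibble of per-population allele frequencies).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths)
  genome_len <- sum(config$chrom_lengths)

  # --- sites ---
  site_list <- lapply(chroms, function(cc) {
    len <- config$chrom_lengths[[cc]]
    n <- max(2L, round(len * config$snv_density / 1e6))
    tibble::tibble(chrom = cc, pos = sort(sample.int(len, n)))
  })
  sites <- dplyr::bind_rows(site_list)
  n_sites <- nrow(sites)

  # --- allele frequencies ---
  # Beta(a, a) with Var = (0.5 - het)/2 so that E[2p(1-p)] = het
  v <- (0.5 - config$het_outside) / 2
  a <- (1 / (4 * v) - 1) / 2
  p_anc <- stats::rbeta(n_sites, a, a)
  p_anc <- pmin(pmax(p_anc, 0.005), 0.995)
  pop_freq <- matrix(rep(p_anc, each = config$n_pops),
                     nrow = config$n_pops)
  if (config$n_pops > 1 && config$divergence > 0) {
    for (k in seq_len(config$n_pops)) {
      pop_freq[k, ] <- stats::plogis(
        stats::qlogis(p_anc) + stats::rnorm(n_sites, 0, config$divergence))
    }
  }
  pops <- rep_len(seq_len(config$n_pops), config$n_samples)
  sample_ids <- sprintf("S%02d", seq_len(config$n_samples))

  target <- config$target_froh
  if (anyNA(target)) {
    target <- stats::runif(config$n_samples, 0.32, 0.52)
  }

  # --- planted segments ---
  carriers <- integer(0)
  if (!is.null(config$shared_region)) {
    sr <- config$shared_region
    frac <- if (is.null(sr$carrier_frac)) 1 else sr$carrier_frac
    carriers <- seq_len(ceiling(frac * config$n_samples))
  }
  seg_list <- vector("list", config$n_samples)
  for (s in seq_len(config$n_samples)) {
    segs <- tibble::tibble(chrom = character(), start = numeric(),
                           end = numeric())
    placed <- 0
    if (s %in% carriers) {
      sr <- config$shared_region
      segs <- tibble::tibble(chrom = sr$chrom, start = sr$start,
                             end = sr$end)
      placed <- sr$end - sr$start + 1
    }
    target_bp <- target[s] * genome_len
    fails <- 0L
    while (placed < target_bp - 1) {
      remaining <- target_bp - placed
      ci <- sample.int(nrow(config$length_mixture), 1,
                       prob = config$length_mixture$weight)
      len <- rtruncexp(1, config$length_mixture$lo[ci],
                       config$length_mixture$hi[ci],
                       config$length_mixture$mean[ci])
      if (len > remaining) {
        if (remaining < 3e5) break  # sub-callable remainder; accept shortfall
        len <- remaining
      }
      len <- round(len)
      cc <- sample(chroms, 1, prob = config$chrom_lengths)
      clen <- config$chrom_lengths[[cc]]
      if (len >= clen) { fails <- fails + 1L; next }
      st <- sample.int(clen - len, 1)
      en <- st + len - 1
      same <- segs[segs$chrom == cc, , drop = FALSE]
      if (nrow(same) > 0 && any(st <= same$end & en >= same$start)) {
        fails <- fails + 1L
        if (fails > 2000L) {
          rlang::abort(sprintf(
            "target_froh %.3f unreachable for sample %s: %.0f bp short",
            target[s], sample_ids[s], target_bp - placed))
        }
        next
      }
      segs <- dplyr::bind_rows(segs,
                               tibble::tibble(chrom = cc, start = st,
                                              end = en))
      placed <- placed + len
    }
    segs$sample <- sample_ids[s]
    seg_list[[s]] <- dplyr::arrange(segs, .data$chrom, .data$start)
  }
  truth_segments <- dplyr::bind_rows(seg_list) |>
    dplyr::mutate(length_bp = .data$end - .data$start + 1) |>
    dplyr::select("sample", "chrom", "start", "end", "length_bp")

  # --- genotypes ---
  calls <- matrix(NA_integer_, config$n_samples, n_sites)
  chrom_first <- vapply(chroms, function(cc) match(cc, sites$chrom),
                        integer(1))
  chrom_last <- vapply(chroms, function(cc) {
    length(sites$chrom) + 1L - match(cc, rev(sites$chrom))
  }, integer(1))
  for (s in seq_len(config$n_samples)) {
    q <- pop_freq[pops[s], ]
    g <- stats::rbinom(n_sites, 2L, q)
    segs <- seg_list[[s]]
    inside <- rep(FALSE, n_sites)
    for (r in seq_len(nrow(segs))) {
      i0 <- chrom_first[[segs$chrom[r]]]
      i1 <- chrom_last[[segs$chrom[r]]]
      pos_c <- sites$pos[i0:i1]
      lo <- findInterval(segs$start[r] - 0.5, pos_c) + 1L
      hi <- findInterval(segs$end[r] + 0.5, pos_c)
      if (lo <= hi) inside[(i0 + lo - 1L):(i0 + hi - 1L)] <- TRUE
    }
    n_in <- sum(inside)
    if (n_in > 0) {
      hom <- 2L * stats::rbinom(n_in, 1L, q[inside])
      err <- stats::runif(n_in) < config$error_rate
      hom[err] <- 1L
      g[inside] <- hom
    }
    if (config$missing_rate > 0) {
      g[stats::runif(n_sites) < config$missing_rate] <- NA_integer_
    }
    calls[s, ] <- g
  }

  sites$ref <- "A"
  sites$alt <- "C"
  sites$filter <- "PASS"
  sites$vtype <- "SNV"
  geno <- geno_matrix(sample_ids, sites, calls)

  realized <- vapply(seg_list, function(s) sum(s$end - s$start + 1),
                     numeric(1)) / genome_len
  truth_samples <- tibble::tibble(
    sample = sample_ids,
    pop = paste0("pop", pops),
    target_froh = target,
    true_froh = realized
  )
  site_freqs <- tibble::tibble(
    chrom = rep(sites$chrom, config$n_pops),
    pos = rep(sites$pos, config$n_pops),
    pop = rep(paste0("pop", seq_len(config$n_pops)), each = n_sites),
    freq = as.vector(t(pop_freq))
  )
  list(geno = geno,
       truth = list(segments = truth_segments, samples = truth_samples,
                    site_freqs = site_freqs))
}

#' Compare called ROH segments against simulator truth
#'
#' Base-pair recall is the planted length recovered by called segments;
#' precision is the called length that lies inside planted segments. Both
#' are reported per sample, per planted length class, and overall. A sample
#' with no called segments has undefined precision (reported `NA`).
#'
#' @param called Called segments (`sample`, `chrom`, `start`, `end`).
#' @param truth_segments Planted segments from [simulate_cohort()] truth.
#' @param scheme Length-class scheme used for the per-class breakdown of
#'   planted segments.
#' @return List of tibbles: `by_sample`, `by_class`, `overall`.
#' @export
truth_compare <- function(called, truth_segments,
                          scheme = length_class_scheme()) {
  called <- tibble::as_tibble(called)
  truth_segments <- tibble::as_tibble(truth_segments) |>
    dplyr::mutate(length_bp = .data$end - .data$start + 1,
                  class = length_class(.data$end - .data$start + 1, scheme))

  overlap_bp <- function(a_start, a_end, b_start, b_end) {
    if (length(a_start) == 0 || length(b_start) == 0) return(0)
    ia <- IRanges::reduce(IRanges::IRanges(a_start, a_end))
    ib <- IRanges::reduce(IRanges::IRanges(b_start, b_end))
    sum(IRanges::width(IRanges::intersect(ia, ib)))
  }

  samples <- unique(truth_segments$sample)
  by_sample <- purrr::map_dfr(samples, function(sm) {
    tr <- truth_segments[truth_segments$sample == sm, ]
    ca <- called[called$sample == sm, ]
    ov <- sum(vapply(unique(tr$chrom), function(cc) {
      overlap_bp(tr$start[tr$chrom == cc], tr$end[tr$chrom == cc],
                 ca$start[ca$chrom == cc], ca$end[ca$chrom == cc])
    }, numeric(1)))
    planted <- sum(tr$length_bp)
    called_len <- sum(ca$end - ca$start + 1)
    tibble::tibble(sample = sm, planted_bp = planted,
                   called_bp = called_len, overlap_bp = ov,
                   recall = ifelse(planted > 0, ov / planted, NA_real_),
                   precision = ifelse(called_len > 0, ov / called_len,
                                      NA_real_))
  })

  by_class <- truth_segments |>
    dplyr::mutate(recovered = purrr::pmap_dbl(
      list(.data$sample, .data$chrom, .data$start, .data$end),
      function(sm, cc, st, en) {
        ca <- called[called$sample == sm & called$chrom == cc, ]
        overlap_bp(st, en, ca$start, ca$end)
      })) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(planted_bp = sum(.data$length_bp),
                     recovered_bp = sum(.data$recovered),
                     recall = sum(.data$recovered) / sum(.data$length_bp),
                     .groups = "drop")

  overall <- tibble::tibble(
    recall = sum(by_sample$overlap_bp) / sum(by_sample$planted_bp),
    precision = ifelse(sum(by_sample$called_bp) > 0,
                       sum(by_sample$overlap_bp) / sum(by_sample$called_bp),
                       NA_real_)
  )
  list(by_sample = by_sample, by_class = by_class, overall = overall)
}
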