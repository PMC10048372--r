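#' Parameters for sliding-window ROH detection
#'
#' Defaults follow the PLINK v1.9 `--homozyg` conventions: scanning windows of
#' 50 SNVs, at most 5 missing calls per homozygous window, a 5% window-hit
#' threshold per SNV, a maximum gap of 1000 kb between consecutive segment
#' SNVs, and a density bound of 50 kb per SNV. The study-style settings are
#' 3 heterozygous calls tolerated per window and a 300 kb minimum segment
#' length. `min_snv` may be left `NULL`, in which case [detect_roh()] computes
#' it from the data with [min_snv_threshold()].
#'
#' @param window_snp SNVs per scanning window.
#' @param window_het Maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_missing Maximum missing calls for a window to count as
#'   homozygous.
#' @param hit_threshold Minimum fraction of homozygous windows covering a SNV
#'   for that SNV to be ROH-eligible.
#' @param min_snv Minimum SNVs per called segment, or `NULL` to calibrate from
#'   the data.
#' @param min_kb Minimum segment length in kb.
#' @param max_gap_kb Maximum distance between consecutive segment SNVs, kb.
#' @param max_kb_per_snv Maximum average kb per SNV inside a segment.
#' @return A `roh_params` object.
#' @export
roh_params <- function(window_snp = 50, window_het = 3, window_missing = 5,
                       hit_threshold = 0.05, min_snv = NULL, min_kb = 300,
                       max_gap_kb = 1000, max_kb_per_snv = 50) {
  stopifnot(window_snp >= 1, window_het >= 0, window_missing >= 0,
            hit_threshold > 0, hit_threshold <= 1,
            min_kb > 0, max_gap_kb > 0, max_kb_per_snv > 0)
  if (!is.null(min_snv)) stopifnot(min_snv >= 1)
  structure(
    list(window_snp = as.integer(window_snp),
         window_het = as.integer(window_het),
         window_missing = as.integer(window_missing),
         hit_threshold = hit_threshold,
         min_snv = if (is.null(min_snv)) NULL else as.integer(min_snv),
         min_kb = min_kb, max_gap_kb = max_gap_kb,
         max_kb_per_snv = max_kb_per_snv),
    class = "roh_params"
  )
}

#' Minimum SNVs per ROH to bound the false-ROH rate
#'
#' Under random mating, a stretch of l consecutive SNVs is spuriously
#' homozygous in one individual with probability about (1 - het)^l, where
#' het is the mean observed heterozygosity. Requiring
#'
#'   l >= ln(alpha / (n_samples * n_snvs)) / ln(1 - het)
#'
#' bounds the expected number of chance ROH across the whole dataset below
#' alpha. The returned value is the ceiling of that ratio.
#'
#' @param alpha Tolerated rate of randomly generated ROH (e.g. 0.05).
#' @param n_samples Number of individuals.
#' @param n_snvs Number of SNVs in the working dataset.
#' @param mean_het Mean observed heterozygosity, strictly in (0, 1).
#' @return Integer minimum number of SNVs per ROH.
#' @export
min_snv_threshold <- function(alpha, n_samples, n_snvs, mean_het) {
  stopifnot(alpha > 0, alpha < 1, n_samples >= 1, n_snvs >= 1)
  if (mean_het <= 0 || mean_het >= 1) {
    rlang::abort("mean_het must be strictly between 0 and 1")
  }
  as.integer(ceiling(log(alpha / (n_samples * n_snvs)) / log(1 - mean_het)))
}

#' Sliding-window eligibility scan for one sample on one chromosome
#'
#' Every window of `window_snp` consecutive SNVs is classed homozygous iff it
#' contains at most `window_het` heterozygous and at most `window_missing`
#' missing calls. Each SNV's hit fraction is the proportion of windows
#' containing it that are homozygous; the SNV is ROH-eligible iff that
#' fraction reaches `hit_threshold` and its own call is not heterozygous.
#' Chromosomes with fewer SNVs than `window_snp` are scanned with a single
#' truncated window covering all of them.
#'
#' @param calls Integer dosage vector for one sample (0/1/2/NA).
#' @param positions Strictly increasing bp positions, same length as `calls`.
#' @param params A [roh_params()].
#' @return Logical eligibility mask, one element per SNV.
#' @export
window_scan <- function(calls, positions, params = roh_params()) {
  n <- length(calls)
  stopifnot(length(positions) == n)
  if (n == 0) return(logical(0))
  het <- !is.na(calls) & calls == 1L
  miss <- is.na(calls)
  w <- min(params$window_snp, n)
  nwin <- n - w + 1L
  cs_het <- c(0L, cumsum(het))
  cs_miss <- c(0L, cumsum(miss))
  starts <- seq_len(nwin)
  win_het <- cs_het[starts + w] - cs_het[starts]
  win_miss <- cs_miss[starts + w] - cs_miss[starts]
  homwin <- win_het <= params$window_het & win_miss <= params$window_missing
  cs_hom <- c(0L, cumsum(homwin))
  j <- seq_len(n)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nwin)
  n_containing <- hi - lo + 1L
  n_hits <- cs_hom[hi + 1L] - cs_hom[lo]
  frac <- n_hits / n_containing
  frac >= params$hit_threshold - 1e-12 & !het
}

#' Assemble ROH segments from an eligibility mask
#'
#' Maximal runs of eligible SNVs are split wherever the gap between
#' consecutive SNVs exceeds `max_gap_kb`, trimmed so that no segment begins or
#' ends on a missing call, and emitted when they meet the `min_snv`, `min_kb`
#' and kb-per-SNV density thresholds. Missing-call SNVs inside a run do not
#' break it and are spanned by the segment, but are not counted in `n_snvs`.
#'
#' @param mask Logical eligibility mask from [window_scan()].
#' @param calls,positions As in [window_scan()].
#' @param params A [roh_params()] whose `min_snv` must be set.
#' @return Tibble with columns `start`, `end`, `n_snvs`, `n_het`, `length_bp`
#'   (1-based inclusive coordinates).
#' @export
call_segments <- function(mask, calls, positions, params = roh_params(min_snv = 72)) {
  n <- length(mask)
  stopifnot(length(calls) == n, length(positions) == n)
  if (is.null(params$min_snv)) {
    rlang::abort("params$min_snv must be set; see min_snv_threshold()")
  }
  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          n_snvs = integer(), n_het = integer(),
                          length_bp = numeric())
  if (n == 0 || !any(mask)) return(empty)
  r <- rle(mask)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  out <- vector("list", sum(r$values))
  k <- 0L
  max_gap <- params$max_gap_kb * 1000
  for (ri in which(r$values)) {
    i0 <- run_start[ri]; i1 <- run_end[ri]
    idx <- i0:i1
    # split on large inter-SNV gaps
    gaps <- diff(positions[idx])
    cut_after <- which(gaps > max_gap)
    piece_bounds <- cbind(c(1L, cut_after + 1L), c(cut_after, length(idx)))
    for (pi in seq_len(nrow(piece_bounds))) {
      p <- idx[piece_bounds[pi, 1]:piece_bounds[pi, 2]]
      # trim so segment ends land on called (non-missing) SNVs
      called <- !is.na(calls[p])
      if (!any(called)) next
      p <- p[min(which(called)):max(which(called))]
      n_snvs <- sum(!is.na(calls[p]))
      len <- positions[p[length(p)]] - positions[p[1]] + 1
      if (n_snvs >= params$min_snv &&
          len >= params$min_kb * 1000 &&
          len / n_snvs <= params$max_kb_per_snv * 1000) {
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          start = positions[p[1]], end = positions[p[length(p)]],
          n_snvs = n_snvs,
          n_het = sum(!is.na(calls[p]) & calls[p] == 1L),
          length_bp = len
        )
      }
    }
  }
  if (k == 0L) return(empty)
  dplyr::bind_rows(out[seq_len(k)])
}

#' Detect runs of homozygosity for every sample in a cohort
#'
#' Runs the sliding-window scan and segment assembly per sample and per
#' chromosome. If `params$min_snv` is `NULL` it is calibrated from the matrix
#' itself via [min_snv_threshold()] at the given `alpha`, using the cohort
#' mean observed heterozygosity, and the chosen value is reported in a
#' message and attached as the `min_snv` attribute of the result.
#'
#' @param m A filtered [geno_matrix()].
#' @param params A [roh_params()].
#' @param alpha False-ROH rate used when calibrating `min_snv`.
#' @return Tibble of segments: `sample`, `chrom`, `start`, `end`, `n_snvs`,
#'   `n_het`, `length_bp`, sorted by (sample, chrom, start). Deterministic for
#'   fixed input.
#' @export
detect_roh <- function(m, params = roh_params(), alpha = 0.05) {
  stopifnot(inherits(m, "geno_matrix"))
  if (is.null(params$min_snv)) {
    het <- observed_heterozygosity(m)
    params$min_snv <- min_snv_threshold(alpha, length(m$samples),
                                        nrow(m$sites),
                                        attr(het, "cohort_mean"))
    rlang::inform(paste0("min_snv calibrated to ", params$min_snv))
  }
  chroms <- unique(m$sites$chrom)
  chrom_idx <- lapply(chroms, function(cc) which(m$sites$chrom == cc))
  res <- purrr::map(seq_along(m$samples), function(i) {
    per_chrom <- purrr::map(seq_along(chroms), function(ci) {
      idx <- chrom_idx[[ci]]
      calls <- m$calls[i, idx]
      pos <- m$sites$pos[idx]
      mask <- window_scan(calls, pos, params)
      seg <- call_segments(mask, calls, pos, params)
      if (nrow(seg) > 0) {
        seg$sample <- m$samples[i]
        seg$chrom <- chroms[ci]
      }
      seg
    })
    dplyr::bind_rows(per_chrom)
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_snvs = integer(), n_het = integer(),
                          length_bp = numeric())
  } else {
    out <- dplyr::select(out, "sample", "chrom", "start", "end",
                         "n_snvs", "n_het", "length_bp")
    out <- dplyr::arrange(out, .data$sample, .data$chrom, .data$start)
  }
  attr(out, "min_snv") <- params$min_snv
  out
}
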