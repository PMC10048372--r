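#' Per-SNV ROH incidence across the cohort
#'
#' For each retained SNV, the fraction of samples with at least one ROH
#' segment spanning its position.
#'
#' @param segments ROH segments for all samples ([detect_roh()] output).
#' @param m The [geno_matrix()] the segments were derived from.
#' @return Tibble with `chrom`, `pos`, `n_covered`, `incidence`, ordered as
#'   the sites of `m`.
#' @export
snv_incidence <- function(segments, m) {
  stopifnot(inherits(m, "geno_matrix"))
  segments <- tibble::as_tibble(segments)
  n_samples <- length(m$samples)
  count <- integer(nrow(m$sites))
  for (cc in unique(m$sites$chrom)) {
    idx <- which(m$sites$chrom == cc)
    pos <- m$sites$pos[idx]
    seg <- segments[segments$chrom == cc, , drop = FALSE]
    if (nrow(seg) == 0) next
    # segments are non-overlapping within a sample, so summing index ranges
    # over all segments counts each (sample, SNV) pair at most once
    lo <- findInterval(seg$start - 0.5, pos) + 1L  # first pos >= start
    hi <- findInterval(seg$end + 0.5, pos)         # last pos <= end
    keep <- lo <= hi
    if (!any(keep)) next
    delta <- integer(length(idx) + 1L)
    for (k in which(keep)) {
      delta[lo[k]] <- delta[lo[k]] + 1L
      delta[hi[k] + 1L] <- delta[hi[k] + 1L] - 1L
    }
    count[idx] <- cumsum(delta[seq_along(idx)])
  }
  tibble::tibble(chrom = m$sites$chrom, pos = m$sites$pos,
                 n_covered = count, incidence = count / n_samples)
}

#' Call ROH islands from an incidence track
#'
#' Islands are maximal runs of consecutive SNVs (in SNV-index order within a
#' chromosome; bp gaps do not break islands) whose incidence reaches the
#' threshold. There is no minimum size: a single qualifying SNV is an island.
#' With n samples, "at least 90%" means at least `ceiling(0.9 * n)` samples
#' (30 of 33). The largest bp gap between consecutive member SNVs is reported
#' for audit.
#'
#' @param track Incidence track from [snv_incidence()], ordered by
#'   (chrom, pos).
#' @param threshold Minimum incidence, default 0.90.
#' @param n_samples Cohort size used to convert the threshold into a minimum
#'   sample count; taken from the track's `n_covered`/`incidence` ratio if
#'   absent.
#' @return Tibble with `chrom`, `start`, `end`, `n_snvs`, `min_incidence`,
#'   `max_gap_bp`, sorted by (chrom, start).
#' @export
call_islands <- function(track, threshold = 0.90, n_samples = NULL) {
  track <- tibble::as_tibble(track)
  if (is.null(n_samples)) {
    with_cov <- which(track$n_covered > 0)
    if (length(with_cov) == 0) return(empty_islands())
    n_samples <- round(track$n_covered[with_cov[1]] /
                         track$incidence[with_cov[1]])
  }
  min_count <- ceiling(threshold * n_samples - 1e-9)
  out <- list()
  for (cc in unique(track$chrom)) {
    t_c <- track[track$chrom == cc, , drop = FALSE]
    ok <- t_c$n_covered >= min_count
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      i <- starts[ri]:ends[ri]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = cc,
        start = t_c$pos[i[1]],
        end = t_c$pos[i[length(i)]],
        n_snvs = length(i),
        min_incidence = min(t_c$incidence[i]),
        max_gap_bp = if (length(i) > 1) max(diff(t_c$pos[i])) else 0
      )
    }
  }
  if (length(out) == 0) return(empty_islands())
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

empty_islands <- function() {
  tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                 n_snvs = integer(), min_incidence = numeric(),
                 max_gap_bp = numeric())
}

#' Annotate islands with overlapping genes
#'
#' A gene is listed for an island iff its interval overlaps the island by at
#' least 1 bp. Annotation may be a GFF3 or BED file path (read with
#' `rtracklayer`) or a `GRanges` object; gene identifiers are taken from the
#' `Name`, `gene`, `ID` or BED `name` attribute, in that order of preference.
#'
#' @param regions Island tibble from [call_islands()].
#' @param annotation File path or `GRanges` of gene intervals (1-based for
#'   GFF3; BED is converted by the reader).
#' @param feature_type For GFF3 input, restrict to this `type` (default
#'   `"gene"`; `NULL` keeps all features).
#' @return `regions` with list-column `genes` and integer `n_genes` added.
#' @export
annotate_islands <- function(regions, annotation, feature_type = "gene") {
  regions <- tibble::as_tibble(regions)
  gr <- load_annotation(annotation, feature_type)
  labels <- annotation_labels(gr)
  genes <- vector("list", nrow(regions))
  ann_chroms <- as.character(GenomicRanges::seqnames(gr))
  for (i in seq_len(nrow(regions))) {
    if (!(regions$chrom[i] %in% ann_chroms)) {
      if (nrow(regions) > 0) {
        rlang::warn(paste0("chromosome ", regions$chrom[i],
                           " absent from annotation; empty gene list"))
      }
      genes[[i]] <- character(0)
      next
    }
    q <- GenomicRanges::GRanges(regions$chrom[i],
                                IRanges::IRanges(regions$start[i],
                                                 regions$end[i]))
    hits <- GenomicRanges::findOverlaps(q, gr)
    genes[[i]] <- unique(labels[S4Vectors::subjectHits(hits)])
  }
  regions$genes <- genes
  regions$n_genes <- lengths(genes)
  regions
}

load_annotation <- function(annotation, feature_type = "gene") {
  if (inherits(annotation, "GRanges")) return(annotation)
  gr <- rtracklayer::import(annotation)
  if (!is.null(feature_type) && "type" %in%
      names(S4Vectors::mcols(gr))) {
    sel <- as.character(gr$type) == feature_type
    if (any(sel)) gr <- gr[sel]
  }
  gr
}

annotation_labels <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("Name", "gene", "ID", "name")) {
    if (col %in% names(mc)) {
      lab <- as.character(mc[[col]])
      if (!all(is.na(lab))) return(lab)
    }
  }
  paste0("feature_", seq_along(gr))
}

#' Audit the shared haplotype inside an island
#'
#' Checks whether all samples carry the same homozygous genotype at every
#' member SNV (verdict `"identical"`; missing calls are ignored), and locates
#' heterozygous breaks: maximal sub-intervals of the island where one or more
#' samples show at least `min_run` consecutive heterozygous calls. Breaks
#' from different samples that overlap are merged and reported once with the
#' affected-sample count.
#'
#' @param region One island (a 1-row tibble or list with `chrom`, `start`,
#'   `end`).
#' @param m The [geno_matrix()] the island was called from.
#' @param min_run Minimum consecutive heterozygous calls to count as a break.
#' @return List with elements `verdict` (`"identical"` or `"not_identical"`)
#'   and `het_breaks` (tibble `chrom`, `start`, `end`, `n_samples`).
#' @export
haplotype_audit <- function(region, m, min_run = 2) {
  stopifnot(inherits(m, "geno_matrix"))
  idx <- which(m$sites$chrom == region$chrom &
                 m$sites$pos >= region$start & m$sites$pos <= region$end)
  empty_breaks <- tibble::tibble(chrom = character(), start = numeric(),
                                 end = numeric(), n_samples = integer())
  if (length(idx) == 0) {
    return(list(verdict = "identical", het_breaks = empty_breaks))
  }
  calls <- m$calls[, idx, drop = FALSE]
  pos <- m$sites$pos[idx]
  # identical shared haplotype: at every SNV all non-missing calls agree and
  # are homozygous
  identical_site <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) == 0 || (all(g %in% c(0L, 2L)) && length(unique(g)) == 1L)
  })
  verdict <- if (all(identical_site)) "identical" else "not_identical"
  # per-sample runs of >= min_run consecutive het calls
  runs <- list()
  for (i in seq_len(nrow(calls))) {
    het <- !is.na(calls[i, ]) & calls[i, ] == 1L
    if (!any(het)) next
    r <- rle(het)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= min_run)) {
      runs[[length(runs) + 1L]] <- c(sample = i, start = pos[starts[ri]],
                                     end = pos[ends[ri]])
    }
  }
  if (length(runs) == 0) {
    return(list(verdict = verdict, het_breaks = empty_breaks))
  }
  rdf <- do.call(rbind, runs)
  ir <- IRanges::IRanges(rdf[, "start"], rdf[, "end"])
  merged <- IRanges::reduce(ir)
  ovl <- IRanges::findOverlaps(merged, ir)
  n_samp <- tapply(rdf[S4Vectors::subjectHits(ovl), "sample"],
                   S4Vectors::queryHits(ovl),
                   function(s) length(unique(s)))
  breaks <- tibble::tibble(
    chrom = region$chrom,
    start = IRanges::start(merged),
    end = IRanges::end(merged),
    n_samples = as.integer(n_samp)
  )
  list(verdict = verdict, het_breaks = breaks)
}

#' Genome-wide incidence plot with island cutoff
#'
#' @param track Incidence track from [snv_incidence()].
#' @param threshold Island cutoff drawn as a dashed line.
#' @return A ggplot object, faceted by chromosome.
#' @export
plot_incidence <- function(track, threshold = 0.90) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos / 1e6,
                                      y = .data$incidence)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "darkred") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "Fraction of samples in ROH") +
    ggplot2::theme_minimal()
}
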