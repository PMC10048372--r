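#' Sliding-window LD pruning of a genotype matrix
#'
#' Within each window of `window_size` markers (advanced by `step` markers,
#' per chromosome, with a truncated final window), markers are visited in
#' position order and a marker is removed when its squared Pearson
#' correlation of dosages (over pairwise-complete samples) with any earlier
#' still-retained marker in the window exceeds `r2_max`. The later marker of
#' an offending pair is always the one removed, which makes the retained set
#' deterministic. Monomorphic markers have undefined correlation, treated as
#' r-squared 0.
#'
#' @param m A filtered [geno_matrix()].
#' @param window_size Markers per window (study: 1000).
#' @param step Window step in markers (study: 100).
#' @param r2_max Squared-correlation threshold (study: 0.8).
#' @return Integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(m, window_size = 1000, step = 100, r2_max = 0.8) {
  stopifnot(inherits(m, "geno_matrix"), step <= window_size,
            r2_max > 0, r2_max <= 1)
  keep <- rep(TRUE, nrow(m$sites))
  for (cc in unique(m$sites$chrom)) {
    idx <- which(m$sites$chrom == cc)
    nc <- length(idx)
    starts <- seq(1L, max(1L, nc), by = step)
    starts <- starts[starts <= nc]
    for (s in starts) {
      w_idx <- idx[s:min(s + window_size - 1L, nc)]
      w_idx <- w_idx[keep[w_idx]]
      if (length(w_idx) < 2) next
      g <- m$calls[, w_idx, drop = FALSE]
      r2 <- r2_pairwise(g)
      active <- rep(TRUE, length(w_idx))
      for (j in 2:length(w_idx)) {
        if (any(r2[j, seq_len(j - 1)][active[seq_len(j - 1)]] > r2_max)) {
          active[j] <- FALSE
          keep[w_idx[j]] <- FALSE
        }
      }
    }
  }
  which(keep)
}

#' Pairwise-complete squared Pearson correlation between dosage columns
#'
#' Exact pairwise-complete-observation r-squared for every column pair,
#' computed from cross-products of the zero-filled dosage matrix and its
#' missingness indicator, which is orders of magnitude faster than looping
#' `stats::cor(use = "pairwise.complete.obs")` over sliding windows and
#' agrees with it to numerical precision. Pairs where either column is
#' constant over the complete observations get r-squared 0.
#'
#' @param g Numeric matrix (samples x markers) with `NA` for missing.
#' @return Symmetric matrix of squared correlations.
#' @export
r2_pairwise <- function(g) {
  obs <- !is.na(g)
  x <- g
  x[!obs] <- 0
  mode(obs) <- "numeric"
  n <- crossprod(obs)
  sx <- crossprod(x, obs)     # sx[i, j]: sum of marker i over pairs with j
  sxy <- crossprod(x)
  sxx <- crossprod(x^2, obs)
  vx <- n * sxx - sx^2
  num <- (n * sxy - sx * t(sx))^2
  den <- vx * t(vx)
  r2 <- ifelse(den > 0, num / den, 0)
  r2[n == 0] <- 0
  r2
}

#' Raw Hamming (allele-mismatch) distance matrix
#'
#' For samples i and j, the distance is the number of mismatching alleles
#' summed over sites called in both: opposite homozygotes differ by 2,
#' heterozygote vs either homozygote by 1. No normalisation is applied
#' ("raw"); the pairwise complete-site count is reported alongside, and a
#' per-site-normalised variant is available via `normalize = TRUE` for
#' missing-data robustness.
#'
#' @param m A [geno_matrix()] with at least 2 samples.
#' @param sites Optional integer site indices (e.g. from [ld_prune()]).
#' @param normalize Divide each pairwise distance by its complete-site count.
#' @return A `hamming_dist` object: list with `labels`, `d` (symmetric
#'   matrix), `n_complete` (pairwise complete-site counts).
#' @export
hamming_distance <- function(m, sites = NULL, normalize = FALSE) {
  stopifnot(inherits(m, "geno_matrix"), length(m$samples) >= 2)
  g <- if (is.null(sites)) m$calls else m$calls[, sites, drop = FALSE]
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(m$samples, m$samples))
  ncomp <- matrix(0L, n, n, dimnames = list(m$samples, m$samples))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      both <- !is.na(gi) & !is.na(gj)
      nb <- sum(both)
      if (nb == 0L) {
        rlang::abort(paste0("samples ", m$samples[i], " and ", m$samples[j],
                            " share no called sites"))
      }
      dij <- sum(abs(gi[both] - gj[both]))
      if (normalize) dij <- dij / nb
      d[i, j] <- d[j, i] <- dij
      ncomp[i, j] <- ncomp[j, i] <- nb
    }
  }
  structure(list(labels = m$samples, d = d, n_complete = ncomp),
            class = "hamming_dist")
}

#' @export
print.hamming_dist <- function(x, ...) {
  cat("<hamming_dist> ", length(x$labels), " samples; mean distance ",
      signif(mean(x$d[upper.tri(x$d)]), 4), "\n", sep = "")
  invisible(x)
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson scaling: the squared-distance matrix is double-centred,
#' eigendecomposed, and coordinates are eigenvectors scaled by the square
#' root of their (non-negative) eigenvalues. The sign of each component is
#' fixed so that its first nonzero loading is positive, making results
#' reproducible across platforms. With all-zero distances all coordinates
#' are zero.
#'
#' @param d A `hamming_dist`, `dist`, or symmetric matrix.
#' @param k Number of components to extract (default 3).
#' @return An `mds_result`: list with `coordinates` (tibble `sample`,
#'   `C1`...`Ck`) and `eigenvalues` (descending, length k).
#' @export
classical_mds <- function(d, k = 3) {
  stopifnot(k >= 1)
  if (inherits(d, "hamming_dist")) {
    labels <- d$labels
    dm <- d$d
  } else {
    dm <- as.matrix(d)
    labels <- rownames(dm)
    if (is.null(labels)) labels <- paste0("S", seq_len(nrow(dm)))
  }
  n <- nrow(dm)
  k <- min(k, n - 1)
  if (all(dm == 0)) {
    coords <- matrix(0, n, k)
    eig <- rep(0, k)
  } else {
    fit <- stats::cmdscale(stats::as.dist(dm), k = k, eig = TRUE)
    pts <- fit$points
    if (ncol(pts) < k) {  # rank-deficient configuration: pad with zeros
      pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
    }
    coords <- pts
    eig <- fit$eig[seq_len(k)]
  }
  # deterministic sign convention
  for (col in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, col]) > 1e-9)
    if (length(nz) > 0 && coords[nz[1], col] < 0) {
      coords[, col] <- -coords[, col]
    }
  }
  coord_tbl <- tibble::as_tibble(coords, .name_repair = ~paste0("C", seq_len(k)))
  coord_tbl <- dplyr::bind_cols(tibble::tibble(sample = labels), coord_tbl)
  structure(list(coordinates = coord_tbl, eigenvalues = eig, k = k),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("<mds_result> ", nrow(x$coordinates), " samples, ", x$k,
      " components; eigenvalues ",
      paste(signif(x$eigenvalues, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mds_result <- function(x, ...) x$coordinates

#' @export
glance.mds_result <- function(x, ...) {
  tibble::tibble(k = x$k,
                 eig1 = x$eigenvalues[1],
                 total_positive_eig = sum(x$eigenvalues[x$eigenvalues > 0]))
}

#' Scatter plot of the first two MDS components
#'
#' @param object An `mds_result`.
#' @param groups Optional tibble (`sample`, `group`) to colour points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mds_result <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, tibble::as_tibble(groups), by = "sample")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$C1, y = .data$C2,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$C1, y = .data$C2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Component 1", y = "Component 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
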