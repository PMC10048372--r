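#' Per-sample observed heterozygosity
#'
#' Fraction of called (non-missing) genotypes that are heterozygous, per
#' sample. The cohort mean (unweighted mean over samples) is attached as the
#' `cohort_mean` attribute. A sample with zero called genotypes gets `NA`.
#'
#' @param m A [geno_matrix()].
#' @return Tibble with columns `sample`, `n_called`, `n_het`, `obs_het`.
#' @export
observed_heterozygosity <- function(m) {
  stopifnot(inherits(m, "geno_matrix"))
  n_called <- rowSums(!is.na(m$calls))
  n_het <- rowSums(m$calls == 1L, na.rm = TRUE)
  out <- tibble::tibble(
    sample = m$samples,
    n_called = as.integer(n_called),
    n_het = as.integer(n_het),
    obs_het = ifelse(n_called > 0, n_het / n_called, NA_real_)
  )
  attr(out, "cohort_mean") <- mean(out$obs_het, na.rm = TRUE)
  out
}

#' Autosomal genome denominator for F_ROH
#'
#' By default the denominator is the genome span covered by SNV positions:
#' the per-chromosome span (max position - min position + 1) summed over
#' chromosomes. A fixed constant (such as a published assembly-derived value)
#' may be supplied instead via `override`.
#'
#' @param m A filtered [geno_matrix()].
#' @param override Optional fixed denominator in bp, returned verbatim.
#' @return Denominator in bp (a single number).
#' @export
compute_denominator <- function(m, override = NULL) {
  if (!is.null(override)) {
    stopifnot(override > 0)
    return(as.numeric(override))
  }
  stopifnot(inherits(m, "geno_matrix"))
  spans <- tapply(m$sites$pos, m$sites$chrom,
                  function(p) if (length(p) == 0) 0 else max(p) - min(p) + 1)
  sum(as.numeric(spans))
}

#' Genomic inbreeding coefficient F_ROH
#'
#' F_ROH for a sample is the total length of its ROH divided by the autosomal
#' genome denominator. Accepts segments for one or many samples and returns a
#' per-sample summary. Overlapping segments within a sample are a caller bug
#' and raise an error.
#'
#' @param segments Tibble of ROH segments (`sample`, `chrom`, `start`, `end`,
#'   `length_bp`).
#' @param denominator Denominator in bp, e.g. from [compute_denominator()].
#' @param all_samples Optional character vector of sample names that should
#'   appear in the output even with zero segments (F_ROH = 0).
#' @return Tibble with `sample`, `n_roh`, `total_roh_bp`, `mean_roh_bp`,
#'   `froh`.
#' @export
froh <- function(segments, denominator, all_samples = NULL) {
  stopifnot(denominator > 0)
  segments <- tibble::as_tibble(segments)
  if (!"length_bp" %in% names(segments)) {
    segments$length_bp <- segments$end - segments$start + 1
  }
  assert_non_overlapping(segments)
  out <- segments |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(n_roh = dplyr::n(),
                     total_roh_bp = sum(.data$length_bp),
                     mean_roh_bp = mean(.data$length_bp),
                     .groups = "drop") |>
    dplyr::mutate(froh = .data$total_roh_bp / denominator)
  if (!is.null(all_samples)) {
    out <- tibble::tibble(sample = all_samples) |>
      dplyr::left_join(out, by = "sample") |>
      tidyr::replace_na(list(n_roh = 0L, total_roh_bp = 0, froh = 0))
  }
  out
}

assert_non_overlapping <- function(segments) {
  if (nrow(segments) < 2) return(invisible(TRUE))
  bad <- segments |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(ovl = any(.data$start[-1] <= .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(bad$ovl)) {
    rlang::abort("overlapping ROH segments within a sample: caller bug")
  }
  invisible(TRUE)
}

#' ROH length-class scheme
#'
#' Ascending bp cut points partitioning segments into length classes; the
#' default `1, 2, 4, 8, 10` Mb boundaries give the six classes <1, 1-2, 2-4,
#' 4-8, 8-10 and >10 Mb. Binning is lower-bound inclusive, upper exclusive.
#'
#' @param boundaries Strictly ascending cut points in bp.
#' @return A `length_class_scheme` object with labels.
#' @export
length_class_scheme <- function(boundaries = c(1, 2, 4, 8, 10) * 1e6) {
  stopifnot(length(boundaries) >= 1, all(diff(boundaries) > 0))
  mb <- function(x) {
    ifelse(x %% 1e6 == 0, sprintf("%g", x / 1e6), sprintf("%.2g", x / 1e6))
  }
  labels <- c(paste0("<", mb(boundaries[1]), " Mb"))
  if (length(boundaries) > 1) {
    labels <- c(labels, paste0(mb(boundaries[-length(boundaries)]), "-",
                               mb(boundaries[-1]), " Mb"))
  }
  labels <- c(labels, paste0(">", mb(boundaries[length(boundaries)]), " Mb"))
  structure(list(boundaries = boundaries, labels = labels),
            class = "length_class_scheme")
}

#' Assign ROH segments to length classes
#'
#' @param lengths_bp Numeric segment lengths.
#' @param scheme A [length_class_scheme()].
#' @return Factor of class labels (every segment in exactly one class).
#' @export
length_class <- function(lengths_bp, scheme = length_class_scheme()) {
  idx <- findInterval(lengths_bp, scheme$boundaries) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' F_ROH decomposed by ROH length class
#'
#' Each segment contributes its full length to exactly one class, so the
#' per-class values sum exactly to F_ROH.
#'
#' @inheritParams froh
#' @param scheme A [length_class_scheme()].
#' @return Tibble with `sample`, `class`, `froh_class` (all classes present
#'   for every sample, zero-filled).
#' @export
froh_by_class <- function(segments, scheme = length_class_scheme(),
                          denominator, all_samples = NULL) {
  stopifnot(denominator > 0)
  segments <- tibble::as_tibble(segments)
  if (!"length_bp" %in% names(segments)) {
    segments$length_bp <- segments$end - segments$start + 1
  }
  assert_non_overlapping(segments)
  samples <- if (is.null(all_samples)) unique(segments$sample) else all_samples
  segments$class <- length_class(segments$length_bp, scheme)
  segments |>
    dplyr::group_by(.data$sample, .data$class) |>
    dplyr::summarise(froh_class = sum(.data$length_bp) / denominator,
                     .groups = "drop") |>
    tidyr::complete(sample = samples,
                    class = factor(scheme$labels, levels = scheme$labels),
                    fill = list(froh_class = 0))
}

#' Per-sample diversity summary
#'
#' Combines ROH counts, F_ROH, the length-class decomposition (as wide
#' columns) and observed heterozygosity into one table, optionally joined to
#' group labels (e.g. country of origin).
#'
#' @param m A filtered [geno_matrix()].
#' @param segments ROH segments from [detect_roh()].
#' @param denominator Denominator bp; default computed from `m`.
#' @param scheme A [length_class_scheme()].
#' @param groups Optional tibble with columns `sample`, `group`.
#' @return Tibble, one row per sample.
#' @export
sample_diversity <- function(m, segments, denominator = NULL,
                             scheme = length_class_scheme(), groups = NULL) {
  if (is.null(denominator)) denominator <- compute_denominator(m)
  base <- froh(segments, denominator, all_samples = m$samples)
  byc <- froh_by_class(segments, scheme, denominator, all_samples = m$samples) |>
    dplyr::mutate(class = paste0("froh_", gsub("[ ]", "", .data$class))) |>
    tidyr::pivot_wider(names_from = "class", values_from = "froh_class")
  het <- observed_heterozygosity(m)[, c("sample", "obs_het")]
  out <- base |>
    dplyr::left_join(byc, by = "sample") |>
    dplyr::left_join(het, by = "sample")
  if (!is.null(groups)) {
    out <- dplyr::left_join(out, tibble::as_tibble(groups), by = "sample") |>
      dplyr::relocate("group", .after = "sample")
  }
  out
}

#' One-way ANOVA of a per-sample statistic across groups
#'
#' Classical fixed-effects one-way analysis of variance (via [stats::aov()])
#' of, e.g., F_ROH across countries of origin. Requires at least two groups
#' with at least two samples each.
#'
#' @param values Numeric per-sample values.
#' @param groups Group labels, same length.
#' @return An object of class `roh_anova`; see [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
group_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) rlang::abort("need at least two groups")
  if (any(sizes < 2)) {
    rlang::abort(paste0("every group needs >= 2 samples; too small: ",
                        paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  df1 <- tab[["Df"]][1]
  df2 <- tab[["Df"]][2]
  if (is.na(f)) f <- 0  # zero between- and within-group variance
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(
    list(statistic = f, p_value = p, df_between = df1, df_within = df2,
         group_means = tapply(values, groups, mean), fit = fit),
    class = "roh_anova"
  )
}

#' @export
print.roh_anova <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_between, ", ", x$df_within, ") = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.roh_anova <- function(x, ...) {
  tibble::tibble(group = names(x$group_means),
                 mean = as.numeric(x$group_means))
}

#' @export
glance.roh_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 df_between = x$df_between, df_within = x$df_within)
}

#' Stacked-bar plot of F_ROH by length class
#'
#' @param by_class Output of [froh_by_class()].
#' @return A ggplot object.
#' @export
plot_froh_classes <- function(by_class) {
  ggplot2::ggplot(by_class,
                  ggplot2::aes(x = .data$sample, y = .data$froh_class,
                               fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(F[ROH]), fill = "ROH length") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
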