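#' Scan configuration
#'
#' Parameters of the joint diversity-ratio / F_ST outlier scan. Both
#' statistics use the same empirical top quantile (5% by default); outlier
#' calling is quantile-based, so the log base of the diversity ratio cannot
#' change which windows are selected.
#'
#' @param window_size,step Sliding-window geometry in bp.
#' @param top_quantile Upper tail fraction defining outliers per statistic.
#' @param log_base Base of the diversity log-ratio (display only).
#' @param min_snps Minimum informative SNPs per usable window.
#' @param exclude Optional tibble (`chrom`, `start`, `end`, 0-based
#'   half-open) of intervals removed from the scan, e.g. a region of known
#'   extreme linkage such as the X-linked wing-morph locus.
#' @param per_chromosome_quantiles Compute outlier thresholds per
#'   chromosome instead of genome-wide.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window_size = 10000, step = 2500, top_quantile = 0.05,
                        log_base = 2, min_snps = 3, exclude = NULL,
                        per_chromosome_quantiles = FALSE) {
  stopifnot(top_quantile > 0, top_quantile < 0.5)
  structure(list(window_size = window_size, step = step,
                 top_quantile = top_quantile, log_base = log_base,
                 min_snps = min_snps, exclude = exclude,
                 per_chromosome_quantiles = per_chromosome_quantiles),
            class = "scan_config")
}

#' Diversity log-ratio
#'
#' log of pi_control / pi_focal. A window whose focal diversity is exactly
#' zero while control diversity is positive is the strongest possible sweep
#' signal and is assigned `Inf`, ranking above every finite value; windows
#' with both diversities zero are undefined (`NA`).
#'
#' @param pi_numerator Control-group diversity (numerator).
#' @param pi_denominator Focal-group diversity (denominator).
#' @param log_base Logarithm base.
#' @return Numeric vector of log ratios.
#' @export
pi_log_ratio <- function(pi_numerator, pi_denominator, log_base = 2) {
  out <- log(pi_numerator / pi_denominator, base = log_base)
  out[pi_numerator == 0 & pi_denominator == 0] <- NA_real_
  out
}

#' Call joint outlier windows
#'
#' Returns the usable windows lying in the top `top_quantile` of F_ST and
#' simultaneously in the top `top_quantile` of the diversity log-ratio.
#' Thresholds are empirical quantiles over usable windows (genome-wide by
#' default) and are inclusive, so ties at the threshold are selected; in
#' the degenerate all-equal case every window equals its own quantile and
#' all are selected.
#'
#' @param stats A window-statistics tibble from [window_stats()].
#' @param config A [scan_config()].
#' @return The outlier subset of `stats`.
#' @export
call_outlier_windows <- function(stats, config = scan_config()) {
  q <- config$top_quantile
  usable <- stats[stats$usable, , drop = FALSE]
  if (nrow(usable) < 20 / q)
    stop("too few usable windows (", nrow(usable), ") to estimate the ",
         q, " quantile; enlarge the dataset or the quantile")
  pick <- function(df) {
    # order-statistic (type 1) quantiles: deterministic, tie-safe, and
    # well-defined when the ratio column contains +Inf
    thr_fst <- quantile(df$fst, 1 - q, names = FALSE, type = 1)
    thr_ratio <- quantile(df$pi_log_ratio, 1 - q, names = FALSE, type = 1)
    df[df$fst >= thr_fst & df$pi_log_ratio >= thr_ratio, , drop = FALSE]
  }
  if (config$per_chromosome_quantiles) {
    usable %>% dplyr::group_by(.data$chrom) %>% dplyr::group_modify(~ pick(.x)) %>%
      dplyr::ungroup()
  } else {
    pick(usable)
  }
}

#' Merge outlier windows into candidate regions
#'
#' Overlapping or book-ended (end == start) outlier windows on the same
#' chromosome merge into a single region. Idempotent and order-invariant.
#'
#' @param outliers Tibble of windows (`chrom`, `start`, `end`, optionally
#'   `fst` and `pi_log_ratio`).
#' @return Tibble of disjoint regions with member window counts and the
#'   maxima of each statistic.
#' @export
merge_regions <- function(outliers) {
  if (nrow(outliers) == 0L)
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_windows = integer(), max_fst = numeric(),
                  max_pi_log_ratio = numeric()))
  o <- outliers[order(outliers$chrom, outliers$start, outliers$end), , drop = FALSE]
  has_stats <- all(c("fst", "pi_log_ratio") %in% names(o))
  new_run <- if (nrow(o) == 1L) TRUE else
    c(TRUE, o$chrom[-1] != o$chrom[-nrow(o)] |
        o$start[-1] > cummax_by_run(o))
  grp <- cumsum(new_run)
  o$grp <- grp
  o %>%
    dplyr::group_by(.data$grp) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_windows = dplyr::n(),
      max_fst = if (has_stats) max(.data$fst) else NA_real_,
      max_pi_log_ratio = if (has_stats) max(.data$pi_log_ratio) else NA_real_,
      .groups = "drop"
    ) %>%
    dplyr::select(-"grp")
}

# running maximum of end within chromosome runs, lagged by one, used to
# decide whether window i starts beyond everything seen so far
cummax_by_run <- function(o) {
  n <- nrow(o)
  res <- numeric(n - 1)
  cur_chrom <- o$chrom[1]
  cur_max <- o$end[1]
  for (i in 2:n) {
    if (o$chrom[i] != cur_chrom) {
      cur_chrom <- o$chrom[i]
      cur_max <- o$end[i]
      res[i - 1] <- -Inf
    } else {
      res[i - 1] <- cur_max
      cur_max <- max(cur_max, o$end[i])
    }
  }
  res
}

#' Genes overlapping candidate regions
#'
#' A gene is a candidate if it shares at least one bp with at least one
#' region (half-open intersection; a mere touch is not an overlap). Every
#' overlapping region is recorded as provenance.
#'
#' @param regions Region tibble (`chrom`, `start`, `end`).
#' @param genes Gene-model tibble from [read_gff_genes()].
#' @param label Optional comparison label attached to the result.
#' @return Tibble with one row per gene-region overlap (`gene_id`, gene and
#'   region coordinates); unique gene ids are `unique(result$gene_id)`.
#' @export
genes_in_regions <- function(regions, genes, label = NULL) {
  if (nrow(regions) > 0 && nrow(genes) > 0 &&
      !any(regions$chrom %in% genes$chrom)) {
    stop("chromosome names in regions not found in gene annotation: ",
         paste(unique(regions$chrom), collapse = ", "))
  }
  out <- dplyr::inner_join(
    genes, regions,
    by = "chrom", suffix = c("", "_region"), relationship = "many-to-many"
  ) %>%
    dplyr::filter(.data$start < .data$end_region,
                  .data$end > .data$start_region) %>%
    dplyr::select("gene_id", "chrom", "start", "end",
                  region_start = "start_region", region_end = "end_region")
  attr(out, "label") <- label
  out
}

#' Run one full differentiation comparison
#'
#' End-to-end composition of the scan: windowed statistics for the two
#' groups, joint top-quantile outlier calling, region merging and gene
#' overlap. For temporal comparisons pass the earlier time point as the
#' control group so ongoing diversity loss raises the ratio.
#'
#' @param vt A `variant_table`.
#' @param genes Gene-model tibble.
#' @param focal_samples,control_samples Disjoint sample id vectors
#'   (each of size >= 2).
#' @param chrom_lengths Named chromosome lengths; inferred from the site
#'   table when missing.
#' @param config A [scan_config()].
#' @param label Comparison label carried into the outputs.
#' @return List with `stats` (window tibble), `outliers`, `regions`,
#'   `gene_hits` (provenance tibble) and `gene_ids`.
#' @export
run_comparison <- function(vt, genes, focal_samples, control_samples,
                           chrom_lengths = NULL, config = scan_config(),
                           label = "comparison") {
  if (any(focal_samples %in% control_samples))
    stop("groups must be disjoint")
  if (length(focal_samples) < 2 || length(control_samples) < 2)
    stop("each group needs at least 2 samples")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(vt$sites$pos, vt$sites$chrom, max)
  windows <- make_windows(chrom_lengths, config$window_size, config$step)
  windows <- drop_excluded_windows(windows, config$exclude)
  stats <- window_stats(vt, focal_samples, control_samples, windows,
                        min_snps = config$min_snps)
  outliers <- call_outlier_windows(stats, config)
  regions <- merge_regions(outliers)
  gene_hits <- genes_in_regions(regions, genes, label = label)
  list(label = label, stats = stats, outliers = outliers, regions = regions,
       gene_hits = gene_hits, gene_ids = unique(gene_hits$gene_id))
}

drop_excluded_windows <- function(windows, exclude) {
  if (is.null(exclude) || nrow(exclude) == 0L) return(windows)
  drop <- rep(FALSE, nrow(windows))
  for (i in seq_len(nrow(exclude))) {
    drop <- drop | (windows$chrom == exclude$chrom[i] &
                      windows$start < exclude$end[i] &
                      windows$end > exclude$start[i])
  }
  windows[!drop, , drop = FALSE]
}
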