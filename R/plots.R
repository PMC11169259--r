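#' Plot a windowed scan: F_ST and diversity log-ratio along the genome
#'
#' @param stats A window-statistics tibble from [window_stats()].
#' @param regions Optional candidate-region tibble to shade.
#' @return A ggplot object.
#' @export
plot_window_scan <- function(stats, regions = NULL) {
  long <- stats %>%
    dplyr::filter(.data$usable) %>%
    dplyr::mutate(mid = (.data$start + .data$end) / 2) %>%
    tidyr::pivot_longer(c("fst", "pi_log_ratio"),
                        names_to = "statistic", values_to = "value") %>%
    dplyr::filter(is.finite(.data$value))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "firebrick", alpha = 0.2)
  }
  p
}

#' Manhattan-style association plot
#'
#' @param assoc Tibble from [fisher_assoc_scan()].
#' @param alpha Significance level for the Bonferroni guide line.
#' @return A ggplot object.
#' @export
plot_association <- function(assoc, alpha = 0.05) {
  thr <- alpha / nrow(assoc)
  ggplot2::ggplot(assoc, ggplot2::aes(x = .data$pos, y = -log10(.data$p))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Plot LD decay curves
#'
#' @param ... Named decay tibbles from [ld_decay()], one curve each.
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(...) {
  curves <- list(...)
  if (is.null(names(curves)) || any(names(curves) == ""))
    names(curves) <- paste0("curve", seq_along(curves))
  df <- dplyr::bind_rows(curves, .id = "region")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$mean_r2,
                                   colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (bp)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}

#' Plot a normalised haplotype score track
#'
#' @param object A score-track tibble from [ihs_scan()] or [xpehh_scan()].
#' @return A ggplot object.
#' @export
plot_score_track <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$norm)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = paste0("normalised ", object$stat[1])) +
    ggplot2::theme_minimal()
}

#' Plot the resampling-support distribution
#'
#' Density of the genome-wide support statistic with the retention
#' threshold and candidate supports marked.
#'
#' @param result A `resampling_result`.
#' @param threshold Optional threshold value from [threshold_support()].
#' @return A ggplot object.
#' @export
plot_resampling_support <- function(result, threshold = NULL) {
  df <- tidy(result)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$support_pct)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_point(
      data = df[df$candidate, ],
      ggplot2::aes(y = 0), colour = "firebrick", shape = 17, size = 2) +
    ggplot2::labs(x = "resampling support (%)", y = "genes") +
    ggplot2::theme_minimal()
  if (!is.null(threshold))
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  p
}
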