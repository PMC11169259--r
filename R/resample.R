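#' Enumerate leave-one-out subsamples
#'
#' All `n` subsets of size `n - 1` of a sample group, in deterministic
#' order by omitted sample id. Ten individuals per time point give the ten
#' subsampling scenarios per group used by the resampling validation.
#'
#' @param samples Character vector of sample ids (`length >= 3`).
#' @return Named list of character vectors; names are the omitted ids.
#' @export
enumerate_subsamples <- function(samples) {
  if (length(samples) < 3L) stop("need at least 3 samples to leave one out")
  omitted <- sort(samples)
  setNames(lapply(omitted, function(s) setdiff(samples, s)), omitted)
}

#' Leave-one-out resampling of a differentiation scan
#'
#' Re-runs the full joint-outlier differentiation analysis on every ordered
#' pair of leave-one-out subsamples of the two groups (n_a x n_b
#' iterations; 100 when both groups hold 10 individuals) and scores every
#' annotated gene with the percentage of iterations in which it was a
#' candidate. Genes never selected score 0. The exhaustive enumeration
#' makes the procedure fully deterministic.
#'
#' @param vt A `variant_table`.
#' @param genes Gene-model tibble (the support distribution covers every
#'   annotated gene).
#' @param focal_samples,control_samples The two groups being compared
#'   (earlier time point as control for temporal comparisons).
#' @param chrom_lengths Named chromosome lengths (inferred if `NULL`).
#' @param config A [scan_config()].
#' @param candidates Optional character vector of the full-data candidate
#'   gene ids; computed with [run_comparison()] when absent.
#' @param label Comparison label.
#' @return An object of class `resampling_result`: list with `support`
#'   (tibble `gene_id`, `support_pct`), `n_iterations`, `n_skipped`,
#'   `candidates` and `label`.
#' @export
resample_differentiation <- function(vt, genes, focal_samples, control_samples,
                                     chrom_lengths = NULL,
                                     config = scan_config(),
                                     candidates = NULL,
                                     label = "comparison") {
  if (length(focal_samples) < 3 || length(control_samples) < 3)
    stop("both groups need at least 3 samples for leave-one-out resampling")
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(vt$sites$pos, vt$sites$chrom, max)
  if (is.null(candidates)) {
    candidates <- run_comparison(vt, genes, focal_samples, control_samples,
                                 chrom_lengths, config, label)$gene_ids
  }
  windows <- drop_excluded_windows(
    make_windows(chrom_lengths, config$window_size, config$step),
    config$exclude)
  subs_f <- enumerate_subsamples(focal_samples)
  subs_c <- enumerate_subsamples(control_samples)
  hit_count <- setNames(integer(nrow(genes)), genes$gene_id)
  n_iter <- 0L
  n_skipped <- 0L
  for (sf in subs_f) {
    for (sc in subs_c) {
      n_iter <- n_iter + 1L
      ids <- tryCatch({
        stats <- window_stats(vt, sf, sc, windows, min_snps = config$min_snps)
        out <- call_outlier_windows(stats, config)
        regions <- merge_regions(out)
        unique(genes_in_regions(regions, genes)$gene_id)
      }, error = function(e) NULL)
      if (is.null(ids)) {
        n_skipped <- n_skipped + 1L
      } else if (length(ids)) {
        hit_count[ids] <- hit_count[ids] + 1L
      }
    }
  }
  if (n_skipped > 0.1 * n_iter)
    stop("more than 10% of resampling iterations failed (",
         n_skipped, "/", n_iter, ")")
  done <- n_iter - n_skipped
  structure(list(
    support = tibble(gene_id = genes$gene_id,
                     support_pct = 100 * as.numeric(hit_count) / done),
    n_iterations = done,
    n_skipped = n_skipped,
    candidates = candidates,
    label = label
  ), class = "resampling_result")
}

#' Threshold resampling support at the genome-wide top percentile
#'
#' The significance threshold is the smallest support value within the top
#' `1 - quantile` fraction of the empirical distribution over all annotated
#' genes (zeros included, so the threshold is not circular on candidates).
#' Candidates with support at or above the threshold are retained. If every
#' gene scores zero the threshold degenerates to zero and nothing is
#' excluded.
#'
#' @param result A `resampling_result`.
#' @param quantile Retention quantile (default 0.99, the top 1%).
#' @return List with `threshold`, `retained` (gene ids) and the per-gene
#'   `support` tibble augmented with a `retained` flag.
#' @export
threshold_support <- function(result, quantile = 0.99) {
  stopifnot(inherits(result, "resampling_result"))
  x <- result$support$support_pct
  n <- length(x)
  k <- ceiling(round(n * (1 - quantile), 8)) # genes in the top tail
  threshold <- sort(x, decreasing = TRUE)[k]
  if (all(x == 0)) {
    warning("all resampling supports are zero; nothing excluded")
    threshold <- 0
  }
  retained <- intersect(result$candidates,
                        result$support$gene_id[x >= threshold])
  support <- result$support %>%
    dplyr::mutate(retained = .data$gene_id %in% retained)
  list(threshold = threshold, retained = retained, support = support)
}

#' @export
print.resampling_result <- function(x, ...) {
  cat("<resampling_result>", x$label, "-", x$n_iterations, "iterations",
      paste0("(", x$n_skipped, " skipped);"),
      sum(x$support$support_pct > 0), "of", nrow(x$support),
      "genes with support > 0\n")
  invisible(x)
}
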