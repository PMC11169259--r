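#' Tidy a resampling result into a per-gene tibble
#'
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `support_pct`, `candidate`.
#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) {
  x$support %>% dplyr::mutate(candidate = .data$gene_id %in% x$candidates)
}

#' One-row summary of a resampling result
#'
#' @inheritParams tidy.resampling_result
#' @return Tibble with iteration and candidate counts.
#' @method glance resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  tibble(label = x$label, n_iterations = x$n_iterations,
         n_skipped = x$n_skipped, n_candidates = length(x$candidates),
         max_support = max(x$support$support_pct))
}

#' Tidy a variant table's site information
#'
#' @param x A `variant_table`.
#' @param ... Unused.
#' @return The site tibble with per-site call and missingness counts.
#' @method tidy variant_table
#' @export
tidy.variant_table <- function(x, ...) {
  x$sites %>%
    dplyr::mutate(n_called = rowSums(!is.na(x$gt)),
                  n_missing = rowSums(is.na(x$gt)))
}

#' One-row summary of a variant table
#'
#' @inheritParams tidy.variant_table
#' @return Tibble with site/sample/chromosome counts and missingness.
#' @method glance variant_table
#' @export
glance.variant_table <- function(x, ...) {
  tibble(n_sites = nrow(x$sites), n_samples = length(x$samples),
         n_chromosomes = length(unique(x$sites$chrom)),
         missing_rate = mean(is.na(x$gt)))
}
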