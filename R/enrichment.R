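#' Fisher exact overlap of a candidate gene set with a DEG set
#'
#' Tests whether selection-candidate genes overlap a differentially
#' expressed gene set more than expected by chance over a defined gene
#' universe: a 2x2 table (in both / candidate only / DEG only / neither)
#' with one-sided (enrichment) and two-sided Fisher exact p-values. The
#' odds ratio is the sample cross-product ratio, with a Haldane 0.5
#' correction when a cell is empty. The universe must contain every tested
#' gene; its definition (genes eligible for both the scan and the
#' expression contrast) is the analysis's most consequential choice and is
#' therefore an explicit argument.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param deg_set Character vector of DEG ids.
#' @param universe Character vector of eligible gene ids.
#' @return One-row tibble: `k` (overlap), `n_candidates`, `n_deg`,
#'   `n_universe`, `odds_ratio`, `p_greater`, `p_two_sided`.
#' @export
overlap_fisher <- function(candidates, deg_set, universe) {
  if (!length(universe)) stop("empty gene universe")
  bad <- setdiff(union(candidates, deg_set), universe)
  if (length(bad))
    stop("gene(s) outside the universe: ", paste(head(bad, 5), collapse = ", "))
  candidates <- unique(candidates)
  deg_set <- unique(deg_set)
  N <- length(unique(universe))
  k <- length(intersect(candidates, deg_set))
  n <- length(candidates)
  K <- length(deg_set)
  tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2, byrow = TRUE)
  p_greater <- fisher.test(tab, alternative = "greater")$p.value
  p_two <- fisher.test(tab)$p.value
  t2 <- tab
  if (any(t2 == 0)) t2 <- t2 + 0.5
  odds <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  tibble(k = k, n_candidates = n, n_deg = K, n_universe = N,
         odds_ratio = odds, p_greater = p_greater, p_two_sided = p_two)
}

#' Hypergeometric functional-term enrichment
#'
#' For each functional term, the upper-tail hypergeometric probability
#' P(X >= k) of drawing k term members in a candidate set of size n from a
#' universe of N genes containing K term members. Benjamini-Hochberg FDR is
#' applied across tested terms; terms annotating fewer than `min_size`
#' universe genes are skipped. The richness factor (k/n) / (K/N) is
#' reported alongside.
#'
#' @param gene_set Character vector of candidate gene ids.
#' @param term_map Tibble with columns `gene_id`, `term_id`.
#' @param universe Character vector of eligible gene ids.
#' @param min_size Minimum term size in the universe.
#' @return Tibble per term: `term_id`, `k`, `K`, `n`, `N`, `odds_ratio`,
#'   `p`, `q`, `richness_factor`.
#' @export
term_enrichment <- function(gene_set, term_map, universe, min_size = 3) {
  if (!length(universe)) stop("empty gene universe")
  bad <- setdiff(gene_set, universe)
  if (length(bad))
    stop("gene(s) in set but absent from universe: ",
         paste(head(bad, 5), collapse = ", "))
  gene_set <- unique(gene_set)
  tm <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(gene_set)
  res <- tm %>%
    dplyr::group_by(.data$term_id) %>%
    dplyr::summarise(K = dplyr::n_distinct(.data$gene_id),
                     k = dplyr::n_distinct(intersect(.data$gene_id, gene_set)),
                     .groups = "drop") %>%
    dplyr::filter(.data$K >= min_size) %>%
    dplyr::mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE),
      richness_factor = (.data$k / n) / (.data$K / N)
    )
  if (nrow(res) == 0L) return(res %>% dplyr::mutate(q = numeric(0), odds_ratio = numeric(0)))
  res$q <- bh_fdr(res$p)
  res$odds_ratio <- purrr::map2_dbl(res$k, res$K, function(k, K) {
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2, byrow = TRUE)
    if (any(tab == 0)) tab <- tab + 0.5
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  })
  res[, c("term_id", "k", "K", "n", "N", "odds_ratio", "p", "q",
          "richness_factor")]
}

#' Enrichment robustness under resampling-support filtering
#'
#' Re-runs the term enrichment after restricting the gene set to members
#' whose resampling support reaches progressively stricter genome-wide
#' percentile cutoffs (top 1%, 0.5%, 0.3% by default), reporting which
#' terms stay significant at each level.
#'
#' @param gene_set Character vector of candidate gene ids.
#' @param support Tibble `gene_id`, `support_pct` covering all annotated
#'   genes (from [resample_differentiation()]).
#' @param term_map,universe,min_size As in [term_enrichment()].
#' @param cutoffs Numeric tail fractions (defaults `c(0.01, 0.005, 0.003)`).
#' @param alpha Significance level on FDR q-values.
#' @return Tibble per cutoff: `cutoff`, `threshold`, `n_genes`, `testable`,
#'   and a list-column `enrichment` of per-term results.
#' @export
robustness_filtered_enrichment <- function(gene_set, support, term_map,
                                           universe,
                                           cutoffs = c(0.01, 0.005, 0.003),
                                           min_size = 3, alpha = 0.05) {
  x <- support$support_pct
  purrr::map_dfr(cutoffs, function(cf) {
    kk <- ceiling(round(length(x) * cf, 8))
    thr <- sort(x, decreasing = TRUE)[kk]
    keep <- support$gene_id[x >= thr]
    gs <- intersect(gene_set, keep)
    if (!length(gs)) {
      return(tibble(cutoff = cf, threshold = thr, n_genes = 0L,
                    testable = FALSE, enrichment = list(NULL),
                    n_significant = NA_integer_))
    }
    enr <- term_enrichment(gs, term_map, universe, min_size = min_size)
    tibble(cutoff = cf, threshold = thr, n_genes = length(gs),
           testable = TRUE, enrichment = list(enr),
           n_significant = sum(enr$q < alpha))
  })
}
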