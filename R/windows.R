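#' Build sliding genomic windows
#'
#' Windows start at 0 and advance by `step`; the scan grid uses 10 kb
#' windows with a 2.5 kb step, and `step = size` gives the non-overlapping
#' validation grid. Trailing windows truncated by the chromosome end are
#' emitted but flagged, and are excluded from outlier-quantile computation
#' by default because their shorter span biases per-bp diversity.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param size Window size in bp.
#' @param step Step size in bp (`step <= size`).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open) and
#'   `truncated`.
#' @export
#' @examples
#' make_windows(c(chr1 = 25000), size = 10000, step = 2500)
make_windows <- function(chrom_lengths, size = 10000, step = 2500) {
  stopifnot(size >= step, step >= 1)
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  purrr::map_dfr(names(chrom_lengths), function(cn) {
    L <- chrom_lengths[[cn]]
    if (L <= 0) return(tibble(chrom = character(), start = numeric(),
                              end = numeric(), truncated = logical()))
    starts <- seq(0, max(0, L - 1), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + size, L)
    tibble(chrom = cn, start = starts, end = ends,
           truncated = (starts + size) > L)
  })
}

# per-site allele summaries for a sample subset of a dosage matrix:
# allele-copy counts, alt counts, heterozygote and diploid counts
site_counts <- function(gt) {
  nd <- rowSums(!is.na(gt))
  alt <- rowSums(gt, na.rm = TRUE)
  het <- rowSums(gt == 1L, na.rm = TRUE)
  list(nd = nd, n = 2 * nd, alt = alt, het = het)
}

# per-site pi terms: c_ref*c_alt / choose(n,2); 0 where n < 2
site_pi_terms <- function(sc) {
  n <- sc$n
  term <- ifelse(n >= 2, (n - sc$alt) * sc$alt / (n * (n - 1) / 2), 0)
  term
}

# Weir & Cockerham (1984) per-site variance components for two groups
wc84_components <- function(sc1, sc2) {
  n1 <- sc1$nd; n2 <- sc2$nd
  ok <- n1 >= 1 & n2 >= 1
  p1 <- ifelse(n1 > 0, sc1$alt / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, sc2$alt / (2 * n2), 0)
  h1 <- ifelse(n1 > 0, sc1$het / n1, 0)
  h2 <- ifelse(n2 > 0, sc2$het / n2, 0)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 4
  bad <- !ok | nbar <= 1 | !is.finite(a) | !is.finite(b) | !is.finite(c)
  a[bad] <- 0; b[bad] <- 0; c[bad] <- 0
  # sites with no variance contribute nothing to either sum
  zero <- (a + b + c) == 0
  list(a = a, abc = a + b + c, informative = !zero & !bad)
}

# sum per-site values over windows via cumulative sums; sites and windows
# must share a chromosome namespace. values: matrix (sites x k)
window_sums <- function(sites, windows, values) {
  out <- matrix(0, nrow(windows), ncol(values))
  for (cn in unique(windows$chrom)) {
    wi <- which(windows$chrom == cn)
    si <- which(sites$chrom == cn)
    if (!length(si)) next
    p0 <- sites$pos[si] - 1 # 0-based site coordinate
    cs <- apply(values[si, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    lo <- findInterval(windows$start[wi] - 0.5, p0) + 1L
    hi <- findInterval(windows$end[wi] - 0.5, p0) + 1L
    out[wi, ] <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  out
}

#' Windowed statistics for a two-group comparison
#'
#' Computes per-window nucleotide diversity for each group (per-bp, with
#' the full window length as denominator so invariant positions count as
#' zero diversity), the Weir-Cockerham (1984) ratio-of-sums F_ST, the
#' diversity log-ratio log2(pi_control / pi_focal), and the number of
#' informative SNPs. The "control" group is the comparison's reference:
#' the non-selected population in cross-population scans, or the earlier
#' time point in temporal scans, so diversity loss in the focal group
#' raises the ratio.
#'
#' @param vt A `variant_table`.
#' @param focal_samples,control_samples Character vectors of sample ids.
#' @param windows Window tibble from [make_windows()].
#' @param min_snps Minimum informative SNPs for a window to be usable.
#' @return A window-statistics tibble with columns `chrom`, `start`, `end`,
#'   `n_snps`, `pi_focal`, `pi_control`, `fst`, `pi_log_ratio`, `usable`.
#' @export
window_stats <- function(vt, focal_samples, control_samples, windows,
                         min_snps = 3) {
  stopifnot(!any(focal_samples %in% control_samples))
  sc_f <- site_counts(vt$gt[, focal_samples, drop = FALSE])
  sc_c <- site_counts(vt$gt[, control_samples, drop = FALSE])
  pi_f <- site_pi_terms(sc_f)
  pi_c <- site_pi_terms(sc_c)
  wc <- wc84_components(sc_f, sc_c)
  vals <- cbind(pi_f, pi_c, wc$a, wc$abc, as.numeric(wc$informative))
  sums <- window_sums(vt$sites, windows, vals)
  len <- windows$end - windows$start
  pi_focal <- sums[, 1] / len
  pi_control <- sums[, 2] / len
  fst <- ifelse(sums[, 4] > 0, sums[, 3] / sums[, 4], NA_real_)
  ratio <- log2(pi_control / pi_focal)
  ratio[pi_control == 0 & pi_focal == 0] <- NA_real_
  n_snps <- sums[, 5]
  tibble(
    chrom = windows$chrom, start = windows$start, end = windows$end,
    n_snps = as.integer(n_snps),
    pi_focal = pi_focal, pi_control = pi_control,
    fst = fst, pi_log_ratio = ratio,
    usable = !windows$truncated & n_snps >= min_snps & !is.na(fst) &
      !is.na(ratio)
  )
}

#' Per-window nucleotide diversity for one sample group
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids.
#' @param window Numeric `c(start, end)`, 0-based half-open.
#' @param chrom Chromosome name.
#' @return Per-bp diversity (numeric scalar; `NA` when undefined).
#' @export
window_pi <- function(vt, samples, window, chrom) {
  sel <- vt$sites$chrom == chrom & (vt$sites$pos - 1) >= window[1] &
    (vt$sites$pos - 1) < window[2]
  gt <- vt$gt[sel, samples, drop = FALSE]
  sc <- site_counts(gt)
  if (nrow(gt) > 0 && all(sc$n < 2)) return(NA_real_)
  sum(site_pi_terms(sc)) / (window[2] - window[1])
}

#' Per-window Weir-Cockerham F_ST between two groups
#'
#' Ratio-of-sums ("weighted") estimator: per-site variance components a, b,
#' c are summed over the window and F_ST = sum(a) / sum(a+b+c). Slightly
#' negative estimates are retained, not clamped.
#'
#' @inheritParams window_pi
#' @param group_a,group_b Sample id vectors for the two groups.
#' @return F_ST (numeric scalar; `NA` when no informative site).
#' @export
window_fst <- function(vt, group_a, group_b, window, chrom) {
  sel <- vt$sites$chrom == chrom & (vt$sites$pos - 1) >= window[1] &
    (vt$sites$pos - 1) < window[2]
  sc_a <- site_counts(vt$gt[sel, group_a, drop = FALSE])
  sc_b <- site_counts(vt$gt[sel, group_b, drop = FALSE])
  wc <- wc84_components(sc_a, sc_b)
  if (sum(wc$abc) <= 0) return(NA_real_)
  sum(wc$a) / sum(wc$abc)
}

#' Wright's inbreeding coefficient per individual
#'
#' For individual i, F = (O - E) / (L - E) where O is the observed count of
#' homozygous sites among i's non-missing polymorphic sites, L that site
#' count, and E the expected homozygous count under Hardy-Weinberg using
#' sample allele frequencies with the small-sample correction
#' e_s = 1 - 2 p (1-p) n/(n-1) summed over the same sites.
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids defining both the individuals scored and the
#'   frequency reference panel.
#' @return Tibble with `sample_id`, `f`, `n_sites`.
#' @export
inbreeding_f <- function(vt, samples = vt$samples) {
  gt <- vt$gt[, samples, drop = FALSE]
  sc <- site_counts(gt)
  poly <- sc$n >= 2 & sc$alt > 0 & sc$alt < sc$n
  gt <- gt[poly, , drop = FALSE]
  n <- sc$n[poly]
  p <- sc$alt[poly] / n
  e_s <- 1 - 2 * p * (1 - p) * n / (n - 1)
  nonmiss <- !is.na(gt)
  O <- colSums((gt == 0L | gt == 2L) & nonmiss, na.rm = TRUE)
  E <- as.vector(crossprod(nonmiss, e_s))
  L <- colSums(nonmiss)
  f <- unname(ifelse(L - E != 0, (O - E) / (L - E), NA_real_))
  tibble(sample_id = samples, f = f, n_sites = unname(L))
}
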