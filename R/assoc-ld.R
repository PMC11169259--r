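#' Per-SNP Fisher exact case/control association scan
#'
#' For every SNP, a two-sided Fisher exact test on the 2x2 table of
#' case/control allele-copy counts (the standard small-p rule: the p-value
#' sums the probabilities of all tables with fixed margins whose point
#' probability does not exceed the observed table's). Bonferroni-adjusted
#' p-values (m = SNPs tested) and Benjamini-Hochberg q-values are attached.
#' Monomorphic SNPs are well-defined and score p = 1.
#'
#' @param vt A `variant_table`.
#' @param metadata Sample metadata with `sample_id` and `phenotype`
#'   (`"case"` / `"control"`).
#' @return Tibble per SNP: `chrom`, `pos`, allele counts
#'   (`case_ref`, `case_alt`, `ctrl_ref`, `ctrl_alt`), `p`, `p_bonf`, `q`.
#' @export
fisher_assoc_scan <- function(vt, metadata) {
  cases <- intersect(vt$samples, metadata$sample_id[metadata$phenotype == "case"])
  ctrls <- intersect(vt$samples, metadata$sample_id[metadata$phenotype == "control"])
  if (length(cases) < 2 || length(ctrls) < 2)
    stop("need at least 2 cases and 2 controls")
  gt_a <- vt$gt[, cases, drop = FALSE]
  gt_c <- vt$gt[, ctrls, drop = FALSE]
  ca_alt <- rowSums(gt_a, na.rm = TRUE)
  ca_n <- 2 * rowSums(!is.na(gt_a))
  co_alt <- rowSums(gt_c, na.rm = TRUE)
  co_n <- 2 * rowSums(!is.na(gt_c))
  p <- vapply(seq_along(ca_alt), function(i) {
    tab <- matrix(c(ca_n[i] - ca_alt[i], ca_alt[i],
                    co_n[i] - co_alt[i], co_alt[i]), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    fisher.test(tab)$p.value
  }, numeric(1))
  tibble(
    chrom = vt$sites$chrom, pos = vt$sites$pos,
    case_ref = ca_n - ca_alt, case_alt = ca_alt,
    ctrl_ref = co_n - co_alt, ctrl_alt = co_alt,
    p = p,
    p_bonf = pmin(1, p * length(p)),
    q = bh_fdr(p)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Pairwise linkage disequilibrium r-squared
#'
#' r2 = D^2 / (pA (1-pA) pB (1-pB)) from two-locus haplotype frequencies.
#' With phased input the haplotype frequencies are counted directly; with
#' unphased genotypes they are estimated by the standard two-locus EM
#' algorithm (double heterozygotes split between the coupling and repulsion
#' phases). Pairs where either SNP is monomorphic are undefined and
#' excluded rather than reported as zero, to avoid biasing decay curves.
#'
#' @param vt A `variant_table`.
#' @param samples Sample ids (default all).
#' @param chrom Chromosome to analyse.
#' @param region Optional `c(start, end)` (0-based half-open) restricting
#'   the SNPs considered.
#' @param method `"phased"` or `"em"`.
#' @param max_pairs If the region holds more SNP pairs than this, a
#'   deterministic thinning of SNPs is applied first.
#' @param em_tol,em_max_iter EM convergence parameters.
#' @return Tibble per pair: `pos1`, `pos2`, `distance_bp`, `r2`, `method`.
#' @export
r2_matrix <- function(vt, samples = vt$samples, chrom = vt$sites$chrom[1],
                      region = NULL, method = c("phased", "em"),
                      max_pairs = 2e6, em_tol = 1e-8, em_max_iter = 1000) {
  method <- match.arg(method)
  sel <- vt$sites$chrom == chrom
  if (!is.null(region))
    sel <- sel & (vt$sites$pos - 1) >= region[1] & (vt$sites$pos - 1) < region[2]
  idx <- which(sel)
  if (length(idx) < 2L) stop("need at least 2 SNPs in the region")
  if (choose(length(idx), 2) > max_pairs) {
    thin <- ceiling(length(idx) / floor(sqrt(2 * max_pairs)))
    idx <- idx[seq(1, length(idx), by = thin)]
  }
  pos <- vt$sites$pos[idx]
  if (method == "phased") {
    n2 <- 2L * length(samples)
    h <- rbind(t(vt$a1[idx, samples, drop = FALSE]),
               t(vt$a2[idx, samples, drop = FALSE]))
    keep_hap <- rowSums(is.na(h)) == 0
    h <- h[keep_hap, , drop = FALSE]
    p1 <- colMeans(h)
    # haplotype frequency p_AB for all pairs via crossproduct
    pab <- crossprod(h) / nrow(h)
    d <- pab - outer(p1, p1)
    denom <- outer(p1 * (1 - p1), p1 * (1 - p1))
    r2 <- d^2 / denom
    ut <- upper.tri(r2)
    poly <- p1 > 0 & p1 < 1
    ok <- outer(poly, poly, `&`) & ut
    ij <- which(ok, arr.ind = TRUE)
    out <- tibble(pos1 = pos[ij[, 1]], pos2 = pos[ij[, 2]],
                  r2 = r2[ok], method = "phased")
  } else {
    gt <- vt$gt[idx, samples, drop = FALSE]
    combos <- utils::combn(seq_along(idx), 2)
    rows <- purrr::map(seq_len(ncol(combos)), function(k) {
      i <- combos[1, k]; j <- combos[2, k]
      r2 <- em_r2(gt[i, ], gt[j, ], em_tol, em_max_iter)
      if (is.na(r2)) return(NULL)
      tibble(pos1 = pos[i], pos2 = pos[j], r2 = r2, method = "em")
    })
    out <- dplyr::bind_rows(rows)
  }
  out$distance_bp <- abs(out$pos2 - out$pos1)
  out[, c("pos1", "pos2", "distance_bp", "r2", "method")]
}

# two-locus EM for haplotype frequencies from unphased dosages
em_r2 <- function(g1, g2, tol, max_iter) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  if (n < 2) return(NA_real_)
  pA <- mean(g1) / 2
  pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  # haplotype classes: 00, 01, 10, 11 (alleles at locus 1, locus 2)
  f <- c(`00` = (1 - pA) * (1 - pB), `01` = (1 - pA) * pB,
         `10` = pA * (1 - pB), `11` = pA * pB)
  dh <- g1 == 1 & g2 == 1 # double heterozygotes: phase-ambiguous
  # fixed haplotype counts from unambiguous genotypes
  count_fixed <- setNames(numeric(4), c("00", "01", "10", "11"))
  for (i in which(!dh)) {
    a <- g1[i]; b <- g2[i]
    if (a != 1 && b != 1) {
      count_fixed[hap_key(a / 2, b / 2)] <- count_fixed[hap_key(a / 2, b / 2)] + 2
    } else if (a == 1 && b != 1) {
      count_fixed[hap_key(0, b / 2)] <- count_fixed[hap_key(0, b / 2)] + 1
      count_fixed[hap_key(1, b / 2)] <- count_fixed[hap_key(1, b / 2)] + 1
    } else if (a != 1 && b == 1) {
      count_fixed[hap_key(a / 2, 0)] <- count_fixed[hap_key(a / 2, 0)] + 1
      count_fixed[hap_key(a / 2, 1)] <- count_fixed[hap_key(a / 2, 1)] + 1
    }
  }
  n_dh <- sum(dh)
  for (iter in seq_len(max_iter)) {
    # E step: split double heterozygotes between coupling (00/11) and
    # repulsion (01/10) phases
    pc <- f["00"] * f["11"]
    pr <- f["01"] * f["10"]
    w <- if (pc + pr > 0) pc / (pc + pr) else 0.5
    cnt <- count_fixed
    cnt["00"] <- cnt["00"] + n_dh * w
    cnt["11"] <- cnt["11"] + n_dh * w
    cnt["01"] <- cnt["01"] + n_dh * (1 - w)
    cnt["10"] <- cnt["10"] + n_dh * (1 - w)
    f_new <- cnt / sum(cnt)
    if (max(abs(f_new - f)) < tol) { f <- f_new; break }
    f <- f_new
    if (iter == max_iter) return(NA_real_) # non-convergent pair excluded
  }
  d <- f["11"] - (f["10"] + f["11"]) * (f["01"] + f["11"])
  pA <- f["10"] + f["11"]
  pB <- f["01"] + f["11"]
  unname(d^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

hap_key <- function(a, b) paste0(a, b)

#' LD decay curve
#'
#' Mean r2 within physical-distance bins.
#'
#' @param ld_results Tibble from [r2_matrix()].
#' @param bin_width_bp Distance bin width.
#' @param min_pairs Bins with fewer pairs are suppressed.
#' @return Tibble: `bin_start`, `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(ld_results, bin_width_bp = 10000, min_pairs = 5) {
  if (nrow(ld_results) == 0L)
    return(tibble(bin_start = numeric(), bin_mid = numeric(),
                  mean_r2 = numeric(), n_pairs = integer()))
  ld_results %>%
    dplyr::mutate(bin_start = floor(.data$distance_bp / bin_width_bp) * bin_width_bp) %>%
    dplyr::group_by(.data$bin_start) %>%
    dplyr::summarise(bin_mid = .data$bin_start[1] + bin_width_bp / 2,
                     mean_r2 = mean(.data$r2),
                     n_pairs = dplyr::n(), .groups = "drop") %>%
    dplyr::filter(.data$n_pairs >= min_pairs) %>%
    dplyr::arrange(.data$bin_start)
}

#' Compare LD decay between two regions
#'
#' Tests whether per-pair r2 differs between two regions after matching on
#' distance: within each shared distance bin a two-sample Wilcoxon rank
#' test is applied and the bin p-values are combined by Fisher's method.
#' This rank-based construction is this package's choice of test for
#' region-versus-genome LD contrasts.
#'
#' @param ld_a,ld_b Tibbles from [r2_matrix()] for the two regions.
#' @param bin_width_bp Distance bin width for matching.
#' @param min_pairs Minimum pairs per region per bin.
#' @return List with `per_bin` tibble and combined `p`.
#' @export
ld_decay_compare <- function(ld_a, ld_b, bin_width_bp = 10000, min_pairs = 5) {
  bin <- function(x) floor(x$distance_bp / bin_width_bp) * bin_width_bp
  a <- ld_a %>% dplyr::mutate(b = bin(ld_a))
  b <- ld_b %>% dplyr::mutate(b = bin(ld_b))
  shared <- intersect(unique(a$b), unique(b$b))
  per_bin <- purrr::map_dfr(shared, function(bb) {
    xa <- a$r2[a$b == bb]
    xb <- b$r2[b$b == bb]
    if (length(xa) < min_pairs || length(xb) < min_pairs) return(NULL)
    p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
    tibble(bin_start = bb, n_a = length(xa), n_b = length(xb),
           mean_r2_a = mean(xa), mean_r2_b = mean(xb), p = p)
  })
  if (nrow(per_bin) == 0L) return(list(per_bin = per_bin, p = NA_real_))
  chi <- -2 * sum(log(pmax(per_bin$p, 1e-300)))
  list(per_bin = per_bin,
       p = stats::pchisq(chi, df = 2 * nrow(per_bin), lower.tail = FALSE))
}
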