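#' Build a phased haplotype matrix from a variant table
#'
#' Extracts the phased 0/1 alleles of the chosen samples as a haplotype
#' matrix (two rows per diploid). Sites with any missing or unphased call
#' among the chosen samples are dropped, since extended-haplotype
#' statistics require complete phased data.
#'
#' @param vt A `variant_table` with phased genotypes.
#' @param samples Sample ids to include.
#' @return An object of class `haplotype_matrix`: list with `hap`
#'   (haplotypes x sites 0/1 matrix), `chrom`, `pos` (1-based site
#'   positions), and `sample_of_origin` per row.
#' @export
haplotype_matrix <- function(vt, samples = vt$samples) {
  ph <- vt$phased[, samples, drop = FALSE]
  a1 <- vt$a1[, samples, drop = FALSE]
  a2 <- vt$a2[, samples, drop = FALSE]
  complete <- rowSums(is.na(a1) | is.na(a2)) == 0
  unphased <- !is.na(vt$gt[, samples, drop = FALSE]) & !ph &
    vt$gt[, samples, drop = FALSE] == 1L
  if (any(unphased))
    stop("heterozygous unphased calls present; haplotype statistics need phased input")
  keep <- complete
  if (sum(keep) < 2L) stop("fewer than 2 fully called sites")
  hap <- matrix(0L, nrow = 2L * length(samples), ncol = sum(keep))
  hap[seq(1, nrow(hap), 2), ] <- t(a1[keep, , drop = FALSE])
  hap[seq(2, nrow(hap), 2), ] <- t(a2[keep, , drop = FALSE])
  structure(list(hap = hap,
                 chrom = vt$sites$chrom[keep],
                 pos = vt$sites$pos[keep],
                 sample_of_origin = rep(samples, each = 2L)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("<haplotype_matrix>", nrow(x$hap), "haplotypes x", ncol(x$hap),
      "sites on", length(unique(x$chrom)), "chromosome(s)\n")
  invisible(x)
}

# homozygosity of a grouping: sum over groups of C(n_g,2) / C(n,2)
group_homozygosity <- function(group_ids) {
  n <- length(group_ids)
  tab <- tabulate(group_ids)
  sum(tab * (tab - 1)) / (n * (n - 1))
}

#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at marker x is the probability that two random haplotypes carrying
#' the core allele are identical over the inclusive interval from the core
#' to x; it is 1 at the core and non-increasing with distance.
#'
#' @param hm A `haplotype_matrix` (single chromosome for the walked
#'   direction; sites on other chromosomes are ignored).
#' @param core_site Column index of the core SNP in `hm`.
#' @param allele_class 0 or 1: the core allele whose carriers are followed.
#' @param direction `"left"` or `"right"` of the core.
#' @return Tibble with `distance_bp` (0 at the core) and `ehh`.
#' @export
ehh_curve <- function(hm, core_site, allele_class, direction = c("right", "left")) {
  direction <- match.arg(direction)
  carriers <- which(hm$hap[, core_site] == allele_class)
  if (length(carriers) < 2L) stop("allele class carried by fewer than 2 haplotypes")
  chrom <- hm$chrom[core_site]
  m <- ncol(hm$hap)
  idx <- if (direction == "right") {
    if (core_site >= m) integer(0) else seq(core_site + 1L, m)
  } else {
    if (core_site <= 1L) integer(0) else rev(seq_len(core_site - 1L))
  }
  idx <- idx[hm$chrom[idx] == chrom]
  g <- rep(1L, length(carriers))
  d <- 0
  out_d <- 0
  out_e <- 1
  for (j in idx) {
    a <- hm$hap[carriers, j]
    g <- g * 2L + a
    g <- match(g, unique(g))
    out_d <- c(out_d, abs(hm$pos[j] - hm$pos[core_site]))
    out_e <- c(out_e, group_homozygosity(g))
  }
  tibble(distance_bp = out_d, ehh = out_e)
}

# walk outward from the core integrating EHH by trapezoids until it falls
# below `cutoff` (that terminal trapezoid is included) or truncation
ihh_one_direction <- function(hap, pos, chrom, core_site, carriers, cutoff,
                              max_gap_bp, max_extend_bp, direction) {
  m <- length(pos)
  idx <- if (direction == "right") {
    if (core_site >= m) integer(0) else seq(core_site + 1L, m)
  } else {
    if (core_site <= 1L) integer(0) else rev(seq_len(core_site - 1L))
  }
  idx <- idx[chrom[idx] == chrom[core_site]]
  g <- rep(1L, length(carriers))
  e_prev <- 1
  d_prev <- 0
  total <- 0
  p_prev <- pos[core_site]
  for (j in idx) {
    gap <- abs(pos[j] - p_prev)
    d_cur <- abs(pos[j] - pos[core_site])
    if (gap > max_gap_bp || d_cur > max_extend_bp)
      return(list(ihh = total, truncated = TRUE))
    a <- hap[carriers, j]
    g <- g * 2L + a
    g <- match(g, unique(g))
    e_cur <- group_homozygosity(g)
    total <- total + (d_cur - d_prev) * (e_prev + e_cur) / 2
    if (e_cur < cutoff) return(list(ihh = total, truncated = FALSE))
    e_prev <- e_cur
    d_prev <- d_cur
    p_prev <- pos[j]
  }
  # ran off the end of the site map before EHH dropped below the cutoff
  list(ihh = total, truncated = TRUE)
}

#' Integrated EHH from a core site
#'
#' Trapezoidal integral of the EHH curve over physical distance, walked in
#' both directions from the core until EHH falls below `cutoff`. The value
#' is flagged as truncated when integration is stopped instead by a
#' chromosome end, an inter-SNP gap larger than `max_gap_bp`, or the
#' `max_extend_bp` limit.
#'
#' @inheritParams ehh_curve
#' @param cutoff EHH level at which integration stops (default 0.05).
#' @param max_gap_bp Maximum tolerated gap between adjacent SNPs.
#' @param max_extend_bp Maximum integration distance per side.
#' @return List with `ihh` (bp) and `truncated` (logical).
#' @export
ihh <- function(hm, core_site, allele_class, cutoff = 0.05,
                max_gap_bp = 2e5, max_extend_bp = 1e6) {
  carriers <- which(hm$hap[, core_site] == allele_class)
  if (length(carriers) < 2L) stop("allele class carried by fewer than 2 haplotypes")
  if (cutoff >= 1) return(list(ihh = 0, truncated = FALSE))
  r <- ihh_one_direction(hm$hap, hm$pos, hm$chrom, core_site, carriers,
                         cutoff, max_gap_bp, max_extend_bp, "right")
  l <- ihh_one_direction(hm$hap, hm$pos, hm$chrom, core_site, carriers,
                         cutoff, max_gap_bp, max_extend_bp, "left")
  list(ihh = r$ihh + l$ihh, truncated = r$truncated || l$truncated)
}

#' Genome-wide iHS scan
#'
#' For each core SNP with minor-allele frequency at or above `maf_floor`,
#' the raw integrated haplotype score is ln(iHH_ancestral / iHH_derived).
#' The ancestral allele defaults to the reference allele (the usual choice
#' when no outgroup polarisation is available); `polarity =
#' "alt_ancestral"` swaps the roles, negating every raw score. Raw scores
#' are standardised to z-scores within derived-allele-frequency bins
#' (equal-width; sparse bins are merged with their left neighbour), giving
#' the normalised track mean 0 and unit spread by construction. Cores whose
#' integration was truncated are dropped by default.
#'
#' @param hm A `haplotype_matrix`.
#' @param polarity `"ref_ancestral"` or `"alt_ancestral"`.
#' @param cutoff,max_gap_bp,max_extend_bp Passed to [ihh()].
#' @param maf_floor Minimum minor-allele frequency for a core SNP.
#' @param n_bins Number of derived-frequency bins for normalisation.
#' @param drop_truncated Drop cores with truncated integration.
#' @return A score-track tibble: `chrom`, `pos`, `freq_derived`, `raw`,
#'   `norm`, `truncated`, `stat = "ihs"`.
#' @export
ihs_scan <- function(hm, polarity = c("ref_ancestral", "alt_ancestral"),
                     cutoff = 0.05, max_gap_bp = 2e5, max_extend_bp = 1e6,
                     maf_floor = 0.05, n_bins = 20, drop_truncated = TRUE) {
  polarity <- match.arg(polarity)
  derived <- if (polarity == "ref_ancestral") 1L else 0L
  n <- nrow(hm$hap)
  freq1 <- colMeans(hm$hap)
  daf <- if (derived == 1L) freq1 else 1 - freq1
  maf <- pmin(freq1, 1 - freq1)
  cores <- which(maf >= maf_floor)
  rows <- purrr::map(cores, function(j) {
    anc <- which(hm$hap[, j] != derived)
    der <- which(hm$hap[, j] == derived)
    if (length(anc) < 2L || length(der) < 2L) return(NULL)
    ia <- ihh_core(hm, j, anc, cutoff, max_gap_bp, max_extend_bp)
    id <- ihh_core(hm, j, der, cutoff, max_gap_bp, max_extend_bp)
    if (ia$ihh <= 0 || id$ihh <= 0) return(NULL)
    tibble(chrom = hm$chrom[j], pos = hm$pos[j], freq_derived = daf[j],
           raw = log(ia$ihh / id$ihh),
           truncated = ia$truncated || id$truncated)
  })
  track <- dplyr::bind_rows(rows)
  if (nrow(track) == 0L) stop("no scoreable core SNPs")
  if (drop_truncated) track <- track[!track$truncated, , drop = FALSE]
  track$norm <- normalise_in_bins(track$raw, track$freq_derived, n_bins)
  track$stat <- "ihs"
  track[, c("chrom", "pos", "freq_derived", "raw", "norm", "truncated", "stat")]
}

ihh_core <- function(hm, j, carriers, cutoff, max_gap_bp, max_extend_bp) {
  r <- ihh_one_direction(hm$hap, hm$pos, hm$chrom, j, carriers,
                         cutoff, max_gap_bp, max_extend_bp, "right")
  l <- ihh_one_direction(hm$hap, hm$pos, hm$chrom, j, carriers,
                         cutoff, max_gap_bp, max_extend_bp, "left")
  list(ihh = r$ihh + l$ihh, truncated = r$truncated || l$truncated)
}

normalise_in_bins <- function(raw, freq, n_bins) {
  bin <- pmin(pmax(ceiling(freq * n_bins), 1L), n_bins)
  # merge bins with < 2 scores into the nearest lower occupied bin
  repeat {
    counts <- table(bin)
    small <- as.integer(names(counts)[counts < 2])
    if (!length(small)) break
    b <- small[1]
    others <- setdiff(unique(bin), b)
    if (!length(others)) break
    target <- others[which.min(abs(others - b))]
    bin[bin == b] <- target
  }
  z <- raw
  for (b in unique(bin)) {
    sel <- bin == b
    mu <- mean(raw[sel])
    s <- sd(raw[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (raw[sel] - mu) / s
  }
  z
}

#' Cross-population XP-EHH scan
#'
#' For each shared core SNP, the raw score is ln(iHH_focal / iHH_control)
#' with iHH integrated over all haplotypes of each population (no allele
#' split); positive scores mean longer haplotypes — more recent selection —
#' in the focal population. Scores are standardised genome-wide.
#'
#' @param hm_focal,hm_control `haplotype_matrix` objects sharing the same
#'   site map.
#' @inheritParams ihs_scan
#' @return A score-track tibble with `stat = "xpehh"`.
#' @export
xpehh_scan <- function(hm_focal, hm_control, cutoff = 0.05,
                       max_gap_bp = 2e5, max_extend_bp = 1e6,
                       maf_floor = 0.05, drop_truncated = TRUE) {
  if (!identical(hm_focal$pos, hm_control$pos) ||
      !identical(hm_focal$chrom, hm_control$chrom))
    stop("populations must share the same site map")
  pooled <- (colSums(hm_focal$hap) + colSums(hm_control$hap)) /
    (nrow(hm_focal$hap) + nrow(hm_control$hap))
  maf <- pmin(pooled, 1 - pooled)
  cores <- which(maf >= maf_floor)
  all_f <- seq_len(nrow(hm_focal$hap))
  all_c <- seq_len(nrow(hm_control$hap))
  rows <- purrr::map(cores, function(j) {
    f <- ihh_core(hm_focal, j, all_f, cutoff, max_gap_bp, max_extend_bp)
    c_ <- ihh_core(hm_control, j, all_c, cutoff, max_gap_bp, max_extend_bp)
    if (f$ihh <= 0 || c_$ihh <= 0) return(NULL)
    tibble(chrom = hm_focal$chrom[j], pos = hm_focal$pos[j],
           freq_derived = colMeans(hm_focal$hap[, j, drop = FALSE])[[1]],
           raw = log(f$ihh / c_$ihh),
           truncated = f$truncated || c_$truncated)
  })
  track <- dplyr::bind_rows(rows)
  if (nrow(track) == 0L) stop("no scoreable core SNPs")
  if (drop_truncated) track <- track[!track$truncated, , drop = FALSE]
  mu <- mean(track$raw)
  s <- sd(track$raw)
  track$norm <- if (is.na(s) || s == 0) 0 else (track$raw - mu) / s
  track$stat <- "xpehh"
  track[, c("chrom", "pos", "freq_derived", "raw", "norm", "truncated", "stat")]
}

#' Flag selection windows and validate candidate genes
#'
#' On a non-overlapping window grid, a window is flagged when it contains
#' at least one core SNP with |normalised iHS| above the genome-wide
#' (1 - threshold) percentile, or with normalised XP-EHH above that
#' percentile (positive tail only, so haplotype extension in the control
#' population does not validate). A candidate gene is validated if it
#' overlaps at least one flagged window from either statistic.
#'
#' @param ihs_track,xpehh_track Score-track tibbles (either may be `NULL`).
#' @param windows Non-overlapping window tibble from [make_windows()].
#' @param genes Gene-model tibble.
#' @param candidate_ids Character vector of candidate gene ids.
#' @param threshold Tail fraction defining extreme scores (default 0.05).
#' @return List with `flagged_windows`, `validation` (tibble `gene_id`,
#'   `validated`) and `validated_pct`.
#' @export
flag_windows_and_validate <- function(ihs_track = NULL, xpehh_track = NULL,
                                      windows, genes, candidate_ids,
                                      threshold = 0.05) {
  extreme <- list()
  if (!is.null(ihs_track) && nrow(ihs_track)) {
    thr <- quantile(abs(ihs_track$norm), 1 - threshold, names = FALSE)
    extreme$ihs <- ihs_track[abs(ihs_track$norm) > thr, c("chrom", "pos")]
  }
  if (!is.null(xpehh_track) && nrow(xpehh_track)) {
    thr <- quantile(xpehh_track$norm, 1 - threshold, names = FALSE)
    extreme$xpehh <- xpehh_track[xpehh_track$norm > thr, c("chrom", "pos")]
  }
  snps <- dplyr::bind_rows(extreme)
  if (nrow(snps) == 0L) {
    warning("no extreme scores; nothing validated")
    flagged <- windows[0, , drop = FALSE]
  } else {
    hit <- window_sums(snps %>% dplyr::arrange(.data$chrom, .data$pos),
                       windows, matrix(1, nrow(snps), 1))
    flagged <- windows[hit[, 1] > 0, , drop = FALSE]
  }
  cand <- genes[genes$gene_id %in% candidate_ids, , drop = FALSE]
  validated <- vapply(seq_len(nrow(cand)), function(i) {
    any(flagged$chrom == cand$chrom[i] &
          flagged$start < cand$end[i] &
          flagged$end > cand$start[i])
  }, logical(1))
  validation <- tibble(gene_id = cand$gene_id, validated = validated)
  list(flagged_windows = flagged,
       validation = validation,
       validated_pct = if (nrow(cand)) 100 * mean(validated) else 0)
}
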