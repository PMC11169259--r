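# Independent brute-force oracles used to check the analytic
# implementations on small instances. Deliberately naive: explicit loops
# and enumeration, written directly from first principles.

# mean pairwise differences among allele copies, divided by window length
oracle_pi <- function(gt, window_len) {
  # gt: sites x samples dosage matrix (0/1/2/NA)
  total <- 0
  for (s in seq_len(nrow(gt))) {
    copies <- integer(0)
    for (i in seq_len(ncol(gt))) {
      d <- gt[s, i]
      if (!is.na(d)) copies <- c(copies, c(ifelse(d >= 1, 1L, 0L),
                                           ifelse(d == 2, 1L, 0L)))
    }
    n <- length(copies)
    if (n < 2) next
    diff <- 0
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
      diff <- diff + (copies[i] != copies[j])
    total <- total + diff / choose(n, 2)
  }
  total / window_len
}

# line-by-line Weir & Cockerham (1984) two-population estimator,
# transcribed independently from the published variance components
oracle_wc_fst <- function(gt_a, gt_b) {
  num <- 0
  den <- 0
  for (s in seq_len(nrow(gt_a))) {
    ga <- gt_a[s, ][!is.na(gt_a[s, ])]
    gb <- gt_b[s, ][!is.na(gt_b[s, ])]
    n1 <- length(ga); n2 <- length(gb)
    if (n1 < 1 || n2 < 1) next
    p1 <- sum(ga) / (2 * n1); p2 <- sum(gb) / (2 * n2)
    h1 <- mean(ga == 1); h2 <- mean(gb == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2 / 2
    if (a + b + cc == 0) next
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) return(NA_real_)
  num / den
}

# EHH by explicit haplotype-string grouping over the inclusive interval
oracle_ehh <- function(hap, pos, core, allele, x) {
  carriers <- which(hap[, core] == allele)
  lo <- min(core, x); hi <- max(core, x)
  keys <- apply(hap[carriers, lo:hi, drop = FALSE], 1, paste, collapse = "")
  n <- length(carriers)
  hom_pairs <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    hom_pairs <- hom_pairs + (keys[i] == keys[j])
  hom_pairs / choose(n, 2)
}

# iHH by explicit trapezoid integration of the oracle EHH curve
oracle_ihh <- function(hap, pos, core, allele, cutoff = 0.05) {
  total <- 0
  for (dir in c(-1, 1)) {
    e_prev <- 1; d_prev <- 0
    x <- core
    repeat {
      x <- x + dir
      if (x < 1 || x > ncol(hap)) break
      e <- oracle_ehh(hap, pos, core, allele, x)
      d <- abs(pos[x] - pos[core])
      total <- total + (d - d_prev) * (e_prev + e) / 2
      if (e < cutoff) break
      e_prev <- e; d_prev <- d
    }
  }
  total
}

# two-sided Fisher p by exhaustive enumeration of tables with fixed margins
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  prob <- function(a) dhyper(a, r1, r2, c1)
  p_obs <- prob(tab[1, 1])
  a_range <- max(0, c1 - r2):min(r1, c1)
  sum(vapply(a_range, prob, 1)[vapply(a_range, prob, 1) <= p_obs * (1 + 1e-7)])
}

# upper-tail hypergeometric by term-by-term summation
oracle_hyper_upper <- function(k, K, N, n) {
  x_range <- k:min(K, n)
  sum(choose(K, x_range) * choose(N - K, n - x_range)) / choose(N, n)
}

# random small genotype matrix for property tests
random_gt <- function(n_sites, n_samples, miss = 0.1) {
  gt <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
               nrow = n_sites)
  gt[runif(length(gt)) < miss] <- NA
  gt
}

# wrap a bare dosage matrix as a variant_table on one chromosome
toy_variant_table <- function(gt, pos = NULL, chrom = "chr1",
                              phased_hap = NULL) {
  m <- nrow(gt); n <- ncol(gt)
  if (is.null(pos)) pos <- sort(sample.int(1e5, m))
  ids <- sprintf("S%02d", seq_len(n))
  colnames(gt) <- ids
  if (is.null(phased_hap)) {
    a1 <- ifelse(is.na(gt), NA_integer_, ifelse(gt == 2, 1L, ifelse(gt == 1, 1L, 0L)))
    a2 <- ifelse(is.na(gt), NA_integer_, ifelse(gt == 2, 1L, 0L))
  } else {
    a1 <- phased_hap[, seq(1, 2 * n, 2), drop = FALSE]
    a2 <- phased_hap[, seq(2, 2 * n, 2), drop = FALSE]
    colnames(a1) <- colnames(a2) <- ids
  }
  dp <- matrix(30L, m, n, dimnames = list(NULL, ids))
  sites <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "T",
    qual = 100, qd = 25, fs = 1, mq = 58, mq_rank_sum = 0,
    read_pos_rank_sum = 0
  )
  temporalsweep:::new_variant_table(
    sites, gt, dp, dp - 0L, matrix(0L, m, n, dimnames = list(NULL, ids)),
    a1, a2, matrix(TRUE, m, n, dimnames = list(NULL, ids)), ids)
}

# small, fast simulation configuration for end-to-end tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, pop_size = 120, n_sites_per_chrom = 2500,
             n_chromosomes = 2, chrom_length_bp = 1e6,
             burn_in_generations = 60, split_generations = 80,
             sweep_start_gen = 46, sample_gens = c(56, 76, 80),
             sweep_pos = 5e5, gene_length_bp = 1e4,
             recomb_rate = 3e-7, ...)
}
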