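#' Simulate a temporally sampled cohort with a planted hard sweep
#'
#' Runs a forward Wright-Fisher simulation of two diverged diploid
#' populations. Standing variation is initialised from the neutral site
#' frequency spectrum at linkage equilibrium and a neutral burn-in builds
#' linkage disequilibrium before the populations split. In the focal
#' population a single copy of a beneficial allele (additive fitnesses
#' 1, 1+s, 1+2s) arises at `sweep_start_gen`; if it is lost before the first
#' sample generation the sweep phase is retried from the same pre-sweep
#' state (conditioning a hard sweep on establishment). Phased samples are
#' drawn without replacement at three focal time points and once from the
#' control population, and per-call sequencing depth (DP/AD) plus per-site
#' caller-style QC annotations are attached so downstream filters can be
#' exercised. Gene models are tiled end-to-end and two differentially
#' expressed gene (DEG) lists are drawn with a configurable planted odds
#' ratio between DEG membership and overlap with the sweep window.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sweep_cohort`: a list with elements
#'   `sites` (tibble of site coordinates and QC annotations), `hap`
#'   (sites x 2*samples phased 0/1 matrix), `gt` (sites x samples dosage),
#'   `dp`/`ad_alt` (per-call depth matrices), `samples` (metadata tibble),
#'   `genes` (tiled gene models, 0-based half-open), `deg` (named list of
#'   DEG gene-id vectors), `truth` (sweep ground-truth record) and `config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 42, pop_size = 60, n_sites_per_chrom = 80,
#'                   burn_in_generations = 20, split_generations = 30,
#'                   sweep_start_gen = 10, sample_gens = c(16, 26, 30))
#' ch <- simulate_cohort(cfg)
#' ch$truth$status
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  n2 <- 2L * cfg$pop_size
  m_per <- cfg$n_sites_per_chrom

  # site map: uniform positions per chromosome, sweep site placed exactly
  pos_list <- lapply(seq_len(cfg$n_chromosomes), function(c) {
    p <- sort(sample.int(cfg$chrom_length_bp - 1L, m_per))
    if (c == cfg$sweep_chrom) {
      i <- which.min(abs(p - cfg$sweep_pos))
      p[i] <- as.integer(cfg$sweep_pos)
      p <- sort(unique(p))
      while (length(p) < m_per) p <- sort(unique(c(p, sample.int(cfg$chrom_length_bp - 1L, m_per - length(p)))))
    }
    p
  })
  pos <- unlist(pos_list)
  chrom_idx <- rep(seq_len(cfg$n_chromosomes) - 1L, times = vapply(pos_list, length, 1L))
  m <- length(pos)
  sweep_site <- which(chrom_idx == cfg$sweep_chrom - 1L & pos == as.integer(cfg$sweep_pos))[1] - 1L

  # standing variation: counts from the neutral SFS (P(k) ~ 1/k), assigned
  # to haplotypes at linkage equilibrium; the sweep site starts monomorphic
  sfs_p <- 1 / seq_len(n2 - 1L)
  counts <- sample.int(n2 - 1L, m, replace = TRUE, prob = sfs_p / sum(sfs_p))
  H <- matrix(as.raw(0L), nrow = n2, ncol = m)
  for (j in seq_len(m)) {
    if (j == sweep_site + 1L) next
    H[sample.int(n2, counts[j]), j] <- as.raw(1L)
  }

  chrom_len <- rep(cfg$chrom_length_bp, cfg$n_chromosomes)
  evolve <- function(H, n_gen, s = 0, track = -1L) {
    if (n_gen <= 0L) return(list(H = H, traj = numeric(0)))
    wf_evolve(H, as.numeric(pos), chrom_idx, chrom_len, as.integer(n_gen),
              s, as.integer(track), cfg$recomb_rate)
  }

  H <- evolve(H, cfg$burn_in_generations)$H

  # split: control and focal start as copies of the ancestral population
  ctrl <- evolve(H, cfg$split_generations)$H
  ctrl_samp <- sample.int(cfg$pop_size, cfg$control_sample_size)

  foc <- evolve(H, cfg$sweep_start_gen, s = 0, track = sweep_site)
  traj_pre <- if (cfg$sweep_start_gen > 0) rep(0, cfg$sweep_start_gen) else numeric(0)
  pre_state <- foc$H

  gens <- c(cfg$sweep_start_gen, cfg$sample_gens)
  status <- "ok"
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    Hf <- pre_state
    Hf[sample.int(n2, 1L), sweep_site + 1L] <- as.raw(1L)
    seg1 <- evolve(Hf, gens[2] - gens[1], s = cfg$selection_coeff, track = sweep_site)
    lost <- length(seg1$traj) > 0 && seg1$traj[length(seg1$traj)] == 0
    if (!lost || cfg$selection_coeff == 0) break
    if (attempts >= cfg$max_sweep_retries) { status <- "sweep lost"; break }
  }
  samp1 <- sample.int(cfg$pop_size, cfg$focal_sample_size)
  hap1 <- seg1$H[ind_rows(samp1), , drop = FALSE]
  seg2 <- evolve(seg1$H, gens[3] - gens[2], s = cfg$selection_coeff, track = sweep_site)
  samp2 <- sample.int(cfg$pop_size, cfg$focal_sample_size)
  hap2 <- seg2$H[ind_rows(samp2), , drop = FALSE]
  seg3 <- evolve(seg2$H, gens[4] - gens[3], s = cfg$selection_coeff, track = sweep_site)
  samp3 <- sample.int(cfg$pop_size, cfg$focal_sample_size)
  hap3 <- seg3$H[ind_rows(samp3), , drop = FALSE]

  traj <- c(traj_pre, seg1$traj, seg2$traj, seg3$traj)
  fixation_gen <- if (any(traj == 1)) which(traj == 1)[1] else NA_integer_

  # assemble sampled haplotypes: 3 focal groups then control
  hap_ctrl <- ctrl[ind_rows(ctrl_samp), , drop = FALSE]
  hap_all <- rbind(hap1, hap2, hap3, hap_ctrl)
  hap_int <- matrix(as.integer(hap_all), nrow = nrow(hap_all))

  years <- c(2012L, 2017L, 2018L)
  n_f <- cfg$focal_sample_size
  sample_ids <- c(
    sprintf("K%d_%02d", rep(years, each = n_f), rep(seq_len(n_f), 3)),
    sprintf("AUS_%02d", seq_len(cfg$control_sample_size))
  )
  n_samp <- length(sample_ids)
  samples <- tibble(
    sample_id = sample_ids,
    population = rep(c("focal", "control"), c(3L * n_f, cfg$control_sample_size)),
    year = c(rep(years, each = n_f), rep(NA_integer_, cfg$control_sample_size)),
    phenotype = rep(c("case", "control"), c(3L * n_f, cfg$control_sample_size)),
    sex = rep_len(c("M", "F"), n_samp)
  )

  # hemizygous-X option: males carry a single haplotype on the X,
  # represented as a duplicated chromosome copy
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (!is.na(cfg$x_chromosome)) {
    x_sites <- which(chrom_idx == cfg$x_chromosome - 1L)
    male_cols <- which(samples$sex == "M")
    for (i in male_cols) {
      a <- 2L * i - 1L
      hap_int[2L * i, x_sites] <- hap_int[a, x_sites]
    }
  }

  # keep sites segregating among sampled haplotypes (sweep site always kept)
  ac <- colSums(hap_int)
  keep <- (ac > 0 & ac < 2L * n_samp) | seq_len(m) == (sweep_site + 1L)
  hap_keep <- t(hap_int[, keep, drop = FALSE]) # sites x haplotypes
  pos_k <- pos[keep]
  chrom_k <- chrom_idx[keep]
  m_k <- nrow(hap_keep)

  gt <- hap_keep[, seq(1, 2L * n_samp, by = 2L), drop = FALSE] +
    hap_keep[, seq(2, 2L * n_samp, by = 2L), drop = FALSE]
  colnames(gt) <- sample_ids

  # simulated sequencing depth; halved on a hemizygous X in males
  lambda <- matrix(cfg$mean_depth, nrow = m_k, ncol = n_samp)
  if (!is.na(cfg$x_chromosome)) {
    xs <- chrom_k == cfg$x_chromosome - 1L
    lambda[xs, samples$sex == "M"] <- cfg$mean_depth / 2
  }
  dp <- matrix(rpois(m_k * n_samp, lambda), nrow = m_k)
  q_alt <- matrix(c(cfg$base_error, 0.5, 1 - cfg$base_error)[gt + 1L], nrow = m_k)
  ad_alt <- matrix(rbinom(m_k * n_samp, dp, q_alt), nrow = m_k)
  colnames(dp) <- colnames(ad_alt) <- sample_ids

  sites <- simulate_site_qc(m_k, cfg)
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, m_k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1L), "")
  sites <- tibble(
    chrom = chrom_names[chrom_k + 1L],
    pos = as.integer(pos_k),
    ref = ref, alt = unname(alt),
    sites
  )

  genes <- tile_genes(cfg, chrom_names)
  truth_window <- c(max(0, cfg$sweep_pos - cfg$sweep_window_halfwidth),
                    min(cfg$chrom_length_bp, cfg$sweep_pos + cfg$sweep_window_halfwidth))
  sweep_chrom_name <- chrom_names[cfg$sweep_chrom]
  in_window <- genes$chrom == sweep_chrom_name &
    genes$start < truth_window[2] & genes$end > truth_window[1]

  odds0 <- cfg$deg_fraction / (1 - cfg$deg_fraction)
  p1 <- (cfg$deg_odds_ratio * odds0) / (1 + cfg$deg_odds_ratio * odds0)
  p_deg <- ifelse(in_window, p1, cfg$deg_fraction)
  deg <- list(
    acoustic = genes$gene_id[runif(nrow(genes)) < p_deg],
    infestation = genes$gene_id[runif(nrow(genes)) < p_deg]
  )

  truth <- list(
    sweep_chrom = sweep_chrom_name,
    sweep_pos = as.numeric(cfg$sweep_pos),
    selection_coeff = cfg$selection_coeff,
    trajectory = traj,
    fixation_gen = fixation_gen,
    status = status,
    attempts = attempts,
    true_sweep_window = truth_window,
    deg_planted_genes = genes$gene_id[in_window]
  )

  structure(list(sites = sites, hap = hap_keep, gt = gt, dp = dp,
                 ad_alt = ad_alt, samples = samples, genes = genes,
                 deg = deg, truth = truth, config = cfg),
            class = "sweep_cohort")
}

ind_rows <- function(ind) as.vector(rbind(2L * ind - 1L, 2L * ind))

# caller-style per-site QC annotations: mostly passing values with a small
# planted fraction failing exactly one hard-filter criterion
simulate_site_qc <- function(m, cfg) {
  qc <- tibble(
    qual = round(runif(m, 60, 2000), 2),
    qd = round(pmax(2.5, rnorm(m, 25, 5)), 2),
    fs = round(pmin(55, abs(rnorm(m, 3, 4))), 3),
    mq = round(rnorm(m, 58, 2), 2),
    mq_rank_sum = round(rnorm(m, 0, 0.6), 3),
    read_pos_rank_sum = round(rnorm(m, 0, 0.3), 3)
  )
  n_fail <- floor(m * cfg$qc_fail_fraction)
  if (n_fail > 0) {
    bad <- sample.int(m, n_fail)
    crit <- sample.int(6L, n_fail, replace = TRUE)
    qc$qd[bad[crit == 1]] <- 1.0
    qc$fs[bad[crit == 2]] <- 85
    qc$mq[bad[crit == 3]] <- 32
    qc$mq_rank_sum[bad[crit == 4]] <- -3.5
    qc$read_pos_rank_sum[bad[crit == 5]] <- -1.6
    qc$qual[bad[crit == 6]] <- 12
  }
  qc
}

tile_genes <- function(cfg, chrom_names) {
  per_chrom <- floor(cfg$chrom_length_bp / cfg$gene_length_bp)
  starts <- (seq_len(per_chrom) - 1) * cfg$gene_length_bp
  tibble(
    gene_id = sprintf("g%04d", seq_len(per_chrom * cfg$n_chromosomes)),
    chrom = rep(chrom_names, each = per_chrom),
    start = rep(starts, cfg$n_chromosomes),
    end = rep(starts + cfg$gene_length_bp, cfg$n_chromosomes),
    strand = rep_len(c("+", "-"), per_chrom * cfg$n_chromosomes)
  )
}

#' @export
print.sweep_cohort <- function(x, ...) {
  cat("<sweep_cohort>", nrow(x$sites), "sites x", nrow(x$samples), "samples;",
      "sweep", x$truth$sweep_chrom, "@", x$truth$sweep_pos,
      sprintf("(s = %g, %s)\n", x$truth$selection_coeff, x$truth$status))
  invisible(x)
}
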