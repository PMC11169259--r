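#' Simulation configuration for the temporal sweep cohort generator
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults describe the study design the simulator emulates: a focal
#' population carrying a recent hard sweep, sampled three times (10 diploid
#' individuals each) across the sweep's fixation, plus a diverged neutral
#' control population sampled once (7 individuals). Time is measured in
#' generations since the focal/control split, with roughly four generations
#' per calendar year, so the default sampling generations 176/196/200
#' correspond to field seasons six and one years before the final sample.
#'
#' @param seed Integer seed; the full simulated bundle is a deterministic
#'   function of the configuration including this seed.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_sites_per_chrom Polymorphic sites initialised per chromosome.
#' @param pop_size Diploid population size N (both populations).
#' @param burn_in_generations Neutral generations run before the split to
#'   build up linkage disequilibrium from the linkage-equilibrium start.
#' @param split_generations Generations between the focal/control split and
#'   the final (present-day) sample.
#' @param recomb_rate Crossovers per bp per gamete per generation. The
#'   default is scaled so a toy 1-Mb chromosome carries the map length of a
#'   much longer real one.
#' @param sweep_chrom 1-based index of the chromosome carrying the sweep.
#' @param sweep_pos Target position (bp) of the selected site; the nearest
#'   simulated site is used and recorded in the truth record.
#' @param selection_coeff Additive selection coefficient s; genotype
#'   fitnesses are 1, 1+s, 1+2s.
#' @param sweep_start_gen Generation (since split) at which the sweep allele
#'   arises as a single copy.
#' @param sample_gens Three strictly increasing generations (since split) at
#'   which focal samples are drawn; the last must equal `split_generations`.
#' @param focal_sample_size Diploids sampled per focal time point.
#' @param control_sample_size Diploids sampled from the control population.
#' @param mean_depth Mean simulated read depth for DP/AD fields.
#' @param base_error Per-read allele miscall rate used when splitting AD.
#' @param gene_length_bp Genes are tiled end-to-end at this length.
#' @param deg_fraction Baseline probability that a gene is labelled
#'   differentially expressed.
#' @param deg_odds_ratio Planted odds ratio of DEG membership for genes
#'   overlapping the true sweep window.
#' @param sweep_window_halfwidth Half-width (bp) of the interval around the
#'   sweep site recorded as the expected reduced-diversity window.
#' @param qc_fail_fraction Fraction of sites given a deliberately failing
#'   site-QC annotation so hard filters are exercised.
#' @param x_chromosome Optional 1-based index of a chromosome treated as
#'   hemizygous in males (default none).
#' @param max_sweep_retries Attempts to re-run the sweep phase when the
#'   allele is lost before the first sample generation.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_sites_per_chrom = 200, pop_size = 100)
#' cfg$selection_coeff
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length_bp = 1e6,
                       n_sites_per_chrom = 2000L,
                       pop_size = 1000L,
                       burn_in_generations = 200L,
                       split_generations = 200L,
                       recomb_rate = 1e-7,
                       sweep_chrom = 1L,
                       sweep_pos = 5e5,
                       selection_coeff = 0.5,
                       sweep_start_gen = 160L,
                       sample_gens = c(176L, 196L, 200L),
                       focal_sample_size = 10L,
                       control_sample_size = 7L,
                       mean_depth = 30,
                       base_error = 0.005,
                       gene_length_bp = 1e4,
                       deg_fraction = 0.1,
                       deg_odds_ratio = 1,
                       sweep_window_halfwidth = 5e4,
                       qc_fail_fraction = 0.02,
                       x_chromosome = NA_integer_,
                       max_sweep_retries = 200L) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_sites_per_chrom = as.integer(n_sites_per_chrom),
    pop_size = as.integer(pop_size),
    burn_in_generations = as.integer(burn_in_generations),
    split_generations = as.integer(split_generations),
    recomb_rate = as.numeric(recomb_rate),
    sweep_chrom = as.integer(sweep_chrom),
    sweep_pos = as.numeric(sweep_pos),
    selection_coeff = as.numeric(selection_coeff),
    sweep_start_gen = as.integer(sweep_start_gen),
    sample_gens = as.integer(sample_gens),
    focal_sample_size = as.integer(focal_sample_size),
    control_sample_size = as.integer(control_sample_size),
    mean_depth = as.numeric(mean_depth),
    base_error = as.numeric(base_error),
    gene_length_bp = as.numeric(gene_length_bp),
    deg_fraction = as.numeric(deg_fraction),
    deg_odds_ratio = as.numeric(deg_odds_ratio),
    sweep_window_halfwidth = as.numeric(sweep_window_halfwidth),
    qc_fail_fraction = as.numeric(qc_fail_fraction),
    x_chromosome = as.integer(x_chromosome),
    max_sweep_retries = as.integer(max_sweep_retries)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if <- function(bad, msg) if (isTRUE(bad)) stop("invalid sim_config: ", msg, call. = FALSE)
  stop_if(cfg$selection_coeff < 0, "selection_coeff must be >= 0")
  stop_if(cfg$sweep_pos >= cfg$chrom_length_bp, "sweep_pos must be < chrom_length_bp")
  stop_if(length(cfg$sample_gens) != 3L || any(diff(cfg$sample_gens) <= 0),
          "sample_gens must be three strictly increasing generations")
  stop_if(cfg$sample_gens[3] != cfg$split_generations,
          "last sample generation must equal split_generations")
  stop_if(cfg$sweep_start_gen >= cfg$sample_gens[1],
          "sweep_start_gen must precede the first sample generation")
  stop_if(any(c(cfg$n_chromosomes, cfg$chrom_length_bp, cfg$n_sites_per_chrom,
                cfg$pop_size, cfg$focal_sample_size, cfg$control_sample_size,
                cfg$gene_length_bp, cfg$mean_depth) <= 0),
          "all sizes must be positive")
  stop_if(cfg$pop_size < max(cfg$focal_sample_size, cfg$control_sample_size),
          "pop_size must allow sampling without replacement")
  stop_if(cfg$sweep_chrom < 1L || cfg$sweep_chrom > cfg$n_chromosomes,
          "sweep_chrom out of range")
  stop_if(cfg$recomb_rate < 0, "recomb_rate must be >= 0")
  stop_if(cfg$deg_fraction <= 0 || cfg$deg_fraction >= 1, "deg_fraction must be in (0,1)")
  stop_if(cfg$deg_odds_ratio <= 0, "deg_odds_ratio must be > 0")
  invisible(cfg)
}
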