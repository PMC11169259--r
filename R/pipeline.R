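#' Run the full temporal sweep-scan pipeline on a simulated cohort
#'
#' Orchestrates the stages end to end on a synthetic cohort: simulation,
#' post-calling filters, focal-versus-control scans per time point,
#' temporal differentiation scans with leave-one-out resampling validation,
#' phased-haplotype (iHS / XP-EHH) validation of the pooled candidates,
#' case/control association, and overlap enrichment of candidate gene sets
#' against the simulated DEG lists. Returns every stage result plus a run
#' manifest (configuration snapshot, seed, stage counters) sufficient to
#' reproduce the run.
#'
#' @param sim A [sim_config()].
#' @param scan A [scan_config()].
#' @param stages Character vector of optional stages to run in addition to
#'   the core scan: any of `"resample"`, `"haplostats"`, `"assoc"`,
#'   `"enrich"`.
#' @param out_dir Optional directory; when given, the synthetic bundle and
#'   a JSON manifest are written there.
#' @return List with `cohort`, `vt` (filtered variant table), per-stage
#'   results and `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(), scan = scan_config(),
                         stages = c("resample", "haplostats", "assoc", "enrich"),
                         out_dir = NULL) {
  cohort <- simulate_cohort(sim)
  if (!is.null(out_dir)) write_synthetic_bundle(cohort, out_dir)
  vt <- as_variant_table(cohort)
  n_raw <- nrow(vt$sites)
  vt <- apply_site_hard_filters(vt)
  vt <- apply_depth_missingness_filters(vt, cohort$samples)
  genes <- cohort$genes
  md <- cohort$samples
  chrom_lengths <- setNames(rep(sim$chrom_length_bp, sim$n_chromosomes),
                            paste0("chr", seq_len(sim$n_chromosomes)))
  grp <- function(y) md$sample_id[!is.na(md$year) & md$year == y]
  ctrl <- md$sample_id[md$population == "control"]
  years <- sort(unique(md$year[!is.na(md$year)]))

  selected <- lapply(years, function(y)
    run_comparison(vt, genes, grp(y), ctrl, chrom_lengths, scan,
                   label = paste0("kauai_", y, "_vs_control")))
  names(selected) <- paste0("y", years)
  temporal_pairs <- list(c(years[1], years[2]), c(years[2], years[3]))
  temporal <- lapply(temporal_pairs, function(pr)
    run_comparison(vt, genes, grp(pr[2]), grp(pr[1]), chrom_lengths, scan,
                   label = paste0(pr[1], "_vs_", pr[2])))
  names(temporal) <- vapply(temporal_pairs, paste, "", collapse = "_")

  out <- list(cohort = cohort, vt = vt, selected = selected,
              temporal = temporal)

  if ("resample" %in% stages) {
    out$resampling <- lapply(seq_along(temporal), function(i) {
      pr <- temporal_pairs[[i]]
      rs <- resample_differentiation(vt, genes, grp(pr[2]), grp(pr[1]),
                                     chrom_lengths, scan,
                                     candidates = temporal[[i]]$gene_ids,
                                     label = temporal[[i]]$label)
      c(list(result = rs), threshold_support(rs))
    })
    names(out$resampling) <- names(temporal)
  }

  all_candidates <- unique(c(unlist(lapply(selected, `[[`, "gene_ids")),
                             unlist(lapply(temporal, `[[`, "gene_ids"))))

  if ("haplostats" %in% stages) {
    hm_f <- haplotype_matrix(vt, grp(years[3]))
    hm_c <- haplotype_matrix(vt, ctrl)
    ihs <- ihs_scan(hm_f)
    xp <- tryCatch(xpehh_scan(hm_f, hm_c), error = function(e) NULL)
    grid <- make_windows(chrom_lengths, size = 10000, step = 10000)
    out$haplostats <- flag_windows_and_validate(ihs, xp, grid, genes,
                                                all_candidates)
    out$haplostats$ihs <- ihs
    out$haplostats$xpehh <- xp
  }

  if ("assoc" %in% stages) {
    out$assoc <- fisher_assoc_scan(vt, md)
  }

  if ("enrich" %in% stages) {
    universe <- genes$gene_id
    out$enrichment <- lapply(cohort$deg, function(deg)
      overlap_fisher(all_candidates, intersect(deg, universe), universe))
  }

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("temporalsweep")),
    sim_config = unclass(sim),
    scan_config = unclass(scan)[c("window_size", "step", "top_quantile",
                                  "log_base", "min_snps")],
    stages = stages,
    counters = list(
      sites_raw = n_raw,
      sites_filtered = nrow(vt$sites),
      candidate_genes = length(all_candidates),
      sweep_status = cohort$truth$status
    )
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Exclude genomic intervals from a scan configuration
#'
#' Adds BED intervals (for example a known long-range linkage block such as
#' an X-linked wing-morph region) to a scan configuration; windows and
#' genes intersecting them are excluded from outlier calling, resampling
#' and enrichment universes. Association and LD scans are unaffected.
#'
#' @param config A [scan_config()].
#' @param bed A tibble (`chrom`, `start`, `end`) or path to a BED file
#'   (0-based half-open, as BED is defined).
#' @return The updated `scan_config`.
#' @export
exclude_region <- function(config, bed) {
  if (is.character(bed)) {
    bed <- readr::read_tsv(bed, col_names = c("chrom", "start", "end"),
                           col_types = "cdd", comment = "#")
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (nrow(bed) > 0 && any(bed$end <= bed$start)) stop("malformed intervals")
  config$exclude <- dplyr::bind_rows(config$exclude, bed)
  config
}
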