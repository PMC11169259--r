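#' Write a simulated cohort to an analysis-ready file bundle
#'
#' Serialises a [simulate_cohort()] result as the file set a resequencing
#' pipeline would consume: a multi-sample VCFv4.2 with phased GT, per-call
#' DP/AD and per-site QC annotations (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum), a GFF3 of tiled gene models, a sample-metadata TSV, one
#' DEG list file per simulated expression experiment, and the ground-truth
#' record as JSON. Output is plain text and byte-reproducible from the
#' configuration seed.
#'
#' @param cohort A `sweep_cohort` object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_synthetic_bundle <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sweep_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  paths <- list(
    vcf = file.path(out_dir, "cohort.vcf"),
    gff = file.path(out_dir, "genes.gff3"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_cohort_vcf(cohort, paths$vcf)
  write_gene_gff3(cohort$genes, paths$gff)
  readr::write_tsv(cohort$samples, paths$metadata, na = "NA")
  for (exp in names(cohort$deg)) {
    p <- file.path(out_dir, paste0("deg_", exp, ".txt"))
    writeLines(cohort$deg[[exp]], p)
    paths[[paste0("deg_", exp)]] <- p
  }
  jsonlite::write_json(cohort$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

write_cohort_vcf <- function(cohort, path) {
  s <- cohort$sites
  cfg <- cohort$config
  contigs <- sprintf("##contig=<ID=chr%d,length=%d>",
                     seq_len(cfg$n_chromosomes), as.integer(cfg$chrom_length_bp))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=temporalsweep",
    contigs,
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank-sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  info <- sprintf("QD=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s",
                  fmt_num(s$qd), fmt_num(s$fs), fmt_num(s$mq),
                  fmt_num(s$mq_rank_sum), fmt_num(s$read_pos_rank_sum))
  n_samp <- nrow(cohort$samples)
  a1 <- cohort$hap[, seq(1, 2L * n_samp, by = 2L), drop = FALSE]
  a2 <- cohort$hap[, seq(2, 2L * n_samp, by = 2L), drop = FALSE]
  calls <- matrix(sprintf("%d|%d:%d:%d,%d", a1, a2, cohort$dp,
                          cohort$dp - cohort$ad_alt, cohort$ad_alt),
                  nrow = nrow(cohort$hap))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, fmt_num(s$qual), "PASS",
                info, "GT:DP:AD",
                apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))

write_gene_gff3 <- function(genes, path) {
  lines <- sprintf("%s\ttemporalsweep\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
                   genes$chrom, as.integer(genes$start) + 1L,
                   as.integer(genes$end), genes$strand,
                   genes$gene_id, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
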