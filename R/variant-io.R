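#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCFv4.x file (plain or gzipped, via \pkg{vcfR}) into the
#' package's variant-table container. Only biallelic SNP records are kept;
#' multiallelic and indel records are dropped with a message. Genotypes are
#' stored as alt-allele dosage (0/1/2, `NA` for missing) together with the
#' phased allele pair, per-call DP and AD, and the per-site caller QC
#' annotations (QUAL, QD, FS, MQ, MQRankSum, ReadPosRankSum). Missing
#' annotations are recorded as `NA`, not zero. VCF coordinates stay 1-based
#' here; window and interval operations convert to 0-based half-open
#' internally.
#'
#' @param path Path to a VCF file.
#' @return An object of class `variant_table`: a list with `sites` (tibble),
#'   matrices `gt`, `dp`, `ad_ref`, `ad_alt`, `a1`, `a2`, `phased`, and the
#'   `samples` character vector.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  nuc <- c("A", "C", "G", "T")
  biallelic <- fix$REF %in% nuc & fix$ALT %in% nuc
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    message(n_drop, " non-biallelic-SNP record(s) dropped")
    v <- v[biallelic, ]
    fix <- fix[biallelic, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)

  info_num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key))
  )
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = info_num("QD"),
    fs = info_num("FS"),
    mq = info_num("MQ"),
    mq_rank_sum = info_num("MQRankSum"),
    read_pos_rank_sum = info_num("ReadPosRankSum")
  )
  o <- order(sites$chrom, sites$pos)

  gt_str <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, element = "AD")
  a1 <- suppressWarnings(matrix(as.integer(substr(gt_str, 1, 1)), nrow = nrow(gt_str)))
  a2 <- suppressWarnings(matrix(as.integer(substr(gt_str, 3, 3)), nrow = nrow(gt_str)))
  phased <- !is.na(gt_str) & substr(gt_str, 2, 2) == "|"
  gt <- a1 + a2
  ad_ref <- suppressWarnings(matrix(as.integer(sub(",.*", "", ad)), nrow = nrow(ad)))
  ad_alt <- suppressWarnings(matrix(as.integer(sub(".*,", "", ad)), nrow = nrow(ad)))
  samples <- colnames(gt_str)
  for (m in c("gt", "dp", "ad_ref", "ad_alt", "a1", "a2", "phased")) {
    x <- get(m)
    x <- x[o, , drop = FALSE]
    colnames(x) <- samples
    assign(m, x)
  }
  new_variant_table(sites[o, ], gt, dp, ad_ref, ad_alt, a1, a2, phased, samples)
}

new_variant_table <- function(sites, gt, dp, ad_ref, ad_alt, a1, a2, phased, samples) {
  structure(list(sites = sites, gt = gt, dp = dp, ad_ref = ad_ref,
                 ad_alt = ad_alt, a1 = a1, a2 = a2, phased = phased,
                 samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("<variant_table>", nrow(x$sites), "sites x", length(x$samples), "samples on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Convert a simulated cohort to a variant table
#'
#' In-memory bridge from [simulate_cohort()] output to the container used by
#' the filtering and scan functions, equivalent to writing the bundle and
#' re-reading the VCF.
#'
#' @param cohort A `sweep_cohort` object.
#' @return A `variant_table`.
#' @export
as_variant_table <- function(cohort) {
  stopifnot(inherits(cohort, "sweep_cohort"))
  n <- nrow(cohort$samples)
  a1 <- cohort$hap[, seq(1, 2L * n, by = 2L), drop = FALSE]
  a2 <- cohort$hap[, seq(2, 2L * n, by = 2L), drop = FALSE]
  ids <- cohort$samples$sample_id
  colnames(a1) <- colnames(a2) <- ids
  gt <- a1 + a2
  phased <- matrix(TRUE, nrow(gt), ncol(gt), dimnames = list(NULL, ids))
  ad_ref <- cohort$dp - cohort$ad_alt
  new_variant_table(cohort$sites, gt, cohort$dp, ad_ref, cohort$ad_alt,
                    a1, a2, phased, ids)
}

#' Apply hard site-quality filters
#'
#' Removes sites failing any of the caller-annotation criteria:
#' QD < 2.0, FS > 60.0, MQ < 40.0, MQRankSum < -2.5,
#' ReadPosRankSum < -1.0, or QUAL < 30. Inequalities are strict, so boundary
#' values are retained, and a site missing an annotation passes that
#' criterion (rank-sum annotations are only emitted when computable).
#'
#' @param vt A `variant_table`.
#' @param thresholds Named list overriding any of `qd`, `fs`, `mq`,
#'   `mq_rank_sum`, `read_pos_rank_sum`, `qual`.
#' @return The filtered `variant_table`.
#' @export
apply_site_hard_filters <- function(vt, thresholds = list()) {
  th <- utils::modifyList(
    list(qd = 2.0, fs = 60.0, mq = 40.0, mq_rank_sum = -2.5,
         read_pos_rank_sum = -1.0, qual = 30), thresholds)
  s <- vt$sites
  pass <- function(x, ok) is.na(x) | ok
  keep <- pass(s$qd, s$qd >= th$qd) &
    pass(s$fs, s$fs <= th$fs) &
    pass(s$mq, s$mq >= th$mq) &
    pass(s$mq_rank_sum, s$mq_rank_sum >= th$mq_rank_sum) &
    pass(s$read_pos_rank_sum, s$read_pos_rank_sum >= th$read_pos_rank_sum) &
    pass(s$qual, s$qual >= th$qual)
  subset_variant_table(vt, keep)
}

subset_variant_table <- function(vt, keep) {
  vt$sites <- vt$sites[keep, , drop = FALSE]
  for (m in c("gt", "dp", "ad_ref", "ad_alt", "a1", "a2", "phased"))
    vt[[m]] <- vt[[m]][keep, , drop = FALSE]
  vt
}

#' Apply per-call depth masking and site missingness filters
#'
#' Masks individual calls whose depth is abnormal — below one third or above
#' three times that sample's mean depth — then removes sites where more than
#' `max_missing` of the individuals have unknown genotypes. On a hemizygous
#' X chromosome the depth bounds for male samples are halved, reflecting
#' their single-copy coverage.
#'
#' @param vt A `variant_table`.
#' @param metadata Optional sample metadata tibble (needed for the X rule).
#' @param mean_depth Optional named numeric vector of per-sample mean
#'   depths; computed from the DP matrix when absent.
#' @param x_chrom Optional chromosome name treated as hemizygous in males.
#' @param max_missing Maximum tolerated missing-call fraction per site.
#' @return The filtered `variant_table` with masked calls set to `NA`.
#' @export
apply_depth_missingness_filters <- function(vt, metadata = NULL,
                                            mean_depth = NULL,
                                            x_chrom = NULL,
                                            max_missing = 0.25) {
  if (all(is.na(vt$dp))) {
    warning("DP field absent; depth filter skipped")
  } else {
    if (is.null(mean_depth)) {
      mean_depth <- colMeans(vt$dp, na.rm = TRUE)
    }
    mean_depth <- mean_depth[vt$samples]
    lo <- matrix(mean_depth / 3, nrow(vt$dp), ncol(vt$dp), byrow = TRUE)
    hi <- matrix(mean_depth * 3, nrow(vt$dp), ncol(vt$dp), byrow = TRUE)
    if (!is.null(x_chrom) && !is.null(metadata)) {
      hemi <- vt$samples %in% metadata$sample_id[metadata$sex == "M"]
      on_x <- vt$sites$chrom == x_chrom
      if (any(on_x) && any(hemi)) {
        lo[on_x, hemi] <- lo[on_x, hemi] / 2
        hi[on_x, hemi] <- hi[on_x, hemi] / 2
      }
    }
    mask <- !is.na(vt$dp) & (vt$dp < lo | vt$dp > hi)
    vt$gt[mask] <- NA_integer_
    vt$a1[mask] <- NA_integer_
    vt$a2[mask] <- NA_integer_
  }
  miss_frac <- rowMeans(is.na(vt$gt))
  subset_variant_table(vt, miss_frac <= max_missing)
}

#' Rectify heterozygous calls on a hemizygous X chromosome
#'
#' Male crickets are XO, so true male genotypes on the X are single-copy.
#' Heterozygous male calls on the X are converted to the homozygous state of
#' the allele whose read depth is at least three times the other allele's;
#' when neither allele has such a supermajority the genotype is set to
#' unknown. Female calls and autosomes are untouched.
#'
#' @param vt A `variant_table`.
#' @param metadata Sample metadata with `sample_id` and `sex` columns.
#' @param x_chrom Chromosome name of the X.
#' @return The corrected `variant_table`.
#' @export
correct_hemizygous_genotypes <- function(vt, metadata, x_chrom) {
  male <- vt$samples %in% metadata$sample_id[metadata$sex == "M"]
  on_x <- vt$sites$chrom == x_chrom
  if (!any(male) || !any(on_x)) return(vt)
  het <- !is.na(vt$gt) & vt$gt == 1L
  target <- het & outer(on_x, male, `&`)
  if (!any(target)) return(vt)
  ref_d <- vt$ad_ref
  alt_d <- vt$ad_alt
  no_ad <- target & (is.na(ref_d) | is.na(alt_d))
  if (any(no_ad)) message(sum(no_ad), " het X call(s) lacked AD; set missing")
  to_ref <- target & !no_ad & ref_d >= 3L * alt_d
  to_alt <- target & !no_ad & alt_d >= 3L * ref_d
  unknown <- target & !to_ref & !to_alt
  vt$gt[to_ref] <- 0L; vt$a1[to_ref] <- 0L; vt$a2[to_ref] <- 0L
  vt$gt[to_alt] <- 2L; vt$a1[to_alt] <- 1L; vt$a2[to_alt] <- 1L
  vt$gt[unknown] <- NA_integer_
  vt$a1[unknown] <- NA_integer_
  vt$a2[unknown] <- NA_integer_
  vt
}

#' Read gene models from a GFF3 file
#'
#' Keeps `gene`-type features only and converts the 1-based inclusive GFF
#' coordinates to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_gff_genes <- function(path) {
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0L) {
    warning("no gene features in ", path)
    return(tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character()))
  }
  id <- sub(";.*", "", sub(".*ID=(gene:)?", "", g$attributes))
  if (anyDuplicated(id)) stop("duplicate gene ids in ", path)
  tibble(
    gene_id = id,
    chrom = as.character(g$seqid),
    start = as.numeric(g$start) - 1,
    end = as.numeric(g$end),
    strand = as.character(g$strand)
  )
}

#' Read a sample metadata table
#'
#' @param path Tab-separated file with columns `sample_id`, `population`,
#'   `year`, `phenotype`, `sex`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "population", "year", "phenotype", "sex")
  missing <- setdiff(need, names(md))
  if (length(missing)) stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  md
}

#' Write a variant table back to VCF
#'
#' Serialises the retained sites and calls of a `variant_table` as a plain
#' VCFv4.2 file; genotypes are written phased when the phase flag is set.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(vt, path) {
  s <- vt$sites
  contigs <- vapply(unique(s$chrom), function(cn)
    sprintf("##contig=<ID=%s,length=%d>", cn, max(s$pos[s$chrom == cn]) + 1L), "")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=temporalsweep",
    contigs,
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank-sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  info_field <- function(key, x) ifelse(is.na(x), NA, paste0(key, "=", fmt_num_na(x)))
  info_parts <- cbind(info_field("QD", s$qd), info_field("FS", s$fs),
                      info_field("MQ", s$mq), info_field("MQRankSum", s$mq_rank_sum),
                      info_field("ReadPosRankSum", s$read_pos_rank_sum))
  info <- apply(info_parts, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) paste(r, collapse = ";") else "."
  })
  sep <- ifelse(vt$phased, "|", "/")
  gt_str <- matrix(
    ifelse(is.na(vt$a1) | is.na(vt$a2), "./.",
           paste0(vt$a1, sep, vt$a2)),
    nrow = nrow(vt$gt))
  dp_str <- ifelse(is.na(vt$dp), ".", vt$dp)
  ad_str <- ifelse(is.na(vt$ad_ref) | is.na(vt$ad_alt), ".",
                   paste0(vt$ad_ref, ",", vt$ad_alt))
  calls <- matrix(paste(gt_str, dp_str, ad_str, sep = ":"), nrow = nrow(vt$gt))
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt,
                ifelse(is.na(s$qual), ".", fmt_num_na(s$qual)), "PASS",
                info, "GT:DP:AD",
                apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

fmt_num_na <- function(x) ifelse(is.na(x), ".", sub("\\.?0+$", "", sprintf("%.4f", x)))
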