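make_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ch <- simulate_cohort(small_sim_config(seed = 8))
      dir <- file.path(tempdir(), "io_bundle")
      write_synthetic_bundle(ch, dir)
      cache <<- list(cohort = ch, dir = dir)
    }
    cache
  }
})

test_that("VCF round trip preserves sites, genotypes, depths and annotations", {
  b <- make_bundle()
  vt <- read_vcf(file.path(b$dir, "cohort.vcf"))
  mem <- as_variant_table(b$cohort)
  expect_equal(nrow(vt$sites), nrow(mem$sites))
  expect_equal(vt$sites$pos, mem$sites$pos)
  expect_equal(unname(vt$gt), unname(mem$gt))
  expect_equal(unname(vt$dp), unname(mem$dp))
  expect_equal(unname(vt$ad_alt), unname(mem$ad_alt))
  expect_equal(vt$sites$qd, mem$sites$qd, tolerance = 1e-6)
  expect_true(all(vt$phased))
  # writing the parsed table back out and re-reading is idempotent
  p2 <- file.path(tempdir(), "rt.vcf")
  write_variant_vcf(vt, p2)
  vt2 <- read_vcf(p2)
  expect_equal(vt2$sites, vt$sites, tolerance = 1e-6)
  expect_equal(unname(vt2$gt), unname(vt$gt))
})

test_that("genotype encodings map to dosage and phase", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB\tC",
    "chr1\t10\t.\tA\tT\t50\tPASS\t.\tGT\t0|1\t1|1\t./.",
    "chr1\t20\t.\tC\tG\t50\tPASS\t.\tGT\t0/0\t0|0\t1|0",
    "chr1\t30\t.\tG\tGA\t50\tPASS\t.\tGT\t0|0\t0|0\t0|0", # indel: dropped
    "chr1\t40\t.\tT\tA,C\t50\tPASS\t.\tGT\t0|0\t0|0\t0|0" # multiallelic: dropped
  )
  p <- tempfile(fileext = ".vcf")
  writeLines(lines, p)
  expect_message(vt <- read_vcf(p), "dropped")
  expect_equal(nrow(vt$sites), 2)
  expect_equal(unname(vt$gt[1, ]), c(1L, 2L, NA))
  expect_true(vt$phased[1, "A"])
  expect_false(vt$phased[2, "A"])
  expect_true(is.na(vt$sites$qd[1])) # absent annotation recorded as NA
})

test_that("hard filters apply the documented criteria with strict bounds", {
  gt <- random_gt(10, 4, miss = 0)
  vt <- toy_variant_table(gt, pos = seq(100, 1000, by = 100))
  vt$sites$qd[1] <- 1.9             # fails QD < 2
  vt$sites$fs[2] <- 60.0            # boundary: retained
  vt$sites$mq[3] <- 39.9            # fails MQ < 40
  vt$sites$read_pos_rank_sum[4] <- -1.2 # fails
  vt$sites$mq_rank_sum[5] <- NA     # missing: passes
  out <- apply_site_hard_filters(vt)
  expect_equal(nrow(out$sites), 7)
  expect_false(100 %in% out$sites$pos)
  expect_true(200 %in% out$sites$pos)
  expect_false(300 %in% out$sites$pos)
  expect_false(400 %in% out$sites$pos)
  expect_true(500 %in% out$sites$pos)

  # brute-force re-check of each rule on a random annotation table
  set.seed(42)
  vt2 <- toy_variant_table(random_gt(50, 3, 0), pos = seq_len(50) * 10)
  vt2$sites$qd <- runif(50, 0, 5)
  vt2$sites$fs <- runif(50, 0, 100)
  vt2$sites$mq <- runif(50, 20, 60)
  vt2$sites$mq_rank_sum <- runif(50, -4, 1)
  vt2$sites$read_pos_rank_sum <- runif(50, -2, 1)
  vt2$sites$qual <- runif(50, 0, 100)
  out2 <- apply_site_hard_filters(vt2)
  manual <- with(vt2$sites, !(qd < 2 | fs > 60 | mq < 40 | mq_rank_sum < -2.5 |
                                read_pos_rank_sum < -1 | qual < 30))
  expect_equal(out2$sites$pos, vt2$sites$pos[manual])
})

test_that("depth masking and the missingness filter follow the stated rules", {
  gt <- matrix(1L, nrow = 2, ncol = 8)
  vt <- toy_variant_table(gt, pos = c(100, 200))
  vt$dp[] <- 30L
  vt$dp[1, 1:3] <- c(9L, 9L, 9L)  # 9 < 30/3: masked; 3/8 = 37.5% missing
  vt$dp[2, 1] <- 10L              # 10 is not < 10: retained
  out <- apply_depth_missingness_filters(vt, mean_depth = setNames(rep(30, 8), vt$samples))
  expect_equal(out$sites$pos, 200)
  expect_equal(sum(is.na(out$gt)), 0)

  # hemizygous X: bounds halved, DP = 7 within (5, 45)
  md <- tibble::tibble(sample_id = vt$samples, sex = "M")
  vtx <- toy_variant_table(gt, pos = c(100, 200), chrom = "chrX")
  vtx$dp[] <- 30L
  vtx$dp[1, 1] <- 7L
  outx <- apply_depth_missingness_filters(vtx, metadata = md,
                                          mean_depth = setNames(rep(30, 8), vtx$samples),
                                          x_chrom = "chrX")
  expect_equal(nrow(outx$sites), 2)
  expect_false(is.na(outx$gt[1, 1]))
})

test_that("hemizygous genotype correction needs an allele-depth supermajority", {
  gt <- matrix(1L, nrow = 3, ncol = 2)
  vt <- toy_variant_table(gt, pos = c(10, 20, 30), chrom = "chrX")
  vt$ad_ref[] <- 5L; vt$ad_alt[] <- 4L
  vt$ad_ref[1, 1] <- 9L; vt$ad_alt[1, 1] <- 3L   # 9 >= 3*3: -> ref hom
  vt$ad_ref[2, 1] <- 2L; vt$ad_alt[2, 1] <- 11L  # -> alt hom
  md <- tibble::tibble(sample_id = vt$samples, sex = c("M", "F"))
  out <- correct_hemizygous_genotypes(vt, md, "chrX")
  expect_equal(unname(out$gt[1, 1]), 0L)
  expect_equal(unname(out$gt[2, 1]), 2L)
  expect_true(is.na(out$gt[3, 1]))   # 5 vs 4: no supermajority -> unknown
  expect_equal(unname(out$gt[, 2]), c(1L, 1L, 1L)) # female untouched
  # non-X chromosome untouched
  vt2 <- toy_variant_table(gt, pos = c(10, 20, 30), chrom = "chr2")
  out2 <- correct_hemizygous_genotypes(vt2, md, "chrX")
  expect_equal(out2$gt, vt2$gt)
})

test_that("GFF gene reading converts coordinates and filters features", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=gene:gA;Name=gA",
    "chr1\tsrc\tmRNA\t1\t100\t.\t+\t.\tID=tA;Parent=gA",
    "chr1\tsrc\tgene\t201\t300\t.\t-\t.\tID=gene:gB;Name=gB",
    "chr1\tsrc\tmRNA\t201\t250\t.\t-\t.\tID=tB;Parent=gB",
    "chr1\tsrc\tmRNA\t251\t300\t.\t-\t.\tID=tC;Parent=gB"
  ), p)
  g <- read_gff_genes(p)
  expect_equal(nrow(g), 2)
  expect_equal(g$start, c(0, 200))
  expect_equal(g$end, c(100, 300))
  empty <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  expect_warning(g0 <- read_gff_genes(empty), "no gene")
  expect_equal(nrow(g0), 0)
})

test_that("bundle GFF and metadata read back consistently", {
  b <- make_bundle()
  g <- read_gff_genes(file.path(b$dir, "genes.gff3"))
  expect_equal(g$gene_id, b$cohort$genes$gene_id)
  expect_equal(g$start, b$cohort$genes$start)
  expect_equal(g$end, b$cohort$genes$end)
  md <- read_sample_metadata(file.path(b$dir, "metadata.tsv"))
  expect_equal(md$sample_id, b$cohort$samples$sample_id)
  suppressWarnings(expect_error(read_sample_metadata(file.path(b$dir, "genes.gff3"))))
})
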