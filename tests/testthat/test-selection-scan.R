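toy_stats <- function(fst, ratio, chrom = "chr1", start = NULL) {
  n <- length(fst)
  if (is.null(start)) start <- seq(0, by = 10000, length.out = n)
  tibble::tibble(chrom = chrom, start = start, end = start + 10000,
                 n_snps = 10L, pi_focal = 1e-4, pi_control = 1e-4,
                 fst = fst, pi_log_ratio = ratio, usable = TRUE)
}

test_that("diversity log-ratio handles identities, scaling and zeros", {
  expect_equal(pi_log_ratio(2e-4, 2e-4), 0)
  expect_equal(pi_log_ratio(4e-4, 1e-4), 2)
  expect_equal(pi_log_ratio(8, 1, log_base = 10), log10(8))
  expect_identical(pi_log_ratio(1e-4, 0), Inf)
  expect_true(is.na(pi_log_ratio(0, 0)))
})

test_that("zero-denominator windows rank above every finite ratio", {
  set.seed(1)
  st <- toy_stats(runif(500), c(rnorm(499), Inf))
  st$fst[500] <- 0.99
  out <- call_outlier_windows(st)
  expect_true(st$start[500] %in% out$start)
})

test_that("joint outlier count matches the independence expectation", {
  set.seed(33)
  counts <- vapply(1:200, function(i) {
    st <- toy_stats(runif(1000), runif(1000))
    nrow(call_outlier_windows(st))
  }, numeric(1))
  # expectation 1000 * 0.05 * 0.05 = 2.5 with inclusive-threshold ties
  # adding ~1 window per statistic (the threshold value itself)
  expect_gt(mean(counts), 1.5)
  expect_lt(mean(counts), 4.5)
})

test_that("a window ranked first on both statistics is always selected", {
  set.seed(9)
  for (i in 1:10) {
    st <- toy_stats(runif(600), runif(600))
    st$fst[17] <- 2; st$pi_log_ratio[17] <- 99
    expect_true(st$start[17] %in% call_outlier_windows(st)$start)
  }
})

test_that("degenerate all-equal statistics select every window", {
  st <- toy_stats(rep(0.3, 500), rep(1.2, 500))
  expect_equal(nrow(call_outlier_windows(st)), 500)
})

test_that("outlier calling is invariant to the ratio's log base", {
  set.seed(14)
  st2 <- toy_stats(runif(800), exp(rnorm(800)))
  st10 <- st2
  st2$pi_log_ratio <- log2(st10$pi_log_ratio)
  st10$pi_log_ratio <- log10(exp(log(2) * st2$pi_log_ratio))
  o2 <- call_outlier_windows(st2)
  o10 <- call_outlier_windows(st10)
  expect_equal(o2$start, o10$start)
})

test_that("region merging joins overlapping and book-ended windows only", {
  w <- tibble::tibble(chrom = "chr1",
                      start = c(0, 7500, 12500),
                      end = c(10000, 17500, 22500))
  r <- merge_regions(w)
  expect_equal(nrow(r), 1) # 0-10000 overlaps 7500-17500 overlaps? 12500<17500 yes
  w2 <- tibble::tibble(chrom = "chr1", start = c(0, 10000), end = c(10000, 20000))
  r2 <- merge_regions(w2)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(0, 20000))
  w3 <- tibble::tibble(chrom = "chr1", start = c(0, 12500), end = c(10000, 22500))
  expect_equal(nrow(merge_regions(w3)), 2)
})

test_that("region merging is idempotent and order-invariant", {
  set.seed(4)
  for (i in 1:10) {
    start <- sample.int(20, 12) * 2500
    w <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 12, TRUE),
                        start = start, end = start + 10000)
    r1 <- merge_regions(w)
    r2 <- merge_regions(w[sample.int(12), ])
    expect_equal(r1[c("chrom", "start", "end")], r2[c("chrom", "start", "end")])
    again <- merge_regions(r1)
    expect_equal(again[c("chrom", "start", "end")], r1[c("chrom", "start", "end")])
  }
})

test_that("gene overlap uses half-open intersection with provenance", {
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "chr1",
                          start = c(5, 0), end = c(15, 10), strand = "+")
  regions <- tibble::tibble(chrom = "chr1", start = 10, end = 20)
  hit <- genes_in_regions(regions, genes)
  expect_equal(hit$gene_id, "a") # 5 bp overlap; gene b only touches
  # tiled genes: one region spanning exactly 3
  tiles <- tibble::tibble(gene_id = sprintf("g%03d", 1:100), chrom = "chr1",
                          start = (0:99) * 1000, end = (1:100) * 1000,
                          strand = "+")
  r <- tibble::tibble(chrom = "chr1", start = 10500, end = 13000)
  got <- sort(unique(genes_in_regions(r, tiles)$gene_id))
  brute <- tiles$gene_id[vapply(seq_len(100), function(i)
    max(tiles$start[i], r$start) < min(tiles$end[i], r$end), logical(1))]
  expect_equal(got, sort(brute))
  expect_length(got, 3)
  expect_error(genes_in_regions(tibble::tibble(chrom = "chrZ", start = 0, end = 10),
                                tiles), "chromosome names")
})

test_that("run_comparison refuses overlapping or tiny groups", {
  ch <- simulate_cohort(small_sim_config(seed = 13))
  vt <- as_variant_table(ch)
  s <- ch$samples$sample_id
  expect_error(run_comparison(vt, ch$genes, s[1:5], s[3:8]), "disjoint")
  expect_error(run_comparison(vt, ch$genes, s[1], s[2:8]), "at least 2")
})

test_that("planted-sweep recovery improves with selection strength", {
  rate <- vapply(c(0, 0.5), function(s_coef) {
    hits <- vapply(1:10, function(i) {
      ch <- simulate_cohort(small_sim_config(seed = 4000 + i,
                                             selection_coeff = s_coef))
      vt <- as_variant_table(ch)
      md <- ch$samples
      foc <- md$sample_id[!is.na(md$year) & md$year == 2018]
      ctl <- md$sample_id[md$population == "control"]
      cmp <- run_comparison(vt, ch$genes, foc, ctl,
                            c(chr1 = 1e6, chr2 = 1e6),
                            scan_config(window_size = 10000, step = 2500))
      tw <- ch$truth$true_sweep_window
      any(cmp$regions$chrom == ch$truth$sweep_chrom &
            cmp$regions$start < tw[2] & cmp$regions$end > tw[1])
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gte(rate[2], rate[1])
  expect_gte(rate[2], 0.7)
})

test_that("window exclusion removes the excluded span from scan and genes", {
  ch <- simulate_cohort(small_sim_config(seed = 21))
  vt <- as_variant_table(ch)
  md <- ch$samples
  foc <- md$sample_id[!is.na(md$year) & md$year == 2018]
  ctl <- md$sample_id[md$population == "control"]
  cl <- c(chr1 = 1e6, chr2 = 1e6)
  excl <- tibble::tibble(chrom = "chr1",
                         start = ch$truth$true_sweep_window[1],
                         end = ch$truth$true_sweep_window[2])
  cfg <- exclude_region(scan_config(), excl)
  cmp <- run_comparison(vt, ch$genes, foc, ctl, cl, cfg)
  expect_false(any(cmp$regions$chrom == "chr1" &
                     cmp$regions$start < excl$end &
                     cmp$regions$end > excl$start))
  # thresholds recomputed on the remainder: all retained windows outside
  expect_false(any(cmp$stats$chrom == "chr1" &
                     cmp$stats$start < excl$end & cmp$stats$end > excl$start))
})
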