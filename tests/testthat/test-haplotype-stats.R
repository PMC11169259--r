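toy_hm <- function(hap, pos = NULL, chrom = NULL) {
  if (is.null(pos)) pos <- seq_len(ncol(hap)) * 1000
  if (is.null(chrom)) chrom <- rep("chr1", ncol(hap))
  structure(list(hap = hap, chrom = chrom, pos = pos,
                 sample_of_origin = rep(sprintf("S%d", seq_len(nrow(hap) / 2)),
                                        each = 2)),
            class = "haplotype_matrix")
}

random_hm <- function(n_hap, n_sites) {
  hap <- matrix(rbinom(n_hap * n_sites, 1, runif(n_sites, 0.2, 0.8)),
                nrow = n_hap, byrow = FALSE)
  toy_hm(hap, pos = sort(sample.int(n_sites * 2000, n_sites)))
}

test_that("EHH is 1 at the core and for identical carriers, and splits correctly", {
  hap <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1),
               c(0, 0, 0), c(0, 0, 0))
  hm <- toy_hm(hap)
  e <- ehh_curve(hm, 1, 1, "right")
  expect_equal(e$ehh[1], 1)
  expect_equal(e$distance_bp[1], 0)
  # 4 carriers split 2+2 at the first flanking SNP: (1+1)/C(4,2) = 1/3
  expect_equal(e$ehh[2], 1 / 3)
  # identical carriers stay at 1
  hm2 <- toy_hm(matrix(rep(c(1, 0, 1, 1), 4), nrow = 4, byrow = TRUE))
  e2 <- ehh_curve(hm2, 1, 1, "right")
  expect_true(all(e2$ehh == 1))
  expect_error(ehh_curve(toy_hm(rbind(c(1, 0), c(0, 0), c(0, 0))), 1, 1),
               "fewer than 2")
})

test_that("EHH curves are non-increasing away from the core", {
  set.seed(55)
  for (i in 1:10) {
    hm <- random_hm(12, 25)
    core <- sample(5:20, 1)
    al <- sample(0:1, 1)
    if (sum(hm$hap[, core] == al) < 2) next
    e <- ehh_curve(hm, core, al, sample(c("left", "right"), 1))
    expect_true(all(diff(e$ehh) <= 1e-12))
  }
})

test_that("EHH matches brute-force haplotype-string grouping", {
  set.seed(66)
  for (i in 1:15) {
    hm <- random_hm(sample(6:16, 1), sample(10:40, 1))
    core <- sample(3:(ncol(hm$hap) - 2), 1)
    al <- sample(0:1, 1)
    if (sum(hm$hap[, core] == al) < 2) next
    e <- ehh_curve(hm, core, al, "right")
    for (k in seq_len(min(5, nrow(e) - 1))) {
      expect_equal(e$ehh[k + 1],
                   oracle_ehh(hm$hap, hm$pos, core, al, core + k),
                   tolerance = 1e-12)
    }
  }
})

test_that("iHH integrates the step curve and scales linearly with distance", {
  # two carriers identical over 4 flanking markers, then distinct:
  # EHH = 1 out to 4000 bp, 0 at 5000 bp, so the hand-computed integral is
  # 4000 + 1000 * (1 + 0)/2 = 4500
  hap <- rbind(c(1, 1, 1, 1, 1, 1),
               c(1, 1, 1, 1, 1, 0),
               c(0, 0, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0))
  pos <- seq(1000, 6000, by = 1000)
  hm <- toy_hm(hap, pos = pos)
  r <- ihh(hm, 1, 1)
  expect_equal(r$ihh, 4500)
  # degenerate cutoff: no integration
  expect_equal(ihh(hm, 1, 1, cutoff = 1)$ihh, 0)
  # doubling inter-marker distances doubles the integral
  hm2 <- toy_hm(hap, pos = pos * 2)
  expect_equal(ihh(hm2, 1, 1)$ihh, 2 * r$ihh)
})

test_that("iHH agrees with explicit trapezoid integration on random matrices", {
  set.seed(77)
  for (i in 1:15) {
    hm <- random_hm(sample(8:16, 1), sample(15:40, 1))
    core <- sample(5:(ncol(hm$hap) - 5), 1)
    al <- sample(0:1, 1)
    if (sum(hm$hap[, core] == al) < 2) next
    got <- ihh(hm, core, al, max_gap_bp = 1e9, max_extend_bp = 1e9)
    want <- oracle_ihh(hm$hap, hm$pos, core, al)
    expect_equal(got$ihh, want, tolerance = 1e-9)
  }
})

test_that("iHS is antisymmetric under polarity swap and ~0 for mirror classes", {
  set.seed(88)
  hm <- random_hm(16, 60)
  t_ref <- ihs_scan(hm, "ref_ancestral", max_gap_bp = 1e9, drop_truncated = FALSE)
  t_alt <- ihs_scan(hm, "alt_ancestral", max_gap_bp = 1e9, drop_truncated = FALSE)
  shared <- intersect(t_ref$pos, t_alt$pos)
  expect_gt(length(shared), 10)
  expect_equal(t_ref$raw[match(shared, t_ref$pos)],
               -t_alt$raw[match(shared, t_alt$pos)], tolerance = 1e-9)

  # mirror-image haplotype structure about the core: raw iHS = 0
  blk <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 1), c(1, 1, 1))
  hap <- cbind(blk[, 1:2], c(0, 0, 1, 1), blk[, 2:3])
  hm2 <- toy_hm(hap)
  r <- ihh(hm2, 3, 1)$ihh - ihh(hm2, 3, 0)$ihh
  expect_equal(r, 0, tolerance = 1e-9)
})

test_that("normalised iHS has mean ~0 and unit spread pooled over bins", {
  ch <- simulate_cohort(small_sim_config(seed = 23))
  vt <- as_variant_table(ch)
  foc <- ch$samples$sample_id[ch$samples$population == "focal"]
  hm <- haplotype_matrix(vt, foc)
  tr <- ihs_scan(hm)
  expect_lt(abs(mean(tr$norm)), 0.05)
  expect_lt(abs(sd(tr$norm) - 1), 0.1)
})

test_that("XP-EHH is 0 for identical populations and antisymmetric on swap", {
  set.seed(99)
  hm <- random_hm(14, 50)
  t0 <- xpehh_scan(hm, hm, max_gap_bp = 1e9, drop_truncated = FALSE)
  expect_true(all(abs(t0$raw) < 1e-12))
  hm2 <- random_hm(14, 50)
  hm2$pos <- hm$pos; hm2$chrom <- hm$chrom
  a <- xpehh_scan(hm, hm2, max_gap_bp = 1e9, drop_truncated = FALSE)
  b <- xpehh_scan(hm2, hm, max_gap_bp = 1e9, drop_truncated = FALSE)
  expect_equal(a$raw, -b$raw, tolerance = 1e-9)
})

test_that("haplotype statistics flag sweeps and validate overlapping genes", {
  ch <- simulate_cohort(small_sim_config(seed = 25))
  vt <- as_variant_table(ch)
  md <- ch$samples
  foc <- md$sample_id[md$population == "focal"]
  ctl <- md$sample_id[md$population == "control"]
  hm_f <- haplotype_matrix(vt, foc)
  hm_c <- haplotype_matrix(vt, ctl)
  xp <- xpehh_scan(hm_f, hm_c)
  tw <- ch$truth$true_sweep_window
  in_sweep <- xp$chrom == ch$truth$sweep_chrom &
    xp$pos - 1 >= tw[1] & xp$pos - 1 < tw[2]
  if (any(in_sweep)) expect_gt(mean(xp$norm[in_sweep]), 0)
  grid <- make_windows(c(chr1 = 1e6, chr2 = 1e6), 1e4, 1e4)
  ihs <- ihs_scan(hm_f)
  rep <- flag_windows_and_validate(ihs, xp, grid, ch$genes,
                                   candidate_ids = ch$genes$gene_id[1:20])
  expect_true(rep$validated_pct >= 0 && rep$validated_pct <= 100)
  expect_equal(nrow(rep$validation), 20)
  # a gene overlapping a flagged window is validated; one on a chromosome
  # with no flags is not
  if (nrow(rep$flagged_windows)) {
    fw <- rep$flagged_windows[1, ]
    g_in <- ch$genes[ch$genes$chrom == fw$chrom &
                       ch$genes$start < fw$end & ch$genes$end > fw$start, ]
    rep2 <- flag_windows_and_validate(ihs, xp, grid, ch$genes,
                                      candidate_ids = g_in$gene_id[1])
    expect_true(all(rep2$validation$validated))
  }
})

test_that("unphased heterozygous input is refused", {
  gt <- random_gt(10, 4, miss = 0)
  vt <- toy_variant_table(gt, pos = seq(100, 1000, 100))
  vt$phased[] <- FALSE
  if (!any(vt$gt == 1)) vt$gt[1, 1] <- 1L
  expect_error(haplotype_matrix(vt), "phased")
})
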