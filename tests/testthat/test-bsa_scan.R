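test_that("variant filtering applies the strict depth and parent rules", {
  tab <- toy_variants(
    bulkA_ref = c(3, 3, 2, 10, 10),
    bulkA_alt = c(3, 2, 2, 10, 10),
    bulkB_ref = c(3, 3, 3, 10, 10),
    bulkB_alt = c(3, 3, 3, 10, 10),
    parent1_gt = c("1/1", "1/1", "1/1", "0/0", "0/1"),
    parent2_gt = c("0/0", "0/0", "0/0", "0/0", "0/0"))
  out <- suppressMessages(filter_variants(tab, filter_config()))
  # row 1: depths (6,6), informative parents -> retained
  # row 2: bulk A total = 5 -> removed (strictly > 5)
  # row 3: total 4 -> removed
  # row 4: parents both 0/0 -> uninformative
  # row 5: het parent -> uninformative
  expect_equal(out$pos, 1000L)
  # without the parent rule rows 1, 4, 5 survive on depth alone
  out2 <- suppressMessages(filter_variants(
    tab, filter_config(require_parent_informative = FALSE)))
  expect_equal(out2$pos, c(1000L, 4000L, 5000L))
  # nothing passing is fine
  expect_equal(nrow(suppressMessages(
    filter_variants(tab, filter_config(min_depth = 1000)))), 0L)
})

test_that("SNP-index and delta obey their definitions and bounds", {
  tab <- toy_variants(bulkA_ref = c(10, 0, 0), bulkA_alt = c(0, 10, 30),
                      bulkB_ref = c(0, 10, 20), bulkB_alt = c(10, 0, 10))
  tr <- compute_index(tab)
  expect_equal(tr$index_A, c(0, 1, 1))
  expect_equal(tr$index_B, c(1, 0, 1 / 3))
  expect_equal(tr$delta, c(-1, 1, 2 / 3))
  expect_true(all(tr$index_A >= 0 & tr$index_A <= 1))
  expect_true(all(abs(tr$delta) <= 1))
  bad <- toy_variants(bulkA_ref = 0, bulkA_alt = 0,
                      bulkB_ref = 5, bulkB_alt = 5)
  expect_error(compute_index(bad), "zero-total-depth")
})

test_that("window means and LOESS track behave on crafted inputs", {
  # one variant alone in its windows
  t1 <- toy_variants(bulkA_ref = 6, bulkA_alt = 4,
                     bulkB_ref = 10, bulkB_alt = 0, pos = 50000)
  tr1 <- compute_index(t1)
  p1 <- window_scan(tr1, scan_config(min_variants = 1),
                    chrom_lengths = c(chr1 = 1e5))
  expect_true(all(abs(p1$mean_delta[p1$n_variants > 0] - 0.4) < 1e-12))

  # two variants in one window average their deltas: 0.2, 0.4 -> 0.3
  t2 <- toy_variants(bulkA_ref = c(8, 6), bulkA_alt = c(2, 4),
                     bulkB_ref = c(10, 10), bulkB_alt = c(0, 0),
                     pos = c(49000, 51000))
  tr2 <- compute_index(t2)
  p2 <- window_scan(tr2, scan_config(min_variants = 2),
                    chrom_lengths = c(chr1 = 3e5))
  expect_true(all(abs(p2$mean_delta[!is.na(p2$mean_delta)] - 0.3) < 1e-12))
  # sparse windows are missing, not zero
  expect_true(anyNA(p2$mean_delta))
  expect_false(any(p2$mean_delta == 0, na.rm = TRUE))

  # constant delta: the smoother reproduces constants
  pos <- seq(10000, 990000, by = 10000)
  t3 <- toy_variants(bulkA_ref = rep(5L, length(pos)),
                     bulkA_alt = rep(5L, length(pos)),
                     bulkB_ref = rep(10L, length(pos)),
                     bulkB_alt = rep(0L, length(pos)), pos = pos)
  p3 <- window_scan(compute_index(t3), scan_config(min_variants = 1),
                    chrom_lengths = c(chr1 = 1e6))
  expect_true(all(abs(p3$smoothed[!is.na(p3$smoothed)] - 0.5) < 1e-6))
})

test_that("null threshold decreases with depth and vanishes as depth grows", {
  pos <- seq(1e5, 3e6, by = 1e5)   # far apart: one variant per window
  mk <- function(depth) {
    tab <- toy_variants(bulkA_ref = rep(depth, length(pos)),
                        bulkA_alt = rep(0L, length(pos)),
                        bulkB_ref = rep(depth, length(pos)),
                        bulkB_alt = rep(0L, length(pos)), pos = pos)
    compute_index(tab)
  }
  scfg <- scan_config(min_variants = 1)
  tcfg <- threshold_config(null_reps = 4000, seed = 99)
  thr_at <- function(depth) {
    tr <- mk(depth)
    pr <- window_scan(tr, scfg, chrom_lengths = c(chr1 = 3e6))
    out <- null_threshold(tr, pr, tcfg, scfg)
    out$threshold_raw[!is.na(out$threshold_raw)]
  }
  t10 <- thr_at(10L); t100 <- thr_at(100L); t2000 <- thr_at(2000L)
  expect_true(all(t100 < t10))
  expect_lt(mean(t2000), 0.05)   # depth -> infinity limit: threshold -> 0
  expect_warning(threshold_config(null_reps = 50), "unstable")
})

test_that("region calling finds runs, merges single missing gaps, respects sign", {
  prof <- data.table(
    chrom = "chr1",
    center = seq(5e4, 1e6 - 5e4, by = 1e4))
  prof[, `:=`(start = center - 5e4, end = center + 5e4,
              n_variants = 5L, mean_delta = 0)]
  prof[, smoothed := 0.05]
  prof[, threshold := 0.2]
  # nothing above threshold: no regions
  expect_equal(nrow(call_regions(prof)), 0L)

  # a positive peak, a one-window missing gap inside it, and a negative peak
  p2 <- copy(prof)
  p2[10:20, smoothed := 0.5]
  p2[15, smoothed := NA]                  # single missing window: merged
  p2[40:45, smoothed := -0.6]             # negative peaks are called too
  regs <- call_regions(p2, method = "SNP-index")
  expect_equal(nrow(regs), 2L)
  expect_equal(regs$sign, c(1, -1))
  expect_equal(regs$start[1], p2$start[10])
  expect_equal(regs$end[1], p2$end[20])
  expect_equal(regs$method, rep("SNP-index", 2))

  # a two-window missing gap is NOT merged
  p3 <- copy(prof)
  p3[10:20, smoothed := 0.5]
  p3[14:15, smoothed := NA]
  expect_equal(nrow(call_regions(p3)), 2L)

  # a below-threshold (non-missing) separator is never merged across
  p4 <- copy(prof)
  p4[10:12, smoothed := 0.5]
  p4[13, smoothed := 0.05]
  p4[14:16, smoothed := 0.5]
  expect_equal(nrow(call_regions(p4)), 2L)
})

test_that("scan output is invariant to input row order", {
  map <- genome_map(c(A01 = 2e6, A02 = 2e6), marker_spacing = 20000,
                    indel_fraction = 0.2)
  trait <- trait_model("A01", 1e6)
  des <- bulk_design(mean_depth = 40, seed = 17)
  g <- simulate_f2_genotypes(map, 323, trait, seed = 17)
  b <- assign_bulks(g, trait, des)
  vt <- simulate_bulk_depths(g, b, des)
  lens <- c(A01 = 2e6, A02 = 2e6)
  args <- list(scan_cfg = scan_config(),
               thr_cfg = threshold_config(null_reps = 500, seed = 17),
               chrom_lengths = lens)
  r1 <- suppressMessages(do.call(bsa_scan, c(list(vt), args)))
  shuffled <- vt[withr::with_seed(1, sample(nrow(vt)))]
  r2 <- suppressMessages(do.call(bsa_scan, c(list(shuffled), args)))
  expect_identical(r1$regions, r2$regions)
  expect_identical(r1$profiles, r2$profiles)
})
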