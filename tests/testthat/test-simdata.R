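test_that("gamete construction honours the Haldane map", {
  # markers at identical positions: distance 0 => r = 0 => always identical
  map <- genome_map(c(chr1 = 1e6), marker_positions = list(chr1 = c(5e5, 5e5)))
  g <- simulate_f2_genotypes(map, 500, seed = 11)
  expect_identical(g$geno[, 1], g$geno[, 2])

  # markers on different chromosomes segregate independently
  map2 <- genome_map(c(chr1 = 1e6, chr2 = 1e6),
                     marker_positions = list(chr1 = 5e5, chr2 = 5e5))
  g2 <- simulate_f2_genotypes(map2, 10000, seed = 12)
  expect_lt(abs(cor(g2$geno[, 1], g2$geno[, 2])), 0.05)

  # pooled heading-parent allele frequency ~ 1/2 at every marker
  map3 <- tiny_map(spacing = 2e5)
  g3 <- simulate_f2_genotypes(map3, 10000, seed = 13)
  freqs <- colMeans(g3$geno) / 2
  expect_true(all(abs(freqs - 0.5) < 0.02))
})

test_that("F2 marginal genotype frequencies are 1:2:1", {
  g <- simulate_f2_genotypes(tiny_map(spacing = 2e5), 10000, seed = 21)
  for (j in seq_len(ncol(g$geno))) {
    tab <- tabulate(g$geno[, j] + 1L, nbins = 3)
    expect_gt(chisq.test(tab, p = c(1, 2, 1) / 4)$p.value, 0.001)
  }
})

test_that("causal position must be a marker", {
  map <- tiny_map()
  expect_error(simulate_f2_genotypes(map, 10, trait_model("chr1", 12345)),
               "not a marker")
  g <- simulate_f2_genotypes(map, 400, seed = 1)
  expect_error(assign_bulks(g, trait_model("chr1", 12345), bulk_design()),
               "not a marker")
})

test_that("bulk assignment reflects mode and penetrance", {
  map <- tiny_map()
  trait <- trait_model("chr1", 5e5, mode = "recessive", penetrance = 1)
  g <- simulate_f2_genotypes(map, 4000, trait, seed = 31)
  des <- bulk_design(n_per_bulk = 400, seed = 31)
  bulks <- assign_bulks(g, trait, des)
  ci <- which(g$markers$chrom == "chr1" & g$markers$pos == 5e5)
  # full-penetrance recessive: heading bulk is homozygous at the causal marker
  expect_true(all(g$geno[bulks$head, ci] == 2L))
  # conditional F2 enumeration: E[freq] = 1 in heading bulk, 1/3 in the other
  fA <- mean(g$geno[bulks$head, ci]) / 2
  fB <- mean(g$geno[bulks$nonhead, ci]) / 2
  expect_equal(fA, 1)
  expect_lt(abs(fB - 1 / 3), 0.05)

  # penetrance 0.5: phenotype independent of genotype, both bulks near 1/2
  trait5 <- trait_model("chr1", 5e5, penetrance = 0.5)
  bulks5 <- assign_bulks(g, trait5, des, seed = 32)
  fA5 <- mean(g$geno[bulks5$head, ci]) / 2
  fB5 <- mean(g$geno[bulks5$nonhead, ci]) / 2
  expect_lt(abs(fA5 - 0.5), abs(fA - 0.5))
  expect_lt(abs(fB5 - 0.5), 0.1)
  expect_lt(abs(fA5 - 0.5), 0.1)

  # insufficient phenotype class errors with counts
  expect_error(
    assign_bulks(simulate_f2_genotypes(map, 60, trait, seed = 33),
                 trait, bulk_design(n_per_bulk = 50)),
    "not enough individuals")
})

test_that("pooled depth simulation follows the binomial sampling model", {
  map <- genome_map(c(chr1 = 1e7), marker_spacing = 1000,
                    indel_fraction = 0)              # 10000 sites
  geno <- simulate_f2_genotypes(map, 60, seed = 41)
  bulks <- list(head = 1:30, nonhead = 31:60)
  des <- bulk_design(n_per_bulk = 30, mean_depth = 30, base_error = 0,
                     seed = 41)

  # f = 1, e = 0: every read carries the alt allele (and f = 0 mirrors it)
  geno$geno[] <- 2L
  vt <- simulate_bulk_depths(geno, bulks, des)
  expect_true(all(vt$bulkA_ref == 0))
  expect_true(all(vt$bulkB_ref == 0))
  geno$geno[] <- 0L
  vt0 <- simulate_bulk_depths(geno, bulks, des)
  expect_true(all(vt0$bulkA_alt == 0))
  expect_true(all(vt0$bulkB_alt == 0))

  # law of large numbers: heading bulk of 30 with 10 alt homozygotes has
  # f exactly 1/3; mean of alt/depth over 10000 sites within +-0.01
  geno$geno[] <- 0L
  geno$geno[1:10, ] <- 2L
  vt3 <- simulate_bulk_depths(geno, bulks, des)
  frac <- vt3$bulkA_alt / (vt3$bulkA_ref + vt3$bulkA_alt)
  expect_lt(abs(mean(frac, na.rm = TRUE) - 1 / 3), 0.01)
})

test_that("expression simulation matches its NB model", {
  # no DE genes when de_fraction = 0
  d0 <- expr_design(n_genes = 100, de_fraction = 0, seed = 5)
  s0 <- simulate_counts(d0)
  expect_identical(sum(s0$truth$is_de), 0L)

  # Poisson limit: dispersion -> 0 gives variance/mean -> 1 across genes
  # (constant baseline, equal libraries, so genes are iid draws)
  dp <- expr_design(n_genes = 4000, dispersion = 1e-6, de_fraction = 0,
                    library_sizes = c(1, 1), baseline_meanlog = log(100),
                    baseline_sdlog = 1e-9, seed = 6)
  sp <- simulate_counts(dp)
  ratio <- var(as.numeric(sp$counts[, 1])) / mean(sp$counts[, 1])
  expect_lt(abs(ratio - 1), 0.15)
  # and a clearly over-dispersed design is far from 1
  dn <- expr_design(n_genes = 4000, dispersion = 0.1, de_fraction = 0,
                    library_sizes = c(1, 1), baseline_meanlog = log(100),
                    baseline_sdlog = 1e-9, seed = 6)
  sn <- simulate_counts(dn)
  expect_gt(var(as.numeric(sn$counts[, 1])) / mean(sn$counts[, 1]), 5)

  # log2fc_effect = 2, equal libraries: mean-count ratio ~ 4 for DE genes
  de <- expr_design(n_genes = 4000, dispersion = 0.05, de_fraction = 1,
                    log2fc_effect = 2, library_sizes = c(1, 1),
                    baseline_meanlog = log(200), baseline_sdlog = 1e-9,
                    seed = 7)
  sd_ <- simulate_counts(de)
  up <- sd_$truth$true_log2fc > 0
  expect_lt(abs(mean(sd_$counts[up, 1]) / mean(sd_$counts[up, 2]) - 4), 0.3)
})

test_that("same seed gives bit-identical simulations", {
  map <- tiny_map(indel_fraction = 0.2)
  trait <- trait_model("chr1", 5e5)
  run <- function() {
    des <- bulk_design(mean_depth = 40, seed = 99)
    g <- simulate_f2_genotypes(map, 323, trait, seed = 99)
    b <- assign_bulks(g, trait, des)
    simulate_bulk_depths(g, b, des)
  }
  expect_identical(run(), run())
  d <- expr_design(n_genes = 50, seed = 77)
  expect_identical(simulate_counts(d), simulate_counts(d))
})

test_that("indel tagging and gene tiling are deterministic and in range", {
  map <- genome_map(c(chr1 = 1e6), marker_spacing = 10000,
                    indel_fraction = 0.2)
  expect_equal(mean(map$markers$variant_type == "indel"), 0.2)
  g <- tile_genes(map)
  expect_true(all(g$start <= g$end))
  expect_true(all(g$end <= 1e6))
  expect_false(anyDuplicated(g$gene_id) > 0)
})
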