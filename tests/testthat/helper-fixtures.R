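suppressPackageStartupMessages(library(data.table))

# small single-chromosome map used across tests
tiny_map <- function(len = 1e6, spacing = 50000, indel_fraction = 0) {
  genome_map(c(chr1 = len), marker_spacing = spacing,
             indel_fraction = indel_fraction)
}

# hand-built variant table rows
toy_variants <- function(bulkA_ref, bulkA_alt, bulkB_ref, bulkB_alt,
                         parent1_gt = "1/1", parent2_gt = "0/0",
                         chrom = "chr1",
                         pos = seq_along(bulkA_ref) * 1000L,
                         variant_type = "SNP") {
  data.table(chrom = chrom, pos = as.integer(pos),
             variant_type = variant_type,
             parent1_gt = parent1_gt, parent2_gt = parent2_gt,
             bulkA_ref = as.integer(bulkA_ref),
             bulkA_alt = as.integer(bulkA_alt),
             bulkB_ref = as.integer(bulkB_ref),
             bulkB_alt = as.integer(bulkB_alt))
}

# independent oracle for the exact conditional NB test: negative
# hypergeometric conditional probabilities from the combinatorial identity
# P(X = x | S = s) = C(x+r-1, x) C(s-x+r-1, s-x) / C(s+2r-1, s), summed by
# brute force over all splits no more probable than the observed one
oracle_nb_exact <- function(a, b, dispersion) {
  r <- 1 / dispersion
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  lp <- lgamma(x + r) - lgamma(r) - lfactorial(x) +
        lgamma(s - x + r) - lgamma(r) - lfactorial(s - x) -
        (lgamma(s + 2 * r) - lgamma(2 * r) - lfactorial(s))
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pobs <- pr[a + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-10)]))
}

# independent BH oracle: adjusted p for each i is the smallest value of
# p_(k) * m / k over all k whose sorted p is >= p_i (double loop, no cummin)
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    ks <- which(ps >= pi - 1e-15)
    min(1, min(ps[ks] * m / ks))
  }, numeric(1))
}

# exact distribution of |X/d - Y/d|, X,Y ~ iid Binomial(d, 1/2):
# full outcome-grid enumeration; quantile = inverse CDF
oracle_null_quantile <- function(depth, confidence) {
  x <- 0:depth
  px <- dbinom(x, depth, 0.5)
  grid <- expand.grid(x = x, y = x)
  d <- abs(grid$x - grid$y) / depth
  w <- px[grid$x + 1] * px[grid$y + 1]
  agg <- aggregate(w, by = list(d = d), FUN = sum)
  agg <- agg[order(agg$d), ]
  cdf <- cumsum(agg$x)
  agg$d[match(TRUE, cdf >= confidence - 1e-12)]
}

# one full simulated scan; returns the called regions
run_sim_scan <- function(seed, trait, map, mean_depth = 30,
                         n_individuals = 323, null_reps = 2000,
                         min_variants = 2) {
  des <- bulk_design(n_per_bulk = 50, mean_depth = mean_depth, seed = seed)
  geno <- simulate_f2_genotypes(map, n_individuals, trait, seed = seed)
  bulks <- assign_bulks(geno, trait, des)
  vt <- simulate_bulk_depths(geno, bulks, des)
  lens <- stats::setNames(map$chromosomes$length, map$chromosomes$chrom)
  suppressMessages(bsa_scan(
    vt,
    scan_cfg = scan_config(min_variants = min_variants),
    thr_cfg = threshold_config(null_reps = null_reps, seed = seed),
    chrom_lengths = lens))
}
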