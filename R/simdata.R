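#' Define a marker map over a synthetic genome
#'
#' Stands in for a reference genome plus the set of biallelic sites fixed for
#' opposite alleles in the two parents of the cross. Markers are either placed
#' on a regular grid (`marker_spacing`) or given explicitly. A fixed fraction
#' of markers is tagged as small indels (type tag only -- length and sequence
#' content are irrelevant to the pooled allele-frequency statistic), assigned
#' deterministically by round-robin so the map itself carries no randomness.
#'
#' @param chrom_lengths named numeric vector, chromosome name -> length in bp.
#' @param marker_spacing bp between adjacent markers when positions are not
#'   supplied. Default 50000.
#' @param marker_positions optional named list (chromosome -> sorted 1-based
#'   positions) overriding the regular grid.
#' @param indel_fraction fraction of markers tagged `"indel"` (the remainder
#'   are `"SNP"`). Default 0.2, roughly the indel:SNP ratio seen in
#'   resequenced Brassica F2 pools.
#' @param cm_per_mb genetic map density in centimorgan per megabase, used by
#'   the Haldane map function during gamete simulation. Default 4.
#' @return an object of class `genome_map`: list with `chromosomes`
#'   (data.table chrom/length), `markers` (data.table chrom/pos/variant_type,
#'   position-sorted) and `cm_per_mb`.
#' @export
genome_map <- function(chrom_lengths, marker_spacing = 50000,
                       marker_positions = NULL, indel_fraction = 0.2,
                       cm_per_mb = 4) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stopf("chrom_lengths must be a named vector")
  if (any(chrom_lengths < 1)) stopf("chromosome lengths must be >= 1 bp")
  if (indel_fraction < 0 || indel_fraction > 1)
    stopf("indel_fraction must be in [0, 1]")
  if (cm_per_mb <= 0) stopf("cm_per_mb must be positive")

  chroms <- data.table(chrom = names(chrom_lengths),
                       length = as.numeric(chrom_lengths))
  mk <- lapply(chroms$chrom, function(cn) {
    len <- chrom_lengths[[cn]]
    p <- if (!is.null(marker_positions)) {
      as.numeric(marker_positions[[cn]])
    } else {
      seq(marker_spacing, len, by = marker_spacing)
    }
    if (length(p) == 0) return(NULL)
    if (is.unsorted(p)) stopf("marker positions on %s must be sorted", cn)
    if (any(p < 1) || any(p > len))
      stopf("marker positions on %s fall outside [1, %d]", cn, as.integer(len))
    data.table(chrom = cn, pos = as.integer(p))
  })
  markers <- rbindlist(mk)
  if (nrow(markers) == 0) stopf("map contains no markers")
  # deterministic round-robin indel tagging
  vt <- rep("SNP", nrow(markers))
  if (indel_fraction > 0) {
    k <- max(1L, round(1 / indel_fraction))
    vt[seq_len(nrow(markers)) %% k == 0L] <- "indel"
  }
  markers[, variant_type := vt]
  structure(list(chromosomes = chroms, markers = markers,
                 cm_per_mb = cm_per_mb),
            class = "genome_map")
}

#' Define the causal-locus model for the segregating trait
#'
#' A monogenic stand-in for the (in reality polygenic) heading trait: one
#' causal marker whose genotype determines the phenotype through a mode and a
#' penetrance. Penetrance acts as symmetric phenotype misclassification:
#' susceptible genotypes head with probability `penetrance`, all other
#' genotypes with probability `1 - penetrance`, so `penetrance = 0.5` makes
#' phenotype independent of genotype and both bulks drift to allele
#' frequency 1/2.
#'
#' @param chrom chromosome carrying the causal locus.
#' @param pos 1-based bp position; must be a marker position of the map used
#'   for genotype simulation (validated there).
#' @param mode `"recessive"` (heading requires two copies of the
#'   heading-parent allele), `"dominant"` (one copy suffices) or
#'   `"additive"` (heading probability interpolates linearly in allele dose).
#' @param penetrance probability in `[0, 1]`, see above. Default 1.
#' @return object of class `trait_model`.
#' @export
trait_model <- function(chrom, pos, mode = c("recessive", "dominant",
                                             "additive"),
                        penetrance = 1) {
  mode <- match.arg(mode)
  if (penetrance < 0 || penetrance > 1) stopf("penetrance must be in [0, 1]")
  structure(list(chrom = chrom, pos = as.numeric(pos), mode = mode,
                 penetrance = penetrance),
            class = "trait_model")
}

#' Bulk composition and pooled-sequencing design
#'
#' @param n_per_bulk individuals pooled per phenotype bulk (default 50, the
#'   usual 50+50 selection from a few hundred F2 plants).
#' @param mean_depth mean pooled coverage per site per bulk (reads); default
#'   75, matching deep F2-bulk resequencing.
#' @param base_error per-read allele miscall probability in `[0, 0.5)`;
#'   default 0.001 (Q30-grade base quality).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return object of class `bulk_design`.
#' @export
bulk_design <- function(n_per_bulk = 50, mean_depth = 75, base_error = 0.001,
                        seed = 1L) {
  if (n_per_bulk < 1) stopf("n_per_bulk must be >= 1")
  if (mean_depth <= 0) stopf("mean_depth must be > 0")
  if (base_error < 0 || base_error >= 0.5)
    stopf("base_error must be in [0, 0.5)")
  structure(list(n_per_bulk = as.integer(n_per_bulk),
                 mean_depth = mean_depth, base_error = base_error,
                 seed = as.integer(seed)),
            class = "bulk_design")
}

#' Between-bulk expression-count design
#'
#' One RNA library per bulk (no replicates), negative-binomial counts with a
#' fixed dispersion -- the same model the fixed-dispersion exact test assumes.
#'
#' @param n_genes number of genes.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); default 0.1.
#' @param de_fraction fraction of genes differentially expressed; default 0.05.
#' @param log2fc_effect absolute log2 fold change of DE genes between bulks
#'   (split symmetrically across the two bulks); default 2.
#' @param library_sizes length-2 vector of total mapped fragments per bulk
#'   (bulkA, bulkB); defaults mirror deep heading vs non-heading bulk
#'   RNA libraries (62.66M and 52.15M fragments).
#' @param baseline_meanlog,baseline_sdlog lognormal parameters of the
#'   baseline per-gene mean count (median ~150 by default).
#' @param seed integer seed.
#' @return object of class `expr_design`.
#' @export
expr_design <- function(n_genes = 2000, dispersion = 0.1, de_fraction = 0.05,
                        log2fc_effect = 2,
                        library_sizes = c(62663675, 52154937),
                        baseline_meanlog = log(150), baseline_sdlog = 1.2,
                        seed = 1L) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (de_fraction < 0 || de_fraction > 1)
    stopf("de_fraction must be in [0, 1]")
  if (length(library_sizes) != 2 || any(library_sizes <= 0))
    stopf("library_sizes must be two positive numbers")
  structure(list(n_genes = as.integer(n_genes), dispersion = dispersion,
                 de_fraction = de_fraction, log2fc_effect = log2fc_effect,
                 library_sizes = as.numeric(library_sizes),
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, seed = as.integer(seed)),
            class = "expr_design")
}

#' Simulate F2 genotypes under the Haldane map function
#'
#' Each individual is built from two independent gametes per chromosome. The
#' first marker allele of a gamete is Bernoulli(1/2); between adjacent
#' markers a crossover occurs with the Haldane recombination fraction
#' r = (1 - exp(-2 d / 100)) / 2 where d is the inter-marker distance in cM
#' (bp distance times the map's cM/Mb rate). Genotypes count copies of the
#' heading-parent allele (0/1/2), which is the ALT allele in emitted VCFs.
#'
#' @param map a [genome_map()].
#' @param n number of F2 individuals.
#' @param trait optional [trait_model()]; when supplied, its causal position
#'   is validated against the marker set (configuration error otherwise).
#' @param seed integer seed.
#' @return object of class `f2_genotypes`: list with `geno` (integer matrix,
#'   n individuals x markers), `markers` (the map's marker table) and `map`.
#' @export
simulate_f2_genotypes <- function(map, n, trait = NULL, seed = 1L) {
  stopifnot(inherits(map, "genome_map"))
  if (n < 1) stopf("n must be >= 1")
  if (!is.null(trait)) {
    hit <- map$markers[chrom == trait$chrom & pos == trait$pos]
    if (nrow(hit) == 0)
      stopf("causal position %s:%d is not a marker of the map",
            trait$chrom, as.integer(trait$pos))
  }
  geno <- withr::with_seed(seed, {
    blocks <- lapply(split(map$markers$pos, map$markers$chrom)[
      unique(map$markers$chrom)], function(p) {
        m <- length(p)
        d_cm <- p * map$cm_per_mb / 1e6
        r <- 0.5 * (1 - exp(-2 * diff(d_cm) / 100))
        g <- matrix(0L, nrow = 2L * n, ncol = m)
        g[, 1] <- rbinom(2L * n, 1L, 0.5)
        if (m > 1) for (j in 2:m) {
          sw <- rbinom(2L * n, 1L, r[j - 1])
          g[, j] <- (g[, j - 1] + sw) %% 2L
        }
        g[seq_len(n), , drop = FALSE] + g[n + seq_len(n), , drop = FALSE]
      })
    do.call(cbind, blocks)
  })
  colnames(geno) <- paste0(map$markers$chrom, ":", map$markers$pos)
  structure(list(geno = geno, markers = copy(map$markers), map = map),
            class = "f2_genotypes")
}

causal_marker_index <- function(geno, trait) {
  which(geno$markers$chrom == trait$chrom & geno$markers$pos == trait$pos)
}

heading_probability <- function(g, trait) {
  pen <- trait$penetrance
  switch(trait$mode,
    recessive = ifelse(g == 2L, pen, 1 - pen),
    dominant  = ifelse(g >= 1L, pen, 1 - pen),
    additive  = (1 - pen) + (g / 2) * (2 * pen - 1))
}

#' Select the two phenotype bulks from a simulated F2 population
#'
#' Phenotypes are drawn from the causal genotype under the trait model, then
#' `n_per_bulk` individuals are sampled without replacement from each
#' phenotype class. With `trait = NULL` the phenotype is a fair coin,
#' emulating a null experiment with no causal locus.
#'
#' @param geno result of [simulate_f2_genotypes()].
#' @param trait a [trait_model()], or `NULL` for the no-locus null.
#' @param design a [bulk_design()].
#' @param seed integer seed; defaults to `design$seed + 1` so the genotype
#'   and bulk-selection streams differ under a shared design seed.
#' @return list with integer index vectors `head` and `nonhead`, and the
#'   logical phenotype vector `heading`.
#' @export
assign_bulks <- function(geno, trait, design, seed = design$seed + 1L) {
  stopifnot(inherits(geno, "f2_genotypes"), inherits(design, "bulk_design"))
  n <- nrow(geno$geno)
  withr::with_seed(seed, {
    p <- if (is.null(trait)) rep(0.5, n) else {
      ci <- causal_marker_index(geno, trait)
      if (length(ci) != 1)
        stopf("causal position %s:%d is not a marker of the map",
              trait$chrom, as.integer(trait$pos))
      heading_probability(geno$geno[, ci], trait)
    }
    heading <- rbinom(n, 1L, p) == 1L
    if (sum(heading) < design$n_per_bulk ||
        sum(!heading) < design$n_per_bulk)
      stopf(paste0("not enough individuals per phenotype: %d heading, ",
                   "%d non-heading, need %d each"),
            sum(heading), sum(!heading), design$n_per_bulk)
    list(head = sort(sample(which(heading), design$n_per_bulk)),
         nonhead = sort(sample(which(!heading), design$n_per_bulk)),
         heading = heading)
  })
}

#' Simulate pooled sequencing of the two bulks
#'
#' Per site and bulk, total depth is Poisson(`mean_depth`) and the
#' heading-parent (ALT) read count is Binomial(depth, f(1-e) + (1-f)e),
#' where f is the bulk's true ALT allele frequency and e the per-read miscall
#' probability. Parents are emitted as fixed opposite homozygotes
#' (heading parent `1/1`, non-heading parent `0/0`).
#'
#' @param geno result of [simulate_f2_genotypes()].
#' @param bulks result of [assign_bulks()] (bulkA = heading bulk).
#' @param design a [bulk_design()].
#' @param seed integer seed; defaults to `design$seed + 2`.
#' @return a variant table: data.table with columns chrom, pos, variant_type,
#'   parent1_gt, parent2_gt, bulkA_ref, bulkA_alt, bulkB_ref, bulkB_alt,
#'   sorted by (chrom, pos). Parent 1 is the heading parent.
#' @export
simulate_bulk_depths <- function(geno, bulks, design,
                                 seed = design$seed + 2L) {
  stopifnot(inherits(geno, "f2_genotypes"), inherits(design, "bulk_design"))
  if (length(intersect(bulks$head, bulks$nonhead)))
    stopf("bulks must be disjoint")
  fA <- colMeans(geno$geno[bulks$head, , drop = FALSE]) / 2
  fB <- colMeans(geno$geno[bulks$nonhead, , drop = FALSE]) / 2
  e <- design$base_error
  m <- length(fA)
  withr::with_seed(seed, {
    dA <- rpois(m, design$mean_depth)
    dB <- rpois(m, design$mean_depth)
    aA <- rbinom(m, dA, fA * (1 - e) + (1 - fA) * e)
    aB <- rbinom(m, dB, fB * (1 - e) + (1 - fB) * e)
    tab <- data.table(geno$markers,
                      parent1_gt = "1/1", parent2_gt = "0/0",
                      bulkA_ref = dA - aA, bulkA_alt = aA,
                      bulkB_ref = dB - aB, bulkB_alt = aB)
    tab[position_order(chrom, pos)]
  })
}

#' Simulate between-bulk expression counts with ground truth
#'
#' Baseline per-gene means are lognormal; each DE gene receives a symmetric
#' `2^(+/- log2fc_effect/2)` shift with random sign, multiplied by the bulk's
#' library-size factor; counts are NB with the design's fixed dispersion.
#'
#' @param design an [expr_design()].
#' @param gene_ids optional gene identifiers (default `gene00001`, ...).
#' @param de_genes optional character vector of gene ids forced to be the DE
#'   set (overrides `de_fraction`).
#' @param seed integer seed; defaults to the design seed.
#' @return list with `counts` (integer matrix n_genes x 2, columns bulkA and
#'   bulkB), `truth` (data.table gene_id, is_de, true_log2fc), `lengths`
#'   (named gene lengths, bp) and `library_sizes`.
#' @export
simulate_counts <- function(design, gene_ids = NULL, de_genes = NULL,
                            seed = design$seed) {
  stopifnot(inherits(design, "expr_design"))
  n <- design$n_genes
  ids <- gene_ids %||% sprintf("gene%05d", seq_len(n))
  if (length(ids) != n) stopf("gene_ids must have length n_genes (%d)", n)
  sf <- design$library_sizes / exp(mean(log(design$library_sizes)))
  withr::with_seed(seed, {
    base <- rlnorm(n, design$baseline_meanlog, design$baseline_sdlog)
    is_de <- if (is.null(de_genes)) {
      seq_len(n) %in% sample(n, round(design$de_fraction * n))
    } else {
      miss <- setdiff(de_genes, ids)
      if (length(miss)) stopf("unknown de_genes: %s",
                              paste(miss, collapse = ", "))
      ids %in% de_genes
    }
    sgn <- ifelse(runif(n) < 0.5, -1, 1)
    lfc <- ifelse(is_de, sgn * design$log2fc_effect, 0)
    muA <- base * 2^(lfc / 2) * sf[1]
    muB <- base * 2^(-lfc / 2) * sf[2]
    counts <- cbind(bulkA = rnbinom(n, mu = muA, size = 1 / design$dispersion),
                    bulkB = rnbinom(n, mu = muB, size = 1 / design$dispersion))
    rownames(counts) <- ids
    lens <- round(runif(n, 500, 5000))
    list(counts = counts,
         truth = data.table(gene_id = ids, is_de = is_de, true_log2fc = lfc),
         lengths = setNames(lens, ids),
         library_sizes = design$library_sizes)
  })
}

#' Tile synthetic gene models over a simulated genome
#'
#' @param map a [genome_map()].
#' @param gene_length gene span in bp (default 2000).
#' @param spacing intergenic gap in bp (default 3000).
#' @param prefix id prefix (default `"gene"`); ids are zero-padded and unique
#'   genome-wide. Clearly synthetic: no real annotation is imitated.
#' @return gene-model data.table: gene_id, chrom, start, end, strand.
#' @export
tile_genes <- function(map, gene_length = 2000, spacing = 3000,
                       prefix = "gene") {
  stopifnot(inherits(map, "genome_map"))
  out <- rbindlist(lapply(seq_len(nrow(map$chromosomes)), function(i) {
    cn <- map$chromosomes$chrom[i]
    len <- map$chromosomes$length[i]
    st <- as.integer(seq(1, max(1, len - gene_length),
                         by = gene_length + spacing))
    data.table(chrom = cn, start = st,
               end = as.integer(pmin(st + gene_length - 1, len)),
               strand = rep_len(c("+", "-"), length(st)))
  }))
  out[, gene_id := sprintf("%s%05d", prefix, seq_len(.N))]
  setcolorder(out, c("gene_id", "chrom", "start", "end", "strand"))
  out[]
}

#' Simulate and write a complete bulked-segregant experiment
#'
#' Convenience wrapper used by the command-line interface: simulates an F2
#' population, both DNA-style bulk variant tables and an expression count
#' matrix (DE genes placed inside the causal region when a trait and gene
#' models are available), and writes VCF / GFF3 / TSV files to `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param map,trait,design,edesign see [genome_map()], [trait_model()],
#'   [bulk_design()], [expr_design()]. `trait` may be `NULL` (null run).
#' @param n_individuals F2 population size before phenotype selection
#'   (default 323).
#' @param genes gene models (default [tile_genes()] over the map).
#' @param de_in_region place half of the DE genes inside a window of
#'   `region_halfwidth` bp around the causal locus when possible.
#' @param region_halfwidth bp, default 250000.
#' @return invisible list of written paths plus the ground-truth objects.
#' @export
simulate_bsa_experiment <- function(out_dir, map, trait, design,
                                    edesign = NULL, n_individuals = 323,
                                    genes = tile_genes(map),
                                    de_in_region = TRUE,
                                    region_halfwidth = 250000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geno <- simulate_f2_genotypes(map, n_individuals, trait,
                                seed = design$seed)
  bulks <- assign_bulks(geno, trait, design)
  vtab <- simulate_bulk_depths(geno, bulks, design)
  paths <- list(vcf = file.path(out_dir, "bulks.vcf"),
                gff3 = file.path(out_dir, "genes.gff3"))
  contig <- setNames(map$chromosomes$length, map$chromosomes$chrom)
  write_variant_vcf(vtab, paths$vcf, contig_lengths = contig)
  write_gff3(genes, paths$gff3)
  counts <- NULL
  if (!is.null(edesign)) {
    edesign$n_genes <- nrow(genes)
    de_genes <- NULL
    if (de_in_region && !is.null(trait)) {
      inreg <- genes[chrom == trait$chrom &
                       end >= trait$pos - region_halfwidth &
                       start <= trait$pos + region_halfwidth, gene_id]
      n_de <- round(edesign$de_fraction * nrow(genes))
      k_in <- min(length(inreg), max(1L, n_de %/% 2L))
      de_genes <- withr::with_seed(edesign$seed + 7L, {
        c(sample(inreg, k_in),
          sample(setdiff(genes$gene_id, inreg), max(0L, n_de - k_in)))
      })
    }
    counts <- simulate_counts(edesign, gene_ids = genes$gene_id,
                              de_genes = de_genes)
    paths$counts <- file.path(out_dir, "counts.tsv")
    paths$truth <- file.path(out_dir, "counts_truth.tsv")
    write_counts_tsv(counts$counts, paths$counts,
                     lengths = counts$lengths)
    fwrite(counts$truth, paths$truth, sep = "\t")
  }
  invisible(list(paths = paths, genotypes = geno, bulks = bulks,
                 variants = vtab, counts = counts, genes = genes))
}
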