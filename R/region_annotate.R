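#' Assign gene models to candidate regions
#'
#' A gene belongs to a region iff its `[start, end]` interval overlaps the
#' region interval by at least 1 bp (any-overlap rule; genes need not be
#' contained). A gene overlapping two regions appears once per region here
#' and once in the de-duplicated gene set. Regions on chromosomes absent
#' from the annotation are skipped with a warning.
#'
#' @param regions region table (see [region_table()]); a `region_id` column
#'   is added if absent.
#' @param genes gene-model data.table (gene_id, chrom, start, end, strand).
#' @param source label of the analysis of origin, e.g. `"BSA"` or `"BSR"`.
#' @return object of class `candidate_gene_set`: data.table with columns
#'   gene_id, chrom, gene_start, gene_end, region_id, method, source. The
#'   per-region tallies (region table with an `n_genes` column counting
#'   distinct genes per region) are attached as attribute `regions`.
#' @export
genes_in_regions <- function(regions, genes, source = "BSA") {
  assert_cols(regions, c("chrom", "start", "end"))
  assert_cols(genes, c("gene_id", "chrom", "start", "end"))
  regions <- copy(regions)
  if (!"region_id" %in% names(regions))
    regions[, region_id := sprintf("%s:%d-%d", chrom, as.integer(start),
                                   as.integer(end))]
  if (!"method" %in% names(regions)) regions[, method := NA_character_]
  unknown <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warnf("region chromosome(s) %s absent from annotation; skipped",
          paste(unknown, collapse = ", "))
    regions <- regions[!chrom %in% unknown]
  }
  hits <- if (nrow(regions) && nrow(genes)) {
    gr_reg <- GenomicRanges::GRanges(regions$chrom,
      IRanges::IRanges(regions$start, regions$end))
    gr_gen <- GenomicRanges::GRanges(genes$chrom,
      IRanges::IRanges(genes$start, genes$end))
    ov <- GenomicRanges::findOverlaps(gr_gen, gr_reg, minoverlap = 1L)
    data.table(gene_id = genes$gene_id[S4Vectors::queryHits(ov)],
               chrom = genes$chrom[S4Vectors::queryHits(ov)],
               gene_start = genes$start[S4Vectors::queryHits(ov)],
               gene_end = genes$end[S4Vectors::queryHits(ov)],
               region_id = regions$region_id[S4Vectors::subjectHits(ov)],
               method = regions$method[S4Vectors::subjectHits(ov)])
  } else {
    data.table(gene_id = character(), chrom = character(),
               gene_start = integer(), gene_end = integer(),
               region_id = character(), method = character())
  }
  data.table::set(hits, j = "source", value = rep(source, nrow(hits)))
  tallies <- hits[, .(n_genes = data.table::uniqueN(gene_id)),
                  by = region_id]
  regions[, n_genes := 0L]
  regions[tallies, n_genes := i.n_genes, on = "region_id"]
  out <- hits[order(gene_id, region_id)]
  setattr(out, "regions", regions[])
  setattr(out, "source", source)
  setattr(out, "class", c("candidate_gene_set", class(out)))
  out
}

#' Tally per-region and per-method candidate-gene counts
#'
#' The reporting path behind the candidate-region tables: given a region
#' table carrying per-region gene counts, sums them per method. Accepts
#' either a `candidate_gene_set` (uses its attached region tallies) or a
#' region table with an `n_genes` column.
#'
#' @param x `candidate_gene_set` or region table.
#' @return data.table: method, n_regions, total_genes.
#' @export
tally_region_genes <- function(x) {
  regions <- if (inherits(x, "candidate_gene_set")) attr(x, "regions") else x
  assert_cols(regions, c("method", "n_genes"), "region table")
  regions[, .(n_regions = .N, total_genes = sum(n_genes)), by = method]
}

#' Distinct gene ids of a candidate gene set
#'
#' @param x a `candidate_gene_set`.
#' @return sorted character vector of unique gene ids.
#' @export
candidate_gene_ids <- function(x) sort(unique(x$gene_id))

#' Conjunctive intersection of two candidate gene sets
#'
#' The crosstalk step of a conjunctive BSA x BSR analysis: genes present in
#' both the DNA-derived and the RNA-derived candidate sets, stable-sorted by
#' gene id, with the regions of origin in each analysis attached.
#'
#' @param set_a,set_b outputs of [genes_in_regions()] over the same gene
#'   namespace.
#' @return data.table: gene_id, regions_a, regions_b (comma-separated
#'   region ids of origin per analysis).
#' @export
conjunctive_intersect <- function(set_a, set_b) {
  common <- intersect(unique(set_a$gene_id), unique(set_b$gene_id))
  common <- sort(common)
  prov <- function(s, ids) {
    p <- s[gene_id %in% ids, .(regions = paste(sort(unique(region_id)),
                                               collapse = ",")),
           by = gene_id]
    setNames(p$regions, p$gene_id)
  }
  pa <- prov(set_a, common)
  pb <- prov(set_b, common)
  data.table(gene_id = common,
             regions_a = unname(pa[common]),
             regions_b = unname(pb[common]))
}
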