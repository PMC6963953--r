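#' Write a bulk variant table as VCF 4.2
#'
#' Emits one biallelic record per site with FORMAT `GT:AD:DP` for four
#' samples: parent 1 (heading parent, fixed ALT homozygote), parent 2 (fixed
#' REF homozygote), bulk A (heading bulk) and bulk B. SNP rows are written as
#' `A>T`, indel rows as `A>AT`, so variant type survives a round trip; real
#' alleles are irrelevant to the pooled-frequency statistic. The ALT allele is
#' the heading-parent allele by convention (stated in the header).
#'
#' @param x variant table (see [simulate_bulk_depths()] for columns).
#' @param path output path (`.gz` supported).
#' @param sample_names named character vector mapping roles
#'   `parent1, parent2, bulkA, bulkB` to VCF sample names.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @param parent_depth constant depth written for the parent samples'
#'   AD/DP (parents are not part of the modelled data; default 27).
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(x, path,
                              sample_names = c(parent1 = "R01",
                                               parent2 = "R02",
                                               bulkA = "R03", bulkB = "R04"),
                              contig_lengths = NULL, parent_depth = 27L) {
  assert_cols(x, c("chrom", "pos", "variant_type", "parent1_gt", "parent2_gt",
                   "bulkA_ref", "bulkA_alt", "bulkB_ref", "bulkB_alt"))
  roles <- c("parent1", "parent2", "bulkA", "bulkB")
  if (!all(roles %in% names(sample_names)))
    stopf("sample_names must name all of: %s", paste(roles, collapse = ", "))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bulkmapr",
           "##ALT_allele=heading-parent allele (parent1)",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
                  "\"Allelic depths (ref,alt)\">"),
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_names[roles]), collapse = "\t"))
  ref <- "A"
  alt <- ifelse(x$variant_type == "indel", "AT", "T")
  pd <- as.integer(parent_depth)
  fmt_gt <- function(gt, ad, dp) paste0(gt, ":", ad, ":", dp)
  p1 <- fmt_gt(x$parent1_gt,
               ifelse(x$parent1_gt == "1/1", paste0("0,", pd),
                      paste0(pd, ",0")), pd)
  p2 <- fmt_gt(x$parent2_gt,
               ifelse(x$parent2_gt == "1/1", paste0("0,", pd),
                      paste0(pd, ",0")), pd)
  bgt <- function(ref_d, alt_d) {
    tot <- ref_d + alt_d
    gt <- ifelse(tot == 0, "./.",
          ifelse(ref_d == 0, "1/1", ifelse(alt_d == 0, "0/0", "0/1")))
    fmt_gt(gt, paste0(ref_d, ",", alt_d), tot)
  }
  body <- paste(x$chrom, format(x$pos, scientific = FALSE, trim = TRUE),
                ".", ref, alt, ".", "PASS", ".", "GT:AD:DP",
                p1, p2, bgt(x$bulkA_ref, x$bulkA_alt),
                bgt(x$bulkB_ref, x$bulkB_alt), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a four-sample bulk VCF into the internal variant table
#'
#' Consumes biallelic records only; multi-allelic records and records with a
#' missing genotype in any of the four roles are dropped with a logged count.
#' Variant type is classified from REF/ALT lengths (equal length 1 = SNP,
#' otherwise indel). Bulk allele depths come from the AD field (AD is
#' authoritative; DP, when present, is only sanity-checked). Rows are
#' returned sorted by (chromosome natural order, position).
#'
#' @param path VCF path (plain or gzipped).
#' @param roles named character vector mapping roles
#'   `parent1, parent2, bulkA, bulkB` to VCF sample names.
#' @return variant table (data.table), as in [simulate_bulk_depths()].
#' @export
read_variant_vcf <- function(path,
                             roles = c(parent1 = "R01", parent2 = "R02",
                                       bulkA = "R03", bulkB = "R04")) {
  need <- c("parent1", "parent2", "bulkA", "bulkB")
  if (!all(need %in% names(roles)))
    stopf("roles must name all of: %s", paste(need, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  smp <- colnames(vcf)
  miss <- setdiff(unname(roles[need]), smp)
  if (length(miss))
    stopf("sample(s) %s not present in %s (has: %s)",
          paste(miss, collapse = ", "), path, paste(smp, collapse = ", "))
  n0 <- nrow(vcf)
  multi <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf)) != 1L
  vcf <- vcf[!multi]
  gt <- VariantAnnotation::geno(vcf)$GT[, unname(roles[need]), drop = FALSE]
  nogt <- rowSums(gt == "./." | gt == "." | is.na(gt)) > 0
  vcf <- vcf[!nogt]
  gt <- gt[!nogt, , drop = FALSE]
  msgf("read_variant_vcf: %d records; dropped %d multi-allelic, %d with missing genotypes; kept %d",
       n0, sum(multi), sum(nogt), nrow(vcf))
  rr <- SummarizedExperiment::rowRanges(vcf)
  reflen <- nchar(as.character(VariantAnnotation::ref(vcf)))
  altlen <- nchar(as.character(unlist(VariantAnnotation::alt(vcf))))
  vtype <- ifelse(reflen == 1L & altlen == 1L, "SNP", "indel")
  ad <- VariantAnnotation::geno(vcf)$AD
  get_ad <- function(role, allele) {
    col <- unname(roles[[role]])
    if (length(dim(ad)) == 3) {
      as.integer(ad[, col, allele])
    } else {
      as.integer(vapply(ad[, col], function(v) v[allele], numeric(1)))
    }
  }
  out <- data.table(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    variant_type = vtype,
    parent1_gt = unname(gt[, roles[["parent1"]]]),
    parent2_gt = unname(gt[, roles[["parent2"]]]),
    bulkA_ref = get_ad("bulkA", 1L), bulkA_alt = get_ad("bulkA", 2L),
    bulkB_ref = get_ad("bulkB", 1L), bulkB_alt = get_ad("bulkB", 2L))
  out[position_order(chrom, pos)]
}

#' Read gene models from GFF3
#'
#' Keeps `type == "gene"` rows only; coordinates stay 1-based inclusive.
#' Gene ids come from the `ID` attribute. A file without gene rows yields an
#' empty table with a warning.
#'
#' @param path GFF3 path (plain or gzipped).
#' @return gene-model data.table: gene_id, chrom, start, end, strand, sorted
#'   by position.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    warnf("no gene features in %s", path)
    return(data.table(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  }
  out <- data.table(gene_id = as.character(gr$ID),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  if (anyDuplicated(out$gene_id)) stopf("duplicate gene ids in %s", path)
  out[position_order(chrom, pos = start)]
}

#' Write gene models as GFF3
#'
#' @param genes gene-model data.table (gene_id, chrom, start, end, strand).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  assert_cols(genes, c("gene_id", "chrom", "start", "end", "strand"))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$source <- "bulkmapr"
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write gene-level fragment counts as TSV
#'
#' Layout: `gene_id`, optional `length`, then one integer column per bulk.
#'
#' @param path TSV path.
#' @return list with `counts` (integer matrix, genes x bulks) and `lengths`
#'   (named vector, or NULL when the file has no length column).
#' @export
read_counts_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  assert_cols(dt, "gene_id", "counts file")
  lens <- NULL
  if ("length" %in% names(dt)) {
    lens <- setNames(dt$length, dt$gene_id)
    dt[, length := NULL]
  }
  cnt <- as.matrix(dt[, -"gene_id"])
  rownames(cnt) <- dt$gene_id
  storage.mode(cnt) <- "integer"
  list(counts = cnt, lengths = lens)
}

#' @rdname read_counts_tsv
#' @param counts integer matrix, genes x bulks, with rownames.
#' @param lengths optional named gene lengths written as a `length` column.
#' @export
write_counts_tsv <- function(counts, path, lengths = NULL) {
  dt <- data.table(gene_id = rownames(counts))
  if (!is.null(lengths)) dt[, length := as.integer(lengths[gene_id])]
  dt <- cbind(dt, as.data.table(counts))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Expected columns: `gene`, `sample_id`, `part`, `ct` and optionally
#' `replicate` (technical replicates are averaged downstream).
#'
#' @param path TSV path.
#' @return data.table.
#' @export
read_qpcr_tsv <- function(path) {
  dt <- fread(path, sep = "\t")
  assert_cols(dt, c("gene", "sample_id", "part", "ct"), "qPCR file")
  dt
}
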