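#' @import data.table
#' @importFrom stats rbinom rpois rlnorm rnbinom runif loess loess.control
#'   predict quantile dnbinom setNames p.adjust chisq.test
#' @importFrom graphics plot lines abline
#' @importFrom utils packageVersion
NULL

# data.table NSE column names used throughout
utils::globalVariables(c(
  ".", ".N", ".SD", "chrom", "pos", "variant_type", "parent1_gt", "parent2_gt",
  "bulkA_ref", "bulkA_alt", "bulkB_ref", "bulkB_alt", "depth_A", "depth_B",
  "index_A", "index_B", "delta", "center", "n_variants", "mean_delta",
  "smoothed", "threshold", "threshold_raw", "gene_id", "start", "end",
  "strand", "region_id", "method", "n_genes", "size_mb", "size_bp", "sign",
  "call", "fdr", "log2fc", "p_value", "ct", "sample_id", "part", "gene",
  "dct", "is_de", "gene_start", "gene_end", "total_genes", "n_regions",
  "i.n_genes", "ref_ct", "cal_dct", "ddct", "rel_expr", "length",
  "true_log2fc", "count_a", "count_b", "fpkm_a", "fpkm_b"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural ordering of chromosome names
#'
#' Orders names such as `A02`, `A10`, `Scaffold000111` by their alphabetic
#' prefix first and embedded integer second, so `A2` sorts before `A10`.
#'
#' @param x character vector of chromosome names.
#' @return integer permutation, as from [order()].
#' @export
chrom_order <- function(x) {
  prefix <- gsub("[0-9]+", "", x)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]+", "", x)))
  num[is.na(num)] <- -Inf
  order(prefix, num, x)
}

# order by natural chrom key then position
position_order <- function(chrom, pos) {
  prefix <- gsub("[0-9]+", "", chrom)
  num <- suppressWarnings(as.numeric(gsub("[^0-9]+", "", chrom)))
  num[is.na(num)] <- -Inf
  order(prefix, num, chrom, pos)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

assert_cols <- function(dt, cols, what = deparse(substitute(dt))) {
  miss <- setdiff(cols, names(dt))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(dt)
}
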