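#' DEG-calling settings
#'
#' @param dispersion fixed NB dispersion used by the exact test
#'   (default 0.1, the standard choice when each bulk is a single pooled
#'   library and no replicate-based estimate exists).
#' @param alpha_fdr FDR cutoff, strict `<` (default 0.05).
#' @param min_abs_log2fc fold-change cutoff, inclusive `>=` (default 1).
#' @export
deg_config <- function(dispersion = 0.1, alpha_fdr = 0.05,
                       min_abs_log2fc = 1) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  structure(list(dispersion = dispersion, alpha_fdr = alpha_fdr,
                 min_abs_log2fc = min_abs_log2fc),
            class = "deg_config")
}

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (library_size * length)`.
#'
#' @param counts vector or matrix of fragment counts (genes x samples).
#' @param lengths gene lengths in bp (> 0), recycled across samples.
#' @param library_sizes total mapped fragments per sample (> 0); defaults to
#'   column sums.
#' @return numeric object shaped like `counts`.
#' @export
fpkm <- function(counts, lengths,
                 library_sizes = if (is.matrix(counts)) colSums(counts)
                                 else sum(counts)) {
  if (any(lengths <= 0)) stopf("gene lengths must be > 0")
  if (any(library_sizes <= 0)) stopf("library sizes must be > 0")
  if (is.matrix(counts)) {
    sweep(counts * 1e9 / lengths, 2, library_sizes, "/")
  } else {
    counts * 1e9 / (lengths * library_sizes)
  }
}

# conditional probabilities P(X = x | X + Y = s) for two iid NB(mu, phi)
# counts; free of mu when the dispersions match, so any positive mu works
# numerically. Returned on the log scale, normalized.
nb_conditional_logprob <- function(s, dispersion) {
  size <- 1 / dispersion
  mu <- max(s / 2, 0.5)
  x <- 0:s
  lp <- dnbinom(x, size = size, mu = mu, log = TRUE) +
        dnbinom(s - x, size = size, mu = mu, log = TRUE)
  lp - {
    mx <- max(lp)
    mx + log(sum(exp(lp - mx)))
  }
}

#' Exact conditional test for two NB counts with fixed dispersion
#'
#' Under the null both counts share one negative-binomial mean with the given
#' dispersion. Conditioning on the sum `s = a + b` removes the unknown mean;
#' the two-sided p-value sums the conditional probabilities of all splits
#' `(x, s - x)` no more probable than the observed one.
#'
#' @param a,b non-negative integer counts (vectorized; recycled).
#' @param dispersion NB dispersion, > 0.
#' @return two-sided p-values in `(0, 1]`.
#' @export
nb_exact_test <- function(a, b, dispersion = 0.1) {
  if (dispersion <= 0) stopf("dispersion must be > 0")
  if (any(a < 0) || any(b < 0)) stopf("counts must be non-negative")
  n <- max(length(a), length(b))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  vapply(seq_len(n), function(i) {
    s <- a[i] + b[i]
    if (s == 0) return(1)
    lp <- nb_conditional_logprob(s, dispersion)
    lobs <- lp[a[i] + 1]
    min(1, sum(exp(lp[lp <= lobs + 1e-12])))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment `p * m / rank` with monotonicity enforced from the
#' largest p downward; output aligned to the input order.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Classify genes from fold change and FDR
#'
#' The decision rule shared by [call_degs()]: `up` when
#' `log2fc >= min_abs_log2fc` (inclusive) and `fdr < alpha_fdr` (strict),
#' `down` for the mirrored condition, otherwise `ns`.
#'
#' @param log2fc,fdr numeric vectors.
#' @param cfg a [deg_config()].
#' @return character vector of calls.
#' @export
deg_call <- function(log2fc, fdr, cfg = deg_config()) {
  fifelse(fdr < cfg$alpha_fdr & log2fc >= cfg$min_abs_log2fc, "up",
  fifelse(fdr < cfg$alpha_fdr & log2fc <= -cfg$min_abs_log2fc, "down",
          "ns"))
}

#' Call differentially expressed genes between two bulks
#'
#' One library per bulk: counts are scaled to a common library size (simple
#' total-count ratio; geometric-mean reference), log2 fold change uses a 0.5
#' pseudo-count on the normalized means, p-values come from the
#' fixed-dispersion exact conditional test on the rounded normalized counts,
#' and FDR from [bh_fdr()]. A gene is `up` if `log2fc >= min_abs_log2fc` and
#' `fdr < alpha_fdr` (positive log2fc = higher in bulk A, the first column),
#' `down` for the mirrored condition, else `ns`.
#'
#' @param counts integer matrix with two columns (bulk A, bulk B) and gene
#'   rownames, or the list returned by [read_counts_tsv()].
#' @param cfg a [deg_config()].
#' @param library_sizes two library sizes; defaults to column sums.
#' @return DEG table (data.table): gene_id, count_a, count_b, log2fc,
#'   p_value, fdr, call.
#' @export
call_degs <- function(counts, cfg = deg_config(), library_sizes = NULL) {
  if (is.list(counts) && !is.matrix(counts)) counts <- counts$counts
  if (ncol(counts) != 2) stopf("counts must have exactly two bulk columns")
  libs <- library_sizes %||% colSums(counts)
  if (any(libs <= 0)) stopf("library sizes must be > 0")
  sf <- libs / exp(mean(log(libs)))
  an <- counts[, 1] / sf[1]
  bn <- counts[, 2] / sf[2]
  lfc <- log2((an + 0.5) / (bn + 0.5))
  p <- nb_exact_test(round(an), round(bn), cfg$dispersion)
  q <- bh_fdr(p)
  dt <- data.table(
    gene_id = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
    count_a = counts[, 1], count_b = counts[, 2],
    log2fc = lfc, p_value = p, fdr = q)
  dt[, call := deg_call(log2fc, fdr, cfg)]
  dt[]
}

#' Tally a DEG table
#'
#' The reporting path behind DEG summaries: up / down / total counts.
#'
#' @param deg DEG table with a `call` column.
#' @return data.table: up, down, total_de, ns.
#' @export
deg_summary <- function(deg) {
  assert_cols(deg, "call", "DEG table")
  data.table(up = sum(deg$call == "up"), down = sum(deg$call == "down"),
             total_de = sum(deg$call != "ns"), ns = sum(deg$call == "ns"))
}

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (gene, sample, part); the delta Ct
#' is `Ct_target - Ct_reference` within each sample/part, the delta-delta Ct
#' subtracts the gene's delta Ct in the calibrator sample/part, and relative
#' expression is `2^(-ddCt)` (calibrator = 1 by construction).
#'
#' @param panel data.table with columns gene, sample_id, part, ct (one row
#'   per technical replicate is fine).
#' @param reference_gene internal reference (e.g. an actin gene); must be
#'   measured in every sample/part, else an error names the offender.
#' @param calibrator_sample,calibrator_part the sample/part whose expression
#'   defines 1.0.
#' @return data.table: gene, sample_id, part, dct, ddct, rel_expr.
#' @export
ddct <- function(panel, reference_gene, calibrator_sample,
                 calibrator_part) {
  assert_cols(panel, c("gene", "sample_id", "part", "ct"), "qPCR panel")
  if (any(panel$ct <= 0)) stopf("Ct values must be > 0")
  mean_ct <- panel[, .(ct = mean(ct)), by = .(gene, sample_id, part)]
  ref <- mean_ct[gene == reference_gene,
                 .(sample_id, part, ref_ct = ct)]
  tgt <- mean_ct[gene != reference_gene]
  out <- merge(tgt, ref, by = c("sample_id", "part"), all.x = TRUE)
  if (any(is.na(out$ref_ct))) {
    bad <- unique(out[is.na(ref_ct), paste(sample_id, part, sep = "/")])
    stopf("reference gene %s not measured for: %s", reference_gene,
          paste(bad, collapse = ", "))
  }
  out[, dct := ct - ref_ct]
  cal <- out[sample_id == calibrator_sample & part == calibrator_part,
             .(gene, cal_dct = dct)]
  if (nrow(cal) == 0)
    stopf("calibrator %s/%s not present in panel", calibrator_sample,
          calibrator_part)
  out <- merge(out, cal, by = "gene", all.x = TRUE)
  if (any(is.na(out$cal_dct)))
    stopf("calibrator measurement missing for gene(s): %s",
          paste(unique(out[is.na(cal_dct), gene]), collapse = ", "))
  out[, ddct := dct - cal_dct]
  out[, rel_expr := 2^(-ddct)]
  out[, .(gene, sample_id, part, dct, ddct, rel_expr)][
    order(gene, sample_id, part)]
}
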