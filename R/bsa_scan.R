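#' Variant filtering settings
#'
#' Defaults follow the usual bulked-segregant pre-filter: per-bulk coverage
#' strictly above 5x, and only sites where the two parents are homozygous for
#' opposite alleles (informative in an F2).
#'
#' @param min_depth exclusive lower bound on each bulk's total depth
#'   (default 5: depth must be > 5).
#' @param require_parent_informative drop sites whose parent genotypes are
#'   not opposite homozygotes. Default TRUE.
#' @export
filter_config <- function(min_depth = 5, require_parent_informative = TRUE) {
  if (min_depth < 0) stopf("min_depth must be >= 0")
  structure(list(min_depth = min_depth,
                 require_parent_informative =
                   isTRUE(require_parent_informative)),
            class = "filter_config")
}

#' Sliding-window scan settings
#'
#' @param window_size window width in bp (default 100000).
#' @param step step between window centers in bp (default 10000; must be
#'   <= window_size).
#' @param loess_span LOESS span in (0, 1] (default 0.3), degree-1 local
#'   regression per chromosome.
#' @param min_variants windows holding fewer variants are marked missing
#'   (NA), never zero. Default 3.
#' @export
scan_config <- function(window_size = 100000, step = 10000,
                        loess_span = 0.3, min_variants = 3) {
  if (step > window_size) stopf("step must be <= window_size")
  if (loess_span <= 0 || loess_span > 1) stopf("loess_span must be in (0,1]")
  structure(list(window_size = window_size, step = step,
                 loess_span = loess_span,
                 min_variants = as.integer(min_variants)),
            class = "scan_config")
}

#' Null-threshold settings
#'
#' @param confidence quantile of the simulated no-QTL null used as the
#'   per-window threshold (default 0.99).
#' @param null_reps Monte-Carlo replicates (default 10000; < 100 warns).
#' @param seed integer seed for the null simulation.
#' @export
threshold_config <- function(confidence = 0.99, null_reps = 10000,
                             seed = 1L) {
  if (confidence <= 0 || confidence >= 1)
    stopf("confidence must be in (0, 1)")
  if (null_reps < 100) warnf("null_reps < 100: quantile will be unstable")
  structure(list(confidence = confidence, null_reps = as.integer(null_reps),
                 seed = as.integer(seed)),
            class = "threshold_config")
}

#' Filter a variant table for association analysis
#'
#' Keeps rows where both bulks have total depth strictly greater than
#' `min_depth` and (optionally) the parents are homozygous for opposite
#' alleles. Input / retained counts are logged, mirroring the bookkeeping a
#' mapping report needs.
#'
#' @param tab variant table.
#' @param cfg a [filter_config()].
#' @return filtered variant table (possibly empty), position-sorted.
#' @export
filter_variants <- function(tab, cfg = filter_config()) {
  assert_cols(tab, c("chrom", "pos", "bulkA_ref", "bulkA_alt",
                     "bulkB_ref", "bulkB_alt"))
  n0 <- nrow(tab)
  keep <- (tab$bulkA_ref + tab$bulkA_alt) > cfg$min_depth &
          (tab$bulkB_ref + tab$bulkB_alt) > cfg$min_depth
  n_depth <- sum(keep)
  if (cfg$require_parent_informative) {
    hom <- function(g) g %in% c("0/0", "1/1", "0|0", "1|1")
    opp <- hom(tab$parent1_gt) & hom(tab$parent2_gt) &
      substr(tab$parent1_gt, 1, 1) != substr(tab$parent2_gt, 1, 1)
    keep <- keep & opp
  }
  out <- tab[keep]
  msgf("filter_variants: %d in, %d pass depth > %g, %d retained",
       n0, n_depth, cfg$min_depth, nrow(out))
  out[position_order(chrom, pos)]
}

#' Per-variant SNP-index and delta(SNP-index)
#'
#' SNP-index of a bulk is alt_depth / (ref_depth + alt_depth), the fraction
#' of reads carrying the heading-parent (ALT) allele; delta is
#' index(bulk A, heading) - index(bulk B, non-heading), in `[-1, 1]`.
#'
#' @param tab filtered variant table; no zero-total-depth rows may remain
#'   (asserted).
#' @return index track data.table: chrom, pos, variant_type, depth_A,
#'   depth_B, index_A, index_B, delta; position-sorted.
#' @export
compute_index <- function(tab) {
  assert_cols(tab, c("chrom", "pos", "bulkA_ref", "bulkA_alt",
                     "bulkB_ref", "bulkB_alt"))
  dA <- tab$bulkA_ref + tab$bulkA_alt
  dB <- tab$bulkB_ref + tab$bulkB_alt
  if (any(dA == 0 | dB == 0))
    stopf("zero-total-depth rows must be filtered out before compute_index")
  out <- data.table(chrom = tab$chrom, pos = tab$pos,
                    variant_type = if ("variant_type" %in% names(tab))
                      tab$variant_type else "SNP",
                    depth_A = dA, depth_B = dB,
                    index_A = tab$bulkA_alt / dA,
                    index_B = tab$bulkB_alt / dB)
  out[, delta := index_A - index_B]
  out[position_order(chrom, pos)]
}

# window centers for one chromosome: regular grid at `step`, spanning the
# chromosome when its length is known, else the marker span
window_centers <- function(pos, cfg, chrom_length = NULL) {
  h <- cfg$window_size / 2
  if (!is.null(chrom_length) && !is.na(chrom_length)) {
    seq(h, max(chrom_length - h, h), by = cfg$step)
  } else {
    seq(min(pos), max(pos), by = cfg$step)
  }
}

# index range [lo, hi] of sorted positions inside [c - w/2, c + w/2)
window_bounds <- function(pos, centers, window_size) {
  h <- window_size / 2
  list(lo = findInterval(centers - h - 0.5, pos) + 1L,
       hi = findInterval(centers + h - 0.5, pos))
}

smooth_track <- function(x, y, span) {
  ok <- !is.na(y)
  n <- sum(ok)
  if (n < 10) return(y)      # too few windows to smooth; identity fallback
  fit <- loess(y[ok] ~ x[ok], span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  out <- y
  out[ok] <- predict(fit, newdata = x[ok])
  out
}

#' Sliding-window scan of a delta(SNP-index) track
#'
#' Per chromosome: windows of `window_size` bp advance by `step`; each
#' window's statistic is the mean delta over the variants inside
#' `[center - w/2, center + w/2)`. Windows with fewer than `min_variants`
#' variants are missing (NA), not zero. A LOESS curve (degree 1, the
#' configured span) is fitted to the non-missing window means per chromosome
#' and evaluated at the same centers.
#'
#' @param track index track from [compute_index()].
#' @param cfg a [scan_config()].
#' @param chrom_lengths optional named vector; when given, windows tile whole
#'   chromosomes instead of the observed marker span.
#' @return window profile data.table: chrom, center, start, end, n_variants,
#'   mean_delta, smoothed. Config is attached as attribute `scan_config`.
#' @export
window_scan <- function(track, cfg = scan_config(), chrom_lengths = NULL) {
  assert_cols(track, c("chrom", "pos", "delta"))
  track <- track[position_order(chrom, pos)]
  chroms <- unique(track$chrom)
  prof <- rbindlist(lapply(chroms, function(cn) {
    tr <- track[chrom == cn]
    if (nrow(tr) == 0) {
      warnf("chromosome %s has no retained variants; profile absent", cn)
      return(NULL)
    }
    centers <- window_centers(tr$pos, cfg, chrom_lengths[cn])
    b <- window_bounds(tr$pos, centers, cfg$window_size)
    n <- pmax(b$hi - b$lo + 1L, 0L)
    cs <- c(0, cumsum(tr$delta))
    mean_delta <- ifelse(n > 0, (cs[b$hi + 1] - cs[b$lo]) / n, NA_real_)
    mean_delta[n < cfg$min_variants] <- NA_real_
    data.table(chrom = cn, center = centers,
               start = centers - cfg$window_size / 2,
               end = centers + cfg$window_size / 2,
               n_variants = n, mean_delta = mean_delta)
  }))
  prof[, smoothed := smooth_track(center, mean_delta, cfg$loess_span),
       by = chrom]
  setattr(prof, "scan_config", cfg)
  prof[]
}

#' Simulated no-QTL null threshold per window
#'
#' Monte-Carlo null in the style of simulated QTL-seq confidence intervals:
#' at each retained variant both bulks' ALT counts are drawn as
#' Binomial(observed depth, 1/2) -- the pooled F2 expectation with no causal
#' locus -- the window-mean delta is recomputed on the same window grid, and
#' the per-window threshold is the `confidence` quantile of |window mean|.
#' The raw quantile track is then LOESS-smoothed with the same settings as
#' the observed track.
#'
#' @param track index track (must carry depth_A / depth_B).
#' @param profile window profile from [window_scan()] on the same track.
#' @param cfg a [threshold_config()].
#' @param scan_cfg the [scan_config()] used for `profile` (defaults to the
#'   attribute attached to it).
#' @return `profile` with columns `threshold_raw` and `threshold` appended
#'   (NA for missing windows).
#' @export
null_threshold <- function(track, profile, cfg = threshold_config(),
                           scan_cfg = attr(profile, "scan_config")) {
  assert_cols(track, c("chrom", "pos", "depth_A", "depth_B"))
  if (is.null(scan_cfg)) stopf("scan_cfg not supplied and not attached")
  track <- track[position_order(chrom, pos)]
  R <- cfg$null_reps
  out <- copy(profile)
  out[, threshold_raw := NA_real_]
  for (cn in unique(out$chrom)) {
    tr <- track[chrom == cn]
    m <- nrow(tr)
    if (m == 0) next
    centers <- out[chrom == cn, center]
    b <- window_bounds(tr$pos, centers, scan_cfg$window_size)
    n <- pmax(b$hi - b$lo + 1L, 0L)
    thr <- withr::with_seed(cfg$seed + match(cn, unique(out$chrom)), {
      dA <- rep(tr$depth_A, each = R)
      dB <- rep(tr$depth_B, each = R)
      sim <- matrix(rbinom(R * m, dA, 0.5) / dA -
                    rbinom(R * m, dB, 0.5) / dB, nrow = R, ncol = m)
      live <- which(n >= scan_cfg$min_variants)
      if (length(live) == 0) rep(NA_real_, length(centers)) else {
        idx <- unlist(lapply(live, function(j) b$lo[j]:b$hi[j]))
        wcol <- rep(seq_along(live), times = n[live])
        W <- Matrix::sparseMatrix(i = idx, j = wcol,
                                  x = 1 / rep(n[live], times = n[live]),
                                  dims = c(m, length(live)))
        wmean <- abs(as.matrix(sim %*% W))
        thr <- rep(NA_real_, length(centers))
        thr[live] <- apply(wmean, 2, quantile, probs = cfg$confidence,
                           names = FALSE)
        thr
      }
    })
    out[chrom == cn, threshold_raw := thr]
  }
  out[, threshold := smooth_track(center, threshold_raw,
                                  scan_cfg$loess_span), by = chrom]
  setattr(out, "scan_config", scan_cfg)
  out[]
}

#' Build a candidate-region table with reported sizes
#'
#' The reporting container behind the region tables: size in Mb is
#' `(end - start) / 1e6` rounded to 2 decimals (raw bp are kept in
#' `size_bp`).
#'
#' @param chrom,start,end region coordinates (bp, 1-based window edges).
#' @param method statistic of origin, e.g. `"SNP-index"` or
#'   `"indel-index"`.
#' @param sign sign of the smoothed delta in the region (+1/-1, NA ok).
#' @param n_genes optional per-region gene counts.
#' @return data.table: chrom, start, end, size_bp, size_mb, method, sign,
#'   n_genes, region_id.
#' @export
region_table <- function(chrom, start, end, method = NA_character_,
                         sign = NA_real_, n_genes = NA_integer_) {
  if (any(start >= end)) stopf("regions must satisfy start < end")
  dt <- data.table(chrom = chrom, start = start, end = end,
                   size_bp = end - start,
                   size_mb = round((end - start) / 1e6, 2),
                   method = method, sign = sign,
                   n_genes = as.integer(n_genes))
  dt[, region_id := sprintf("%s:%d-%d", chrom, as.integer(start),
                            as.integer(end))]
  dt[]
}

#' Call candidate regions from a thresholded window profile
#'
#' Maximal runs of consecutive non-missing windows whose |smoothed delta|
#' exceeds the threshold become regions spanning the outermost window edges.
#' Runs separated by at most one missing window are merged. Peaks of either
#' sign are called (the causal allele may come from either parent).
#'
#' @param profile output of [null_threshold()].
#' @param method method label stored in the region table.
#' @return region table (see [region_table()]); empty when nothing exceeds
#'   the threshold.
#' @export
call_regions <- function(profile, method = "SNP-index") {
  assert_cols(profile, c("chrom", "center", "start", "end", "smoothed",
                         "threshold"))
  res <- list()
  for (cn in unique(profile$chrom)) {
    pr <- profile[chrom == cn]
    missing <- is.na(pr$smoothed) | is.na(pr$threshold)
    exceed <- !missing & abs(pr$smoothed) > pr$threshold
    if (!any(exceed)) next
    r <- rle(exceed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    lo <- starts[r$values]; hi <- ends[r$values]
    # merge runs separated by a single all-missing window
    merged <- list(list(lo = lo[1], hi = hi[1]))
    if (length(lo) > 1) for (k in 2:length(lo)) {
      prev <- merged[[length(merged)]]
      gap <- seq.int(prev$hi + 1L, lo[k] - 1L)
      if (length(gap) <= 1L && all(missing[gap])) {
        merged[[length(merged)]]$hi <- hi[k]
      } else {
        merged[[length(merged) + 1L]] <- list(lo = lo[k], hi = hi[k])
      }
    }
    for (rn in merged) {
      sm <- pr$smoothed[rn$lo:rn$hi]
      res[[length(res) + 1L]] <- region_table(
        chrom = cn, start = pr$start[rn$lo], end = pr$end[rn$hi],
        method = method, sign = base::sign(mean(sm, na.rm = TRUE)))
    }
  }
  if (length(res) == 0)
    return(region_table(character(), numeric(), numeric())[0])
  rbindlist(res)[position_order(chrom, start)]
}

#' Full delta(SNP-index) genome scan of a variant table
#'
#' Filter -> index -> windows -> simulated null threshold -> regions, run
#' separately per variant type (SNPs and small indels, as the two statistics
#' are reported separately) and optionally also on the combined set.
#'
#' @param tab variant table (DNA- or RNA-derived; the statistic is the same).
#' @param filter_cfg,scan_cfg,thr_cfg configuration objects.
#' @param by_type scan SNPs and indels separately (default TRUE); with
#'   FALSE a single combined scan labelled `"combined-index"` is run.
#' @param chrom_lengths optional named chromosome lengths for window tiling.
#' @return list with `profiles` (named list of thresholded window profiles)
#'   and `regions` (one region table, `method` column distinguishing
#'   statistics).
#' @export
bsa_scan <- function(tab, filter_cfg = filter_config(),
                     scan_cfg = scan_config(),
                     thr_cfg = threshold_config(),
                     by_type = TRUE, chrom_lengths = NULL) {
  flt <- filter_variants(tab, filter_cfg)
  sets <- if (by_type) {
    s <- split(flt, flt$variant_type)
    names(s) <- paste0(names(s), "-index")
    s
  } else list("combined-index" = flt)
  profiles <- list()
  regions <- list()
  for (nm in names(sets)) {
    sub <- sets[[nm]]
    if (nrow(sub) == 0) next
    track <- compute_index(sub)
    prof <- window_scan(track, scan_cfg, chrom_lengths)
    prof <- null_threshold(track, prof, thr_cfg, scan_cfg)
    profiles[[nm]] <- prof
    regions[[nm]] <- call_regions(prof, method = nm)
  }
  regions <- if (length(regions)) rbindlist(regions) else
    region_table(character(), numeric(), numeric())[0]
  list(profiles = profiles, regions = regions)
}

#' Plot a scanned chromosome: per-variant deltas, window means and threshold
#'
#' @param track index track.
#' @param profile thresholded window profile.
#' @param chromosome chromosome to draw.
#' @param ... passed to [plot()].
#' @return invisible NULL; draws on the active device.
#' @export
plot_scan <- function(track, profile, chromosome, ...) {
  tr <- track[chrom == chromosome]
  pr <- profile[chrom == chromosome]
  plot(tr$pos / 1e6, tr$delta, pch = 16, cex = 0.4,
       col = "grey60", ylim = c(-1, 1),
       xlab = sprintf("%s position (Mb)", chromosome),
       ylab = expression(Delta * "(SNP-index)"), ...)
  graphics::lines(pr$center / 1e6, pr$smoothed, lwd = 2)
  if ("threshold" %in% names(pr)) {
    graphics::lines(pr$center / 1e6, pr$threshold, col = "red", lty = 2)
    graphics::lines(pr$center / 1e6, -pr$threshold, col = "red", lty = 2)
  }
  graphics::abline(h = 0, col = "grey80")
  invisible(NULL)
}
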