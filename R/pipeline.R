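#' Build a run configuration
#'
#' One object (or JSON file) drives a whole conjunctive run. All
#' field-standard constants surface here as defaults -- depth > 5x,
#' 99% confidence, dispersion 0.1, |log2FC| >= 1, FDR < 0.05 -- nothing is
#' hard-coded downstream.
#'
#' @param bsa_vcf DNA-bulk VCF path (required for the BSA scan).
#' @param gff3 gene-model GFF3 path (required).
#' @param out_dir output directory (required).
#' @param bsr_vcf optional RNA-bulk VCF path; enables the BSR scan and the
#'   conjunctive intersection.
#' @param counts optional counts TSV for between-bulk DEG calling.
#' @param qpcr optional qPCR Ct TSV.
#' @param roles sample-role mapping passed to [read_variant_vcf()].
#' @param reference_gene,calibrator_sample,calibrator_part qPCR settings.
#' @param filter,scan,threshold,deg configuration objects.
#' @param seed integer master seed recorded in the manifest; the null
#'   threshold seed derives from it.
#' @param chrom_lengths optional named vector for window tiling.
#' @return object of class `run_config`.
#' @export
run_config <- function(bsa_vcf, gff3, out_dir, bsr_vcf = NULL,
                       counts = NULL, qpcr = NULL,
                       roles = c(parent1 = "R01", parent2 = "R02",
                                 bulkA = "R03", bulkB = "R04"),
                       reference_gene = NULL, calibrator_sample = NULL,
                       calibrator_part = NULL,
                       filter = filter_config(), scan = scan_config(),
                       threshold = threshold_config(), deg = deg_config(),
                       seed = 1L, chrom_lengths = NULL) {
  cfg <- list(bsa_vcf = bsa_vcf, bsr_vcf = bsr_vcf, gff3 = gff3,
              counts = counts, qpcr = qpcr, out_dir = out_dir,
              roles = roles, reference_gene = reference_gene,
              calibrator_sample = calibrator_sample,
              calibrator_part = calibrator_part,
              filter = filter, scan = scan, threshold = threshold,
              deg = deg, seed = as.integer(seed),
              chrom_lengths = chrom_lengths)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from JSON
#'
#' @param path JSON file whose top-level fields mirror [run_config()]
#'   arguments; nested `filter`/`scan`/`threshold`/`deg` objects hold the
#'   corresponding config fields. Relative paths are resolved against the
#'   JSON file's directory.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || grepl("^/", p)) p else
    file.path(base, p)
  mk <- function(ctor, args) do.call(ctor, as.list(args %||% list()))
  run_config(
    bsa_vcf = rel(j$bsa_vcf), gff3 = rel(j$gff3), out_dir = rel(j$out_dir),
    bsr_vcf = rel(j$bsr_vcf), counts = rel(j$counts), qpcr = rel(j$qpcr),
    roles = if (!is.null(j$roles)) unlist(j$roles) else
      c(parent1 = "R01", parent2 = "R02", bulkA = "R03", bulkB = "R04"),
    reference_gene = j$reference_gene,
    calibrator_sample = j$calibrator_sample,
    calibrator_part = j$calibrator_part,
    filter = mk(filter_config, j$filter),
    scan = mk(scan_config, j$scan),
    threshold = mk(threshold_config, j$threshold),
    deg = mk(deg_config, j$deg),
    seed = j$seed %||% 1L,
    chrom_lengths = if (!is.null(j$chrom_lengths)) unlist(j$chrom_lengths))
}

validate_run_config <- function(cfg) {
  need <- c(bsa_vcf = cfg$bsa_vcf, gff3 = cfg$gff3)
  opt <- c(bsr_vcf = cfg$bsr_vcf, counts = cfg$counts, qpcr = cfg$qpcr)
  paths <- c(need, opt[!vapply(opt, is.null, logical(1))])
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing))
    stopf("input path(s) do not exist: %s",
          paste(sprintf("%s=%s", names(missing), missing), collapse = ", "))
  invisible(cfg)
}

#' Run the conjunctive bulked-segregant pipeline
#'
#' Stages: read inputs -> delta(SNP-index) scan of the DNA bulks (BSA) and,
#' when provided, of the RNA bulks (BSR) -> gene annotation of candidate
#' regions -> conjunctive intersection -> DEG calling -> qPCR relative
#' quantification. All stage tables are written as TSV under `out_dir`
#' together with a deterministic JSON manifest (config echo, seed, per-stage
#' row counts, package version). Same config + seed gives byte-identical
#' outputs.
#'
#' @param cfg a [run_config()] or path to a JSON run configuration.
#' @return invisible list with the manifest and all in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  thr <- cfg$threshold
  thr$seed <- cfg$seed
  counts_log <- list()
  res <- list()

  genes <- read_gff3(cfg$gff3)
  counts_log$genes <- nrow(genes)

  scan_one <- function(vcf_path, label) {
    tab <- read_variant_vcf(vcf_path, cfg$roles)
    counts_log[[paste0(label, "_variants_in")]] <<- nrow(tab)
    sc <- bsa_scan(tab, cfg$filter, cfg$scan, thr,
                   chrom_lengths = cfg$chrom_lengths)
    counts_log[[paste0(label, "_regions")]] <<- nrow(sc$regions)
    set <- genes_in_regions(sc$regions, genes, source = label)
    for (nm in names(sc$profiles))
      fwrite(sc$profiles[[nm]],
             file.path(cfg$out_dir,
                       sprintf("profile_%s_%s.tsv", label,
                               gsub("-index", "", nm))), sep = "\t")
    regs <- attr(set, "regions")
    fwrite(regs, file.path(cfg$out_dir,
                           sprintf("regions_%s.tsv", label)), sep = "\t")
    fwrite(set, file.path(cfg$out_dir,
                          sprintf("genes_%s.tsv", label)), sep = "\t")
    list(scan = sc, genes = set)
  }

  res$bsa <- scan_one(cfg$bsa_vcf, "BSA")
  if (!is.null(cfg$bsr_vcf)) {
    res$bsr <- scan_one(cfg$bsr_vcf, "BSR")
    res$conjunctive <- conjunctive_intersect(res$bsa$genes, res$bsr$genes)
    counts_log$conjunctive_genes <- nrow(res$conjunctive)
    fwrite(res$conjunctive, file.path(cfg$out_dir, "conjunctive.tsv"),
           sep = "\t")
  }
  if (!is.null(cfg$counts)) {
    cm <- read_counts_tsv(cfg$counts)
    res$deg <- call_degs(cm$counts, cfg$deg)
    if (!is.null(cm$lengths)) {
      fk <- fpkm(cm$counts, cm$lengths[rownames(cm$counts)])
      res$deg[, `:=`(fpkm_a = fk[, 1], fpkm_b = fk[, 2])]
    }
    counts_log$deg_total <- deg_summary(res$deg)$total_de
    fwrite(res$deg, file.path(cfg$out_dir, "deg.tsv"), sep = "\t")
  }
  if (!is.null(cfg$qpcr)) {
    if (is.null(cfg$reference_gene) || is.null(cfg$calibrator_sample) ||
        is.null(cfg$calibrator_part))
      stopf("qPCR input requires reference_gene, calibrator_sample and calibrator_part")
    panel <- read_qpcr_tsv(cfg$qpcr)
    res$qpcr <- ddct(panel, cfg$reference_gene, cfg$calibrator_sample,
                     cfg$calibrator_part)
    fwrite(res$qpcr, file.path(cfg$out_dir, "qpcr_relative.tsv"),
           sep = "\t")
  }

  manifest <- list(
    package = "bulkmapr",
    version = as.character(packageVersion("bulkmapr")),
    seed = cfg$seed,
    config = lapply(cfg[c("bsa_vcf", "bsr_vcf", "gff3", "counts", "qpcr",
                          "roles", "filter", "scan", "threshold", "deg",
                          "chrom_lengths")],
                    function(x) if (is.object(x)) unclass(x) else x),
    counts = counts_log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  res$manifest <- manifest
  invisible(res)
}
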