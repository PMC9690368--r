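#' Scan one contrast for selection signatures
#'
#' The in-memory core of the pipeline: computes the three per-SNP
#' statistics (Weir-Cockerham Fst, normalized XP-EHH, log2 theta-pi
#' ratio), calls the empirical top-\code{q} outliers of each (XP-EHH over
#' positive values only), intersects them, and builds merged
#' flank-window candidate regions for both tiers: \code{"2way"}
#' (Fst with XP-EHH) and \code{"3way"} (adding the diversity ratio).
#' Optionally annotates the regions with gene models.
#'
#' @param x a QC-filtered, phased \code{HaplotypeMatrix}.
#' @param contrast a \code{GroupContrast}.
#' @param genes optional \code{GRanges} of gene models (see
#'   \code{\link{readGeneModels}}).
#' @param q top-tail fraction (default 0.01).
#' @param flank flanking-window half-width in bp (default 5000).
#' @param maxGap,cutoff XP-EHH integration parameters.
#' @param mode \code{"3way"} (default; both tiers computed) or
#'   \code{"2way"} (Fst/XP-EHH tier only).
#' @return list with elements \code{stats} (merged per-SNP data.frame),
#'   \code{outliers} (list of \code{OutlierSet}), \code{snps2way},
#'   \code{snps3way} (variant indices), \code{regions2way},
#'   \code{regions3way} (\code{GRanges} with \code{contrast},
#'   \code{support}, \code{source_snps} and, when genes are given,
#'   \code{genes} columns).
#' @export
scanContrast <- function(x, contrast, genes = NULL, q = 0.01, flank = 5000,
                         maxGap = 200000, cutoff = 0.05,
                         mode = c("3way", "2way")) {
  mode <- match.arg(mode)
  fst <- fstScan(x, contrast)
  xp <- normalizeXpehh(xpehhScan(x, contrast, maxGap = maxGap,
                                 cutoff = cutoff))
  pi <- piRatioScan(x, contrast)
  stats <- data.frame(
    chrom = fst$chrom, pos = fst$pos,
    fst_raw = fst$fst_raw, fst = fst$fst,
    ihh_test = xp$ihh_test, ihh_control = xp$ihh_control,
    xpehh_raw = xp$xpehh_raw, xpehh_norm = xp$xpehh_norm,
    pi_test = pi$pi_test, pi_control = pi$pi_control,
    log2_ratio = pi$log2_ratio,
    stringsAsFactors = FALSE)

  outliers <- list(
    fst = topQuantile(stats$fst, q = q, statistic = "fst"),
    xpehh = topQuantile(stats$xpehh_norm, q = q, positiveOnly = TRUE,
                        statistic = "xpehh"),
    pi_ratio = topQuantile(stats$log2_ratio, q = q, statistic = "pi_ratio"))

  bounds <- x@metadata$contigLengths
  buildRegions <- function(idx, support) {
    r <- snpsToRegions(stats$chrom[idx], stats$pos[idx], flank = flank,
                       chromBounds = bounds)
    if (length(r)) {
      S4Vectors::mcols(r)$contrast <- contrast@name
      S4Vectors::mcols(r)$support <- support
    }
    if (!is.null(genes)) r <- annotateRegions(r, genes)
    r
  }
  snps2 <- intersectOutliers(outliers[c("fst", "xpehh")])
  regions2 <- buildRegions(snps2, "2way")
  snps3 <- NULL; regions3 <- NULL
  if (mode == "3way") {
    snps3 <- intersectOutliers(outliers)
    regions3 <- buildRegions(snps3, "3way")
  }
  list(stats = stats, outliers = outliers,
       snps2way = snps2, snps3way = snps3,
       regions2way = regions2, regions3way = regions3)
}

#' Pipeline configuration
#'
#' Bundles the input paths and all tunable parameters of a full run.
#'
#' @param vcf phased multi-sample VCF path.
#' @param groups group-table TSV path (see \code{\link{readGroupContrasts}}).
#' @param gff optional GFF3 gene-model path.
#' @param outDir output directory.
#' @param qc a \code{QcConfig}.
#' @param maxGap,cutoff XP-EHH parameters (defaults 200000 bp, 0.05).
#' @param q top-tail fraction in (0, 0.5) (default 0.01).
#' @param flank candidate-region flank in bp (default 5000).
#' @param mode \code{"3way"} or \code{"2way"}.
#' @param seed seed for any stochastic step (recorded in the manifest).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(vcf, groups, gff = NULL, outDir,
                           qc = qcConfig(), maxGap = 200000, cutoff = 0.05,
                           q = 0.01, flank = 5000,
                           mode = c("3way", "2way"), seed = 1) {
  mode <- match.arg(mode)
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  if (flank < 0) stop("flank must be >= 0")
  structure(list(vcf = vcf, groups = groups, gff = gff, outDir = outDir,
                 qc = qc, maxGap = maxGap, cutoff = cutoff, q = q,
                 flank = flank, mode = mode, seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; QC thresholds
#' live under a \code{qc} block (\code{maf_min}, \code{max_missing},
#' \code{hwe_p_min}, \code{autosome_labels}).
#'
#' @param path YAML file.
#' @return A \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  qc <- qcConfig(
    mafMin = y$qc$maf_min %||% 0.05,
    maxMissing = y$qc$max_missing %||% 0,
    hwePMin = y$qc$hwe_p_min %||% 1e-6,
    autosomeLabels = as.character(y$qc$autosome_labels %||% character()))
  pipelineConfig(
    vcf = y$vcf, groups = y$groups, gff = y$gff, outDir = y$out_dir,
    qc = qc,
    maxGap = y$max_gap %||% 200000, cutoff = y$cutoff %||% 0.05,
    q = y$q %||% 0.01, flank = y$flank %||% 5000,
    mode = y$mode %||% "3way", seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full selection-signature pipeline
#'
#' QC, the three statistics, outlier intersection, candidate regions and
#' gene annotation for every contrast in the group table, written as TSV,
#' BED and a machine-readable run manifest. Identical configuration gives
#' byte-identical outputs.
#'
#' @param cfg a \code{PipelineConfig}.
#' @return the output directory path, invisibly; files written:
#'   \code{qc_report.tsv}, per-contrast \code{stats_<contrast>.tsv},
#'   \code{regions_<tier>_<contrast>.tsv/.bed}, and \code{manifest.json}.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)

  hm <- stage("read_vcf", readHaplotypes(cfg$vcf, requirePhased = TRUE))
  contrasts <- stage("read_groups", readGroupContrasts(cfg$groups, hm))
  genes <- if (!is.null(cfg$gff)) stage("read_gff", readGeneModels(cfg$gff))

  qcRes <- stage("qc", applyQc(hm, cfg$qc))
  write.table(as.data.frame(qcRes$report),
              file.path(cfg$outDir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  hm <- qcRes$matrix
  message(sprintf("QC: retained %d of %d variants",
                  qcRes$report@nRetained, qcRes$report@nInput))

  manifest <- list(
    package = "haploSweep",
    version = as.character(packageVersion("haploSweep")),
    seed = cfg$seed,
    inputs = list(vcf = cfg$vcf, groups = cfg$groups, gff = cfg$gff),
    parameters = list(
      qc = list(maf_min = cfg$qc@mafMin, max_missing = cfg$qc@maxMissing,
                hwe_p_min = cfg$qc@hwePMin,
                autosome_labels = cfg$qc@autosomeLabels),
      max_gap = cfg$maxGap, cutoff = cfg$cutoff, q = cfg$q,
      flank = cfg$flank, mode = cfg$mode),
    qc_report = setNames(as.list(as.data.frame(qcRes$report)$count),
                         as.data.frame(qcRes$report)$step),
    contrasts = list())

  for (cn in names(contrasts)) {
    res <- stage(paste0("scan_", cn),
                 scanContrast(hm, contrasts[[cn]], genes = genes,
                              q = cfg$q, flank = cfg$flank,
                              maxGap = cfg$maxGap, cutoff = cfg$cutoff,
                              mode = cfg$mode))
    statsPath <- file.path(cfg$outDir, sprintf("stats_%s.tsv", cn))
    write.table(.formatStats(res$stats), statsPath, sep = "\t",
                quote = FALSE, row.names = FALSE, na = "NA")
    tiers <- list(`2way` = res$regions2way)
    if (cfg$mode == "3way") tiers$`3way` <- res$regions3way
    for (tier in names(tiers)) {
      r <- tiers[[tier]]
      base <- file.path(cfg$outDir, sprintf("regions_%s_%s", tier, cn))
      write.table(regionTable(r), paste0(base, ".tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      writeRegionsBed(r, paste0(base, ".bed"))
    }
    manifest$contrasts[[cn]] <- list(
      n_test = length(contrasts[[cn]]@testSamples),
      n_control = length(contrasts[[cn]]@controlSamples),
      thresholds = lapply(res$outliers, function(o)
        list(statistic = o@statistic, threshold = o@threshold,
             n_eligible = o@nEligible, n_outliers = length(o@indices))),
      n_snps_2way = length(res$snps2way),
      n_snps_3way = if (is.null(res$snps3way)) NULL else length(res$snps3way),
      n_regions_2way = length(res$regions2way),
      n_regions_3way = if (is.null(res$regions3way)) NULL else
        length(res$regions3way))
    message(sprintf(
      "contrast %s: %d two-way SNPs -> %d regions%s", cn,
      length(res$snps2way), length(res$regions2way),
      if (cfg$mode == "3way")
        sprintf("; %d three-way SNPs -> %d regions",
                length(res$snps3way), length(res$regions3way)) else ""))
  }
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(cfg$outDir)
}

# fixed-precision formatting so output bytes are reproducible and
# locale-independent
.formatStats <- function(df) {
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "pos"
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.6g", x)))
  df
}

#' Assign samples to contrast groups from phenotype records
#'
#' Encodes the phenotype-threshold rules used to build the contrasts:
#' \itemize{
#'   \item \code{pelt_size}: females only; pelt length > 77 cm is the test
#'     (large) group, < 59 cm the control (small) group, in between is
#'     excluded; males are excluded.
#'   \item \code{nap_size}: nap category (1 = extra short ... 8 =
#'     medium-long) at most \code{napShortMax} is the test (short) group,
#'     at least \code{napLongMin} the control (long) group.
#'   \item \code{fur_quality}: numeric grade at least \code{furHighMin} is
#'     test (high), at most \code{furLowMax} control (low); alternatively a
#'     character column of \code{"high"}/\code{"low"}.
#'   \item \code{color}: two contrasts, each with black as control —
#'     \code{Pastel_Black} (pastel = test) and \code{Stardust_Black}
#'     (stardust = test).
#' }
#'
#' @param records data.frame with columns \code{sample_id}, \code{sex}
#'   (for pelt size) and the trait columns \code{pelt_length_cm},
#'   \code{nap_category}, \code{fur_quality}, \code{color} as available.
#' @param trait one of \code{"pelt_size"}, \code{"nap_size"},
#'   \code{"fur_quality"}, \code{"color"}.
#' @param peltLargeMin,peltSmallMax pelt-length thresholds in cm
#'   (exclusive: > 77 / < 59).
#' @param napShortMax,napLongMin nap-category cutoffs (defaults 2 and 6;
#'   intermediate categories are excluded).
#' @param furHighMin,furLowMax fur-quality grade cutoffs.
#' @return A \code{GroupContrast}, or for \code{trait = "color"} a named
#'   list of two (\code{Pastel_Black}, \code{Stardust_Black}).
#' @export
assignGroups <- function(records, trait = c("pelt_size", "nap_size",
                                            "fur_quality", "color"),
                         peltLargeMin = 77, peltSmallMax = 59,
                         napShortMax = 2, napLongMin = 6,
                         furHighMin = NULL, furLowMax = NULL) {
  trait <- match.arg(trait)
  needCol <- function(col) {
    if (!col %in% names(records))
      stop(sprintf("trait '%s' requires column '%s'", trait, col))
    records[[col]]
  }
  mk <- function(name, test, ctrl) {
    if (!length(test) || !length(ctrl))
      stop(sprintf("contrast '%s': empty %s group", name,
                   if (!length(test)) "test" else "control"))
    GroupContrast(name, test, ctrl)
  }
  id <- needCol("sample_id")
  switch(trait,
    pelt_size = {
      len <- needCol("pelt_length_cm")
      sex <- needCol("sex")
      female <- tolower(sex) %in% c("f", "female")
      mk("pelt_size",
         id[female & !is.na(len) & len > peltLargeMin],
         id[female & !is.na(len) & len < peltSmallMax])
    },
    nap_size = {
      cat <- needCol("nap_category")
      if (any(!is.na(cat) & (cat < 1 | cat > 8)))
        stop("nap_category must be in 1..8")
      mk("nap_size",
         id[!is.na(cat) & cat <= napShortMax],
         id[!is.na(cat) & cat >= napLongMin])
    },
    fur_quality = {
      fq <- needCol("fur_quality")
      if (is.character(fq) || is.factor(fq)) {
        fq <- tolower(as.character(fq))
        mk("fur_quality", id[fq == "high"], id[fq == "low"])
      } else {
        if (is.null(furHighMin) || is.null(furLowMax))
          stop("numeric fur_quality grades need furHighMin and furLowMax cutoffs")
        mk("fur_quality",
           id[!is.na(fq) & fq >= furHighMin],
           id[!is.na(fq) & fq <= furLowMax])
      }
    },
    color = {
      col <- tolower(needCol("color"))
      black <- id[col == "black"]
      list(
        Pastel_Black = mk("Pastel_Black", id[col == "pastel"], black),
        Stardust_Black = mk("Stardust_Black", id[col == "stardust"], black))
    })
}
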