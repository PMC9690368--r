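#' Simulation configuration
#'
#' Parameters of the two-population synthetic haplotype generator. The
#' defaults describe the benchmark scenario used throughout the package's
#' validation: 15 + 15 diploid individuals, two 25-Mb chromosomes with
#' 2,500 SNPs each, founder-mosaic background LD, and one hard sweep
#' (carrier frequency 0.9 over a 500-kb span) planted in the test group of
#' chromosome 1.
#'
#' Background haplotypes are mosaics of a small founder pool: each
#' haplotype walks along the chromosome copying one founder and switches
#' founders with probability \code{switchRate} per site, which creates
#' block-wise LD with directly controllable scale. Site allele frequencies
#' in the founder pool are uniform on \code{freqRange}. The sweep replaces
#' the chosen fraction of test-group haplotypes over the sweep span with
#' one fixed carrier haplotype, creating long shared homozygosity and
#' allele-frequency differentiation.
#'
#' QC-violating sites can be planted at recorded indices: low-MAF
#' singletons, sites with a missing genotype call, and
#' Hardy-Weinberg-violating sites built as all-homozygote half/half
#' columns (zero heterozygotes at allele frequency 0.5, which the exact
#' test flags at any reasonable sample size). All remaining sites are
#' guaranteed to pass the default QC thresholds by a deterministic repair
#' pass, so planted counts are recovered exactly by
#' \code{\link{applyQc}}.
#'
#' @param seed RNG seed (all randomness flows from it; same seed, same
#'   output bytes).
#' @param nTest,nControl diploid individuals per group.
#' @param nChrom number of chromosomes.
#' @param chromLength chromosome length in bp.
#' @param nSnpsPerChrom SNPs per chromosome.
#' @param nFounders founder haplotypes behind the mosaic model.
#' @param switchRate per-site founder-switch probability (LD scale:
#'   expected block length is \code{1 / switchRate} sites).
#' @param freqRange range of founder-pool allele frequencies.
#' @param sweep \code{NULL} for a neutral genome, or a list with elements
#'   \code{chrom}, \code{pos}, \code{carrierFreq} (fraction of test-group
#'   haplotypes carrying the sweep haplotype, in (0, 1]), \code{span} (bp).
#' @param plantLowMaf,plantMissing,plantHwe counts of planted QC-violating
#'   sites.
#' @param qcGuarantee a \code{QcConfig}; non-planted sites are repaired to
#'   pass these thresholds.
#' @return list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1,
                      nTest = 15, nControl = 15,
                      nChrom = 2, chromLength = 25e6, nSnpsPerChrom = 2500,
                      nFounders = 8, switchRate = 0.05,
                      freqRange = c(0.1, 0.9),
                      sweep = list(chrom = "chr1", pos = chromLength / 2,
                                   carrierFreq = 0.9, span = 500000),
                      plantLowMaf = 0, plantMissing = 0, plantHwe = 0,
                      qcGuarantee = qcConfig()) {
  stopifnot(nTest >= 2, nControl >= 2, nChrom >= 1, chromLength > 0,
            nSnpsPerChrom >= 10, nFounders >= 2,
            switchRate > 0, switchRate < 1,
            length(freqRange) == 2, freqRange[1] > 0, freqRange[2] < 1,
            plantLowMaf >= 0, plantMissing >= 0, plantHwe >= 0)
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep),
              all(c("chrom", "pos", "carrierFreq", "span") %in% names(sweep)),
              sweep$carrierFreq > 0, sweep$carrierFreq <= 1,
              sweep$pos >= 1, sweep$pos <= chromLength)
  }
  nPlanted <- plantLowMaf + plantMissing + plantHwe
  if (nPlanted > nChrom * nSnpsPerChrom / 2)
    stop("more planted QC violations than available sites")
  structure(as.list(environment()), class = "SimConfig")
}

#' Simulate a two-population genome with an optional planted sweep
#'
#' Generates phased haplotypes under the founder-mosaic model of
#' \code{\link{simConfig}}, plants the sweep and the QC violations, tiles
#' toy gene models across the chromosomes (with one gene centered on the
#' sweep), and returns the ground truth needed for recovery tests. Fully
#' deterministic given \code{cfg$seed}.
#'
#' @param cfg a \code{SimConfig}.
#' @return list with elements \code{haplotypes}
#'   (\linkS4class{HaplotypeMatrix}), \code{contrast}
#'   (\linkS4class{GroupContrast}), \code{genes} (\code{GRanges}),
#'   \code{truth} (list: sweep coordinates/interval/carrier rows, planted
#'   variant indices and counts).
#' @export
simulateSweepData <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  nHap <- 2L * (cfg$nTest + cfg$nControl)
  chroms <- paste0("chr", seq_len(cfg$nChrom))

  alleleBlocks <- vector("list", cfg$nChrom)
  posBlocks <- vector("list", cfg$nChrom)
  carrierBlocks <- vector("list", cfg$nChrom)
  for (ci in seq_len(cfg$nChrom)) {
    m <- cfg$nSnpsPerChrom
    pos <- sort(sample.int(cfg$chromLength - 2L, m)) + 1L
    p <- runif(m, cfg$freqRange[1], cfg$freqRange[2])
    founders <- matrix(rbinom(cfg$nFounders * m, 1L, rep(p, each = cfg$nFounders)),
                       nrow = cfg$nFounders)
    mosaic <- function() {
      sw <- c(TRUE, runif(m - 1L) < cfg$switchRate)
      seg <- cumsum(sw)
      path <- sample.int(cfg$nFounders, max(seg), replace = TRUE)[seg]
      founders[cbind(path, seq_len(m))]
    }
    haps <- matrix(0L, nrow = nHap, ncol = m)
    for (h in seq_len(nHap)) haps[h, ] <- mosaic()
    carrierBlocks[[ci]] <- mosaic()
    alleleBlocks[[ci]] <- haps
    posBlocks[[ci]] <- pos
  }
  alleles <- do.call(cbind, alleleBlocks)
  vchrom <- rep(chroms, each = cfg$nSnpsPerChrom)
  vpos <- unlist(posBlocks, use.names = FALSE)

  testIds <- sprintf("T%02d", seq_len(cfg$nTest))
  ctrlIds <- sprintf("C%02d", seq_len(cfg$nControl))
  testHapRows <- seq_len(2L * cfg$nTest)

  ## --- sweep ---
  truthSweep <- NULL
  carrierRows <- integer()
  sweepCols <- integer()
  if (!is.null(cfg$sweep)) {
    sw <- cfg$sweep
    ci <- match(sw$chrom, chroms)
    if (is.na(ci)) stop("sweep chromosome not in the simulated genome")
    lo <- sw$pos - sw$span / 2
    hi <- sw$pos + sw$span / 2
    inSpan <- which(vchrom == sw$chrom & vpos >= lo & vpos <= hi)
    nCarrier <- max(2L, round(sw$carrierFreq * 2L * cfg$nTest))
    nCarrier <- min(nCarrier, 2L * cfg$nTest)
    carrierRows <- sort(sample(testHapRows, nCarrier))
    carrier <- carrierBlocks[[ci]]
    local <- match(inSpan, which(vchrom == sw$chrom))
    alleles[carrierRows, inSpan] <-
      matrix(carrier[local], nrow = nCarrier, ncol = length(inSpan),
             byrow = TRUE)
    sweepCols <- inSpan
    truthSweep <- list(chrom = sw$chrom, pos = sw$pos, span = sw$span,
                       carrierFreq = sw$carrierFreq,
                       carrierRows = carrierRows,
                       interval = c(max(1, floor(lo)),
                                    min(cfg$chromLength, ceiling(hi))),
                       nSweepSnps = length(inSpan))
  }

  ## --- planted QC violations (kept away from the sweep span) ---
  mTot <- length(vpos)
  eligible <- setdiff(seq_len(mTot), sweepCols)
  nPlant <- cfg$plantLowMaf + cfg$plantMissing + cfg$plantHwe
  planted <- if (nPlant) sort(sample(eligible, nPlant)) else integer()
  idxLowMaf <- head(planted, cfg$plantLowMaf)
  idxMissing <- planted[cfg$plantLowMaf + seq_len(cfg$plantMissing)]
  idxHwe <- tail(planted, cfg$plantHwe)
  for (i in idxLowMaf) {
    col <- rep(0L, nHap)
    col[sample.int(nHap, 1L)] <- 1L
    alleles[, i] <- col
  }
  for (i in idxMissing) {
    s <- sample.int(cfg$nTest + cfg$nControl, 1L)
    alleles[c(2L * s - 1L, 2L * s), i] <- NA_integer_
  }
  nInd <- cfg$nTest + cfg$nControl
  for (i in idxHwe) {
    gt <- rep(c(1L, 0L), length.out = nInd)     # alternate alt-hom / ref-hom
    alleles[, i] <- rep(gt, each = 2L)
  }

  ## --- repair pass: non-planted sites must pass the guaranteed QC ---
  alleles <- .repairBackground(alleles, vchrom, vpos, planted,
                               sweepCols, carrierRows, cfg$qcGuarantee,
                               nInd)

  variants <- data.frame(
    chrom = vchrom, pos = vpos,
    ref = "A", alt = "G",
    id = sprintf("snp_%s_%d", vchrom, vpos),
    stringsAsFactors = FALSE)
  hm <- HaplotypeMatrix(
    alleles, variants, c(testIds, ctrlIds), phased = TRUE,
    metadata = list(contigLengths = setNames(rep(as.integer(cfg$chromLength),
                                                 cfg$nChrom), chroms)))

  ## --- toy gene models ---
  genes <- .tileGenes(chroms, cfg$chromLength, truthSweep)

  truth <- list(
    sweep = truthSweep,
    planted = list(low_maf = idxLowMaf, missing = idxMissing, hwe = idxHwe),
    counts = list(low_maf = length(idxLowMaf), missing = length(idxMissing),
                  hwe = length(idxHwe)),
    sweep_gene_id = if (is.null(truthSweep)) NULL else "gene_sweep")

  list(haplotypes = hm,
       contrast = GroupContrast("sim_contrast", testIds, ctrlIds,
                                description = "simulated test vs control"),
       genes = genes,
       truth = truth)
}

# Deterministically nudge non-planted sites so that realized MAF and the
# pooled exact HWE p-value clear the guaranteed thresholds, without ever
# touching carrier haplotypes inside the sweep span. MAF is raised by
# flipping majority alleles on modifiable rows (one per individual where
# possible); HWE deviations are fixed by allele swaps between individuals,
# which preserve allele counts and therefore MAF.
.repairBackground <- function(alleles, vchrom, vpos, planted, sweepCols,
                              carrierRows, qc, nInd) {
  nHap <- nrow(alleles)
  mafTarget <- ceiling(qc@mafMin * nHap - 1e-9)
  for (i in setdiff(seq_len(ncol(alleles)), planted)) {
    frozen <- if (i %in% sweepCols) carrierRows else integer()
    col <- alleles[, i]
    ## MAF
    cnt <- sum(col)
    minor <- min(cnt, nHap - cnt)
    if (minor < mafTarget) {
      majAllele <- if (cnt > nHap - cnt) 1L else 0L
      cand <- setdiff(which(col == majAllele), frozen)
      ## prefer at most one haplotype per individual
      ind <- (cand + 1L) %/% 2L
      cand <- c(cand[!duplicated(ind)], cand[duplicated(ind)])
      need <- mafTarget - minor
      if (length(cand) < need)
        stop("cannot repair MAF at simulated site ", i)
      col[cand[seq_len(need)]] <- 1L - majAllele
    }
    ## HWE (swaps preserve allele counts)
    g1 <- col[seq(1L, nHap, by = 2L)]
    g2 <- col[seq(2L, nHap, by = 2L)]
    frozenInd <- unique((frozen + 1L) %/% 2L)
    modInd <- setdiff(seq_len(nInd), frozenInd)
    for (iter in seq_len(200L)) {
      g <- g1 + g2
      p <- hweExactTest(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      if (p >= qc@hwePMin) break
      nA <- 2L * sum(g == 0L) + sum(g == 1L)
      na <- 2L * sum(g == 2L) + sum(g == 1L)
      expHet <- nA * na / (nA + na - 1)  # conditional expectation of het count
      if (sum(g == 1L) < expHet) {
        aa <- intersect(which(g == 0L), modInd)
        bb <- intersect(which(g == 2L), modInd)
        if (!length(aa) || !length(bb)) break
        g1[aa[1L]] <- 1L; g2[aa[1L]] <- 0L
        g1[bb[1L]] <- 0L; g2[bb[1L]] <- 1L
      } else {
        het <- intersect(which(g == 1L), modInd)
        if (length(het) < 2L) break
        g1[het[1L]] <- 0L; g2[het[1L]] <- 0L
        g1[het[2L]] <- 1L; g2[het[2L]] <- 1L
      }
    }
    col[seq(1L, nHap, by = 2L)] <- g1
    col[seq(2L, nHap, by = 2L)] <- g2
    alleles[, i] <- col
  }
  alleles
}

.tileGenes <- function(chroms, chromLength, truthSweep) {
  width <- 20000
  step <- 250000
  starts <- seq(100000, chromLength - width, by = step)
  df <- data.frame(
    chrom = rep(chroms, each = length(starts)),
    start = rep(starts, length(chroms)),
    gene_id = sprintf("gene_%s_%03d",
                      rep(chroms, each = length(starts)),
                      rep(seq_along(starts), length(chroms))),
    stringsAsFactors = FALSE)
  widths <- rep(width, nrow(df))
  if (!is.null(truthSweep)) {
    # the sweep gene covers the whole swept haplotype span
    df <- rbind(df, data.frame(chrom = truthSweep$chrom,
                               start = max(1, truthSweep$pos -
                                             truthSweep$span / 2),
                               gene_id = "gene_sweep"))
    widths <- c(widths, truthSweep$span)
  }
  genes <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start, width = widths),
                                  gene_id = df$gene_id)
  sort(genes)
}

#' Write a simulated dataset as pipeline-ready files
#'
#' Emits a plain-text VCF, a group table, a GFF3 of the toy gene models and
#' a JSON ground-truth file into \code{dir}.
#'
#' @param sim output of \code{\link{simulateSweepData}}.
#' @param dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "sim.vcf"),
    groups = file.path(dir, "groups.tsv"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.json"))
  writeHaplotypesVcf(sim$haplotypes, paths[["vcf"]])
  writeGroupContrasts(list(sim$contrast), paths[["groups"]])
  writeGeneModels(sim$genes, paths[["gff"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(paths)
}
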