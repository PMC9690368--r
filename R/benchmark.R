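#' Sweep-recovery benchmark on simulated genomes
#'
#' Runs the full scan (QC, three statistics, three-way top-tail
#' intersection, candidate regions) on one simulated genome per seed and
#' scores recovery: for sweep genomes, whether a three-way candidate
#' region lands within \code{window} bp of the planted sweep position; for
#' neutral genomes, whether the three-way tier stays clean (no
#' "concentrated" region, i.e. none built from more than
#' \code{maxNullSnps} merged windows).
#'
#' @param seeds integer vector of simulation seeds.
#' @param sweep \code{TRUE} to plant the default sweep of
#'   \code{\link{simConfig}}, \code{FALSE} for neutral genomes.
#' @param window recovery tolerance around the sweep position in bp
#'   (default 1e6).
#' @param maxNullSnps largest source-SNP count a neutral three-way region
#'   may have before it counts as a (spurious) concentrated signal.
#' @param cfgFun function(seed) returning a \code{SimConfig}; defaults to
#'   \code{simConfig(seed = seed, sweep = ...)} with the package's
#'   benchmark scenario.
#' @param q,flank,maxGap,cutoff scan parameters (see
#'   \code{\link{scanContrast}}).
#' @return data.frame with one row per seed: \code{seed}, \code{hit}
#'   (sweep recovered / null clean), \code{n_regions_3way},
#'   \code{n_snps_3way}, \code{min_distance} (bp from the sweep position
#'   to the nearest three-way region; NA for null runs or empty tiers),
#'   \code{mean_fst}.
#' @export
sweepBenchmark <- function(seeds, sweep = TRUE, window = 1e6,
                           maxNullSnps = 3, cfgFun = NULL,
                           q = 0.01, flank = 5000, maxGap = 200000,
                           cutoff = 0.05) {
  if (is.null(cfgFun)) {
    cfgFun <- function(seed)
      simConfig(seed = seed,
                sweep = if (sweep)
                  list(chrom = "chr1", pos = 12500000,
                       carrierFreq = 0.9, span = 500000))
  }
  rows <- lapply(seeds, function(seed) {
    sim <- simulateSweepData(cfgFun(seed))
    hm <- applyQc(sim$haplotypes)$matrix
    res <- suppressWarnings(suppressMessages(
      scanContrast(hm, sim$contrast, q = q, flank = flank,
                   maxGap = maxGap, cutoff = cutoff, mode = "3way")))
    r3 <- res$regions3way
    minDist <- NA_real_
    if (sweep) {
      tr <- sim$truth$sweep
      onChrom <- r3[as.character(GenomicRanges::seqnames(r3)) == tr$chrom]
      if (length(onChrom)) {
        minDist <- min(pmax(
          GenomicRanges::start(onChrom) - tr$pos,
          tr$pos - GenomicRanges::end(onChrom), 0))
      }
      hit <- !is.na(minDist) && minDist <= window
    } else {
      hit <- !length(r3) || all(lengths(r3$source_snps) <= maxNullSnps)
    }
    data.frame(seed = seed, hit = hit,
               n_regions_3way = length(r3),
               n_snps_3way = length(res$snps3way),
               min_distance = minDist,
               mean_fst = mean(res$stats$fst, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
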