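#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on diploid genotype counts: conditional on the
#' observed allele counts, the probability of every attainable heterozygote
#' count no more probable than the observed one is summed. Monomorphic
#' sites return 1. This is the standard exact-test definition (not mid-p)
#' used by common VCF tooling.
#'
#' The conditional distribution over heterozygote counts \code{h} (same
#' parity as the minor-allele count) is
#' \deqn{P(h) \propto 2^h / ( ((nA-h)/2)!\, h!\, ((na-h)/2)! )}
#' computed in log space and normalized.
#'
#' @param nAA,nAa,naa non-negative genotype counts (ref-hom, het, alt-hom).
#' @return p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  if (length(nAA) != 1L || length(nAa) != 1L || length(naa) != 1L)
    stop("counts must be scalars")
  if (anyNA(c(nAA, nAa, naa)) || nAA < 0 || nAa < 0 || naa < 0)
    stop("genotype counts must be non-negative")
  n <- nAA + nAa + naa
  if (n == 0) stop("total genotype count must be positive")
  nA <- 2L * nAA + nAa
  na <- 2L * naa + nAa
  if (nA == 0L || na == 0L) return(1)
  rare <- min(nA, na)
  h <- seq.int(rare %% 2L, rare, by = 2L)
  lw <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  pObs <- p[match(nAa, h)]
  min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Apply variant quality control
#'
#' Filters a \linkS4class{HaplotypeMatrix} with the thresholds in a
#' \linkS4class{QcConfig}. Each removed variant is attributed to the first
#' failing filter in the fixed order multiallelic, non-autosomal,
#' missingness, MAF, HWE, so the \linkS4class{QcReport} counts conserve the
#' input total. MAF uses non-missing haplotype alleles only; the HWE exact
#' test uses complete diploid genotypes pooled over all samples; a genotype
#' is missing when either allele is missing.
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param config a \code{QcConfig} (default \code{qcConfig()}).
#' @return list with elements \code{matrix} (filtered
#'   \code{HaplotypeMatrix}) and \code{report} (\code{QcReport}). Zero
#'   retained variants is a warning, not an error.
#' @export
applyQc <- function(x, config = qcConfig()) {
  v <- x@variants
  m <- nrow(v)
  pending <- rep(TRUE, m)

  bases <- c("A", "C", "G", "T")
  failMulti <- !(nchar(v$ref) == 1L & nchar(v$alt) == 1L &
                   v$ref %in% bases & v$alt %in% bases & v$ref != v$alt)
  nMulti <- sum(pending & failMulti)
  pending <- pending & !failMulti

  if (length(config@autosomeLabels)) {
    failAuto <- !(v$chrom %in% config@autosomeLabels)
  } else failAuto <- rep(FALSE, m)
  nAuto <- sum(pending & failAuto)
  pending <- pending & !failAuto

  gs <- genotypeSummary(x)
  ns <- nSamples(x)
  missFrac <- (ns - gs$n) / ns
  failMiss <- missFrac > config@maxMissing
  nMiss <- sum(pending & failMiss)
  pending <- pending & !failMiss

  ac <- alleleCounts(x)
  maf <- ifelse(ac$nHap > 0, pmin(ac$nAlt, ac$nHap - ac$nAlt) / ac$nHap, 0)
  failMaf <- maf < config@mafMin
  nMaf <- sum(pending & failMaf)
  pending <- pending & !failMaf

  # HWE only evaluated for sites still pending (attribution order)
  hweP <- rep(1, m)
  idx <- which(pending)
  if (length(idx)) {
    hweP[idx] <- vapply(idx, function(i) {
      if (gs$n[i] == 0) return(1)
      hweExactTest(gs$nHomRef[i], gs$nHet[i], gs$nHomAlt[i])
    }, numeric(1))
  }
  failHwe <- hweP < config@hwePMin
  nHwe <- sum(pending & failHwe)
  pending <- pending & !failHwe

  report <- new("QcReport",
    nInput = as.integer(m),
    nRemovedMultiallelic = as.integer(nMulti),
    nRemovedNonautosomal = as.integer(nAuto),
    nRemovedMissing = as.integer(nMiss),
    nRemovedMaf = as.integer(nMaf),
    nRemovedHwe = as.integer(nHwe),
    nRetained = as.integer(sum(pending)))

  if (!any(pending))
    warning("no variants retained after QC")
  list(matrix = x[, pending], report = report)
}
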