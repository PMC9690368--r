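#' Per-site nucleotide diversity
#'
#' The per-site form of theta-pi: the proportion of the \code{choose(n, 2)}
#' haplotype pairs that differ at the site,
#' \code{2 * j * (n - j) / (n * (n - 1))} for \code{j} alt alleles among
#' \code{n} non-missing haplotypes. Vectorized.
#'
#' @param j alt-allele count(s), \code{0 <= j <= n}.
#' @param n haplotype count(s), \code{n >= 2}.
#' @return diversity value(s) in [0, 1].
#' @export
piSite <- function(j, n) {
  if (any(n < 2)) stop("pi undefined for fewer than 2 haplotypes")
  if (any(j < 0 | j > n)) stop("alt count must be between 0 and n")
  2 * j * (n - j) / (n * (n - 1))
}

#' Per-SNP diversity-ratio scan
#'
#' Computes per-site theta-pi separately in the test and control groups and
#' the directional ratio \code{log2_ratio = log2(pi_control / pi_test)}:
#' high positive values indicate diversity loss in the test group, the
#' signature of a sweep there. Sites where either group's pi is zero (or
#' where a group has fewer than two non-missing haplotypes) get a missing
#' ratio; their count is reported via a message and they are excluded from
#' downstream quantiles. Missing genotypes reduce \code{n} for that group
#' at that site.
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param contrast a \code{GroupContrast}.
#' @return data.frame with columns \code{chrom}, \code{pos}, \code{pi_test},
#'   \code{pi_control}, \code{log2_ratio}.
#' @export
piRatioScan <- function(x, contrast) {
  validateContrast(contrast, x)
  at <- alleleCounts(x, contrast@testSamples)
  ac <- alleleCounts(x, contrast@controlSamples)
  piOf <- function(cnt) {
    ok <- cnt$nHap >= 2
    out <- rep(NA_real_, nrow(cnt))
    out[ok] <- piSite(cnt$nAlt[ok], cnt$nHap[ok])
    out
  }
  piT <- piOf(at)
  piC <- piOf(ac)
  ratio <- ifelse(!is.na(piT) & !is.na(piC) & piT > 0 & piC > 0,
                  log2(piC / piT), NA_real_)
  nZero <- sum(is.na(ratio))
  if (nZero)
    message(sprintf("piRatioScan: %d of %d sites have undefined log2 ratio (zero diversity in a group)",
                    nZero, length(ratio)))
  v <- x@variants
  data.frame(chrom = v$chrom, pos = v$pos,
             pi_test = piT, pi_control = piC, log2_ratio = ratio,
             stringsAsFactors = FALSE)
}
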