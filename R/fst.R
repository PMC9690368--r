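#' Weir-Cockerham variance components for two populations
#'
#' Computes the among-population (a), among-individual-within-population (b)
#' and within-individual (c) variance components of the Weir & Cockerham
#' (1984) Fst estimator for r = 2 populations, from per-population sample
#' sizes (diploid individuals with complete calls), alt-allele frequencies
#' and observed heterozygote proportions:
#' \deqn{\bar n = (n_1+n_2)/2,\quad n_c = 2\bar n - (n_1^2+n_2^2)/(2\bar n)}
#' \deqn{\bar p = (n_1 p_1 + n_2 p_2)/(2\bar n),\quad
#'       s^2 = \sum_i n_i (p_i-\bar p)^2 / \bar n,\quad
#'       \bar h = (n_1 h_1 + n_2 h_2)/(2\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 -
#'        \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{s^2}{2} -
#'        \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'        \frac{s^2}{2} - \frac{2\bar n - 1}{4\bar n}\bar h\right],\qquad
#'       c = \bar h / 2}
#'
#' All arguments are vectorized over sites.
#'
#' @param n1,n2 diploid sample sizes per population (must give
#'   \code{(n1+n2)/2 > 1}).
#' @param p1,p2 alt-allele frequencies per population.
#' @param h1,h2 observed heterozygote proportions per population.
#' @return data.frame with columns \code{a}, \code{b}, \code{c} plus the
#'   intermediates \code{nbar}, \code{nc}, \code{pbar}, \code{s2},
#'   \code{hbar}.
#' @export
fstComponents <- function(n1, p1, h1, n2, p2, h2) {
  nbar <- (n1 + n2) / 2
  if (any(nbar <= 1, na.rm = TRUE))
    stop("Weir-Cockerham estimator undefined for mean sample size <= 1")
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  data.frame(a = a, b = b, c = c, nbar = nbar, nc = nc, pbar = pbar,
             s2 = s2, hbar = hbar)
}

#' Per-SNP Weir-Cockerham Fst scan
#'
#' Evaluates \code{fst_raw = a / (a + b + c)} at every variant for one
#' test/control contrast and clamps negative values to zero
#' (\code{fst = max(fst_raw, 0)}). A site is reported missing (\code{NA})
#' when either group has fewer than two complete diploid genotypes or when
#' the variance-component denominator is zero (e.g. monomorphic in both
#' groups); missing sites are excluded from downstream quantiles.
#'
#' @param x a \code{HaplotypeMatrix} (QC is the caller's responsibility).
#' @param contrast a \code{GroupContrast} whose samples are all present in
#'   \code{x}.
#' @return data.frame ordered by (chrom, pos) with columns \code{chrom},
#'   \code{pos}, \code{n1}, \code{n2}, \code{p1}, \code{p2}, \code{h1},
#'   \code{h2}, \code{fst_raw}, \code{fst}.
#' @export
fstScan <- function(x, contrast) {
  validateContrast(contrast, x)
  g1 <- genotypeSummary(x, contrast@testSamples)
  g2 <- genotypeSummary(x, contrast@controlSamples)
  ok <- g1$n >= 2 & g2$n >= 2

  raw <- rep(NA_real_, nVariants(x))
  if (any(ok)) {
    comp <- fstComponents(g1$n[ok], g1$p[ok], g1$het[ok],
                          g2$n[ok], g2$p[ok], g2$het[ok])
    denom <- comp$a + comp$b + comp$c
    raw[ok] <- ifelse(denom == 0, NA_real_, comp$a / denom)
  }
  v <- x@variants
  data.frame(
    chrom = v$chrom, pos = v$pos,
    n1 = g1$n, n2 = g2$n, p1 = g1$p, p2 = g2$p, h1 = g1$het, h2 = g2$het,
    fst_raw = raw,
    fst = pmax(raw, 0),
    stringsAsFactors = FALSE)
}
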