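# Small in-code fixtures shared across test files.

# HaplotypeMatrix from an explicit allele matrix (rows = haplotypes).
toyMatrix <- function(alleles, pos = NULL, chrom = "chr1", phased = TRUE,
                      sampleIds = NULL, metadata = list()) {
  alleles <- as.matrix(alleles)
  m <- ncol(alleles)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%02d", seq_len(nrow(alleles) / 2))
  HaplotypeMatrix(
    alleles,
    data.frame(chrom = rep(chrom, length.out = m), pos = pos,
               ref = "A", alt = "G", stringsAsFactors = FALSE),
    sampleIds, phased = phased, metadata = metadata)
}

# Random matrix with controllable missingness.
randomMatrix <- function(nSamples, m, seed = 1, missingRate = 0,
                         chrom = "chr1") {
  set.seed(seed)
  a <- matrix(rbinom(2 * nSamples * m, 1, runif(m, 0.1, 0.9)[
    rep(seq_len(m), each = 2 * nSamples)]), nrow = 2 * nSamples)
  if (missingRate > 0)
    a[runif(length(a)) < missingRate] <- NA_integer_
  toyMatrix(a, chrom = chrom)
}

twoGroupContrast <- function(hm, nTest = nSamples(hm) %/% 2) {
  ids <- sampleIds(hm)
  GroupContrast("test_contrast", ids[seq_len(nTest)],
                ids[(nTest + 1):length(ids)])
}

# Independent pair-enumeration EHH: fraction of haplotype pairs identical
# over columns `cols` (missing matches nothing).
ehhPairOracle <- function(haps, cols) {
  n <- nrow(haps)
  same <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- haps[i, cols]; b <- haps[j, cols]
    if (!anyNA(a) && !anyNA(b) && all(a == b)) same <- same + 1L
  }
  same / choose(n, 2)
}

# Straight-line Weir & Cockerham (1984) two-population components,
# written directly from the estimator's definition as an independent
# cross-check of fstComponents().
wcOracle <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Brute-force HWE exact test: enumerate every attainable heterozygote
# count via the probability-ratio recurrence (no log-factorials), an
# independent route from the implementation.
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  rare <- min(nA, na)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in 2:length(hs)) {
      h <- hs[k]
      # P(h) / P(h-2) = 4 * nhomA(h-2) * nhoma(h-2) / (h * (h-1))
      homA <- (nA - (h - 2)) / 2
      homa <- (na - (h - 2)) / 2
      probs[k] <- probs[k - 1] * 4 * homA * homa / (h * (h - 1))
    }
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hs)]
  min(1, sum(probs[probs <= pObs * (1 + 1e-9)]))
}

# Write a small VCF from header+body lines.
writeVcfLines <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

# Independent per-site XP-EHH oracle: same pooled-extent integration rule
# as the scan, but every EHH value comes from pair enumeration.
xpehhSiteOracle <- function(haps, testRows, ctrlRows, core, positions,
                            maxGap = 200000, cutoff = 0.05) {
  m <- ncol(haps)
  pooled <- c(testRows, ctrlRows)
  areaT <- 0; areaC <- 0
  for (dir in c(-1L, 1L)) {
    dPrev <- 0; eP0 <- 1; eT0 <- 1; eC0 <- 1
    j <- core
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > m) break
      if (abs(positions[nxt] - positions[j]) > maxGap) break
      cols <- core:nxt
      eP <- ehhPairOracle(haps[pooled, , drop = FALSE], cols)
      eT <- ehhPairOracle(haps[testRows, , drop = FALSE], cols)
      eC <- ehhPairOracle(haps[ctrlRows, , drop = FALSE], cols)
      d <- abs(positions[nxt] - positions[core])
      if (eP < cutoff) {
        frac <- (eP0 - cutoff) / (eP0 - eP)
        xs <- dPrev + frac * (d - dPrev)
        areaT <- areaT + (xs - dPrev) * (eT0 + (eT0 + frac * (eT - eT0))) / 2
        areaC <- areaC + (xs - dPrev) * (eC0 + (eC0 + frac * (eC - eC0))) / 2
        break
      }
      areaT <- areaT + (d - dPrev) * (eT0 + eT) / 2
      areaC <- areaC + (d - dPrev) * (eC0 + eC) / 2
      dPrev <- d; eP0 <- eP; eT0 <- eT; eC0 <- eC
      j <- nxt
    }
  }
  c(ihh_test = areaT, ihh_control = areaC)
}
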