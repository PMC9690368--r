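#' Extended haplotype homozygosity around a core site
#'
#' EHH at a site \code{x} on one side of the core is the fraction of the
#' \code{choose(n, 2)} haplotype pairs that are identical over every variant
#' from the core to \code{x} inclusive. All haplotypes of the group are
#' pooled (the XP-EHH convention: no partition by core allele), and the
#' value at physical offset 0 is 1 by definition. Missing alleles never
#' match anything, including each other.
#'
#' Each arm is extended outward until EHH drops below \code{cutoff} (the
#' first sub-cutoff point is kept so the integrator can interpolate the
#' crossing), until the gap to the next site exceeds \code{maxGap} (the arm
#' then ends at the last site before the gap), or until the end of the
#' supplied positions.
#'
#' @param haps matrix of 0/1/NA, one row per haplotype, columns ordered by
#'   \code{positions}.
#' @param coreIndex column index of the core site.
#' @param positions strictly increasing physical positions (bp), one per
#'   column.
#' @param cutoff homozygosity threshold ending an arm (default 0.05).
#' @param maxGap maximum bp between consecutive sites before the arm is
#'   truncated (default 200000).
#' @return An object of class \code{EhhCurve}: list with \code{core_index},
#'   \code{core_pos}, and per-arm data.frames \code{left}/\code{right}
#'   (columns \code{pos}, \code{offset}, \code{ehh}), each starting at the
#'   core with \code{offset = 0}, \code{ehh = 1}.
#' @export
ehhAtCore <- function(haps, coreIndex, positions, cutoff = 0.05,
                      maxGap = 200000) {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) stop("EHH undefined for fewer than 2 haplotypes")
  if (length(positions) != ncol(haps))
    stop("positions must match haplotype columns")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  npairs <- choose(n, 2)

  arm <- function(dir) {
    gid <- .ehhRefine(rep(1L, n), haps[, coreIndex])
    out <- list(data.frame(pos = positions[coreIndex], offset = 0, ehh = 1))
    j <- coreIndex
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > ncol(haps)) break
      if (abs(positions[nxt] - positions[j]) > maxGap) break
      gid <- .ehhRefine(gid, haps[, nxt])
      e <- sum(choose(tabulate(gid), 2)) / npairs
      out[[length(out) + 1L]] <- data.frame(
        pos = positions[nxt],
        offset = abs(positions[nxt] - positions[coreIndex]),
        ehh = e)
      j <- nxt
      if (e < cutoff) break
    }
    do.call(rbind, out)
  }
  structure(
    list(core_index = coreIndex, core_pos = positions[coreIndex],
         left = arm(-1L), right = arm(+1L)),
    class = "EhhCurve")
}

# refine haplotype group ids by the alleles of one more site; missing
# alleles get a per-haplotype unique symbol so they match nothing
.ehhRefine <- function(gid, alleles) {
  sym <- as.integer(alleles)
  miss <- is.na(sym)
  if (any(miss)) sym[miss] <- 2L + which(miss)
  key <- gid * (length(gid) + 3L) + sym
  match(key, unique(key))
}

#' Integrate an EHH curve into iHH
#'
#' Trapezoidal integration of EHH over physical distance, both arms summed.
#' Integration of an arm stops where EHH falls below \code{cutoff}; the
#' final segment is included up to the linearly interpolated crossing
#' point. If two consecutive curve points are more than \code{maxGap}
#' apart, the arm's integral stops at the last point before the gap.
#'
#' @param curve an \code{EhhCurve} from \code{\link{ehhAtCore}}.
#' @param maxGap maximum bp between consecutive points (default 200000).
#' @param cutoff truncation threshold (default 0.05).
#' @return area in bp (0 when no segment is integrable).
#' @export
integrateEhh <- function(curve, maxGap = 200000, cutoff = 0.05) {
  armArea <- function(df) {
    if (is.null(df) || nrow(df) < 2) return(0)
    area <- 0
    for (k in 2:nrow(df)) {
      d0 <- df$offset[k - 1]; d1 <- df$offset[k]
      e0 <- df$ehh[k - 1]; e1 <- df$ehh[k]
      if (d1 - d0 > maxGap) break
      if (e1 < cutoff) {
        # linear interpolation of the cutoff crossing
        frac <- (e0 - cutoff) / (e0 - e1)
        xs <- d0 + frac * (d1 - d0)
        area <- area + (xs - d0) * (e0 + cutoff) / 2
        break
      }
      area <- area + (d1 - d0) * (e0 + e1) / 2
    }
    area
  }
  armArea(curve$left) + armArea(curve$right)
}

#' Cross-population EHH scan (XP-EHH)
#'
#' For every variant, integrates EHH over physical distance separately for
#' the test and control haplotypes and reports
#' \code{xpehh_raw = ln(iHH_test / iHH_control)}. Both groups are
#' integrated over a shared extent per arm, determined by the
#' pooled-sample EHH falling below \code{cutoff} (with linear interpolation
#' of the crossing) or by the \code{maxGap} rule — so the statistic is
#' antisymmetric under swapping the groups. Sites with zero integrated
#' area in either group are reported missing. Positive values indicate
#' longer haplotype homozygosity (a recent sweep) in the test group.
#'
#' The scan runs chromosome by chromosome via a compiled core.
#'
#' @param x a phased \code{HaplotypeMatrix}.
#' @param contrast a \code{GroupContrast}.
#' @param maxGap maximum bp between consecutive sites before an arm is
#'   truncated (default 200000, the Selscan default the method adopts).
#' @param cutoff pooled-EHH threshold ending integration (default 0.05).
#' @return data.frame with columns \code{chrom}, \code{pos},
#'   \code{ihh_test}, \code{ihh_control}, \code{xpehh_raw}.
#' @export
xpehhScan <- function(x, contrast, maxGap = 200000, cutoff = 0.05) {
  if (!isPhased(x))
    stop("XP-EHH requires phased haplotypes")
  validateContrast(contrast, x)
  testRows <- hapRows(x, contrast@testSamples)
  ctrlRows <- hapRows(x, contrast@controlSamples)
  v <- x@variants
  ihhT <- numeric(nrow(v)); ihhC <- numeric(nrow(v))
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    sub <- x@alleles[c(testRows, ctrlRows), idx, drop = FALSE]
    sub[is.na(sub)] <- -1L
    res <- xpehh_chrom_cpp(sub, as.numeric(v$pos[idx]),
                           seq_along(testRows) - 1L,
                           length(testRows) + seq_along(ctrlRows) - 1L,
                           as.numeric(maxGap), as.numeric(cutoff))
    ihhT[idx] <- res[, 1L]
    ihhC[idx] <- res[, 2L]
  }
  raw <- ifelse(ihhT > 0 & ihhC > 0, log(ihhT / ihhC), NA_real_)
  data.frame(chrom = v$chrom, pos = v$pos,
             ihh_test = ihhT, ihh_control = ihhC, xpehh_raw = raw,
             stringsAsFactors = FALSE)
}

#' Genome-wide z-normalization of XP-EHH
#'
#' Standardizes the raw XP-EHH values by subtracting their genome-wide mean
#' and dividing by their sample standard deviation (n - 1 denominator),
#' over all non-missing sites.
#'
#' @param results data.frame from \code{\link{xpehhScan}}.
#' @return the input with an added \code{xpehh_norm} column (NA where raw
#'   is NA).
#' @export
normalizeXpehh <- function(results) {
  raw <- results$xpehh_raw
  ok <- !is.na(raw)
  if (sum(ok) < 2)
    stop("need at least 2 non-missing XP-EHH values to normalize")
  s <- sd(raw[ok])
  if (s == 0)
    stop("XP-EHH values are constant; normalization undefined")
  results$xpehh_norm <- (raw - mean(raw[ok])) / s
  results
}
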