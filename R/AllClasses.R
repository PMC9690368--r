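#' @import methods
#' @importFrom stats sd setNames quantile rbinom runif
#' @importFrom utils read.delim write.table packageVersion head tail
#' @useDynLib haploSweep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Phased haplotype matrix
#'
#' Container for phased biallelic SNP haplotypes. Alleles are coded 0
#' (reference), 1 (alternate) or \code{NA} (missing), one row per haplotype
#' (two consecutive rows per diploid sample, in sample order) and one column
#' per variant. Variants are kept sorted by position within each chromosome;
#' chromosome blocks appear in their input order.
#'
#' @slot alleles integer matrix of \{0, 1, NA\}, \code{2 * nSamples} rows.
#' @slot variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{id}; one row per variant (column of
#'   \code{alleles}).
#' @slot sampleIds character vector; sample \code{i} owns allele rows
#'   \code{2i - 1} and \code{2i}.
#' @slot phased logical scalar; haplotype-level statistics (EHH, XP-EHH)
#'   require \code{TRUE}.
#' @slot metadata list of free-form provenance (e.g. VCF rejection report,
#'   contig lengths).
#'
#' @export
setClass("HaplotypeMatrix",
  slots = c(
    alleles   = "matrix",
    variants  = "data.frame",
    sampleIds = "character",
    phased    = "logical",
    metadata  = "list"
  )
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- character()
  v <- object@variants
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(v)))
    return(sprintf("variants must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(object@alleles) != 2L * length(object@sampleIds))
    msg <- c(msg, "allele row count must be 2 * number of samples")
  if (ncol(object@alleles) != nrow(v))
    msg <- c(msg, "allele column count must equal variant count")
  if (length(object@phased) != 1L || is.na(object@phased))
    msg <- c(msg, "phased must be TRUE or FALSE")
  a <- object@alleles
  if (length(a) && !all(a[!is.na(a)] %in% c(0L, 1L)))
    msg <- c(msg, "alleles must be 0, 1 or NA")
  if (nrow(v)) {
    if (any(v$pos < 1L)) msg <- c(msg, "positions must be >= 1")
    if (any(v$ref == v$alt)) msg <- c(msg, "ref and alt alleles must differ")
    # strictly increasing positions within each chromosome block
    bychrom <- split(v$pos, factor(v$chrom, levels = unique(v$chrom)))
    if (any(vapply(bychrom, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within each chromosome")
  }
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Two-group contrast of samples
#'
#' Names the test and control sample sets for one phenotype contrast.
#' Orientation matters: XP-EHH is \code{ln(iHH_test / iHH_control)} and the
#' diversity ratio is \code{log2(pi_control / pi_test)}, so positive values of
#' both point at a sweep in the test group.
#'
#' @slot name contrast label, e.g. \code{"nap_size"}.
#' @slot testSamples,controlSamples disjoint, nonempty sample-ID sets.
#' @slot description free text.
#' @export
setClass("GroupContrast",
  slots = c(
    name           = "character",
    testSamples    = "character",
    controlSamples = "character",
    description    = "character"
  ),
  prototype = prototype(description = "")
)

setValidity("GroupContrast", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
  if (!length(object@testSamples)) msg <- c(msg, "test sample set is empty")
  if (!length(object@controlSamples)) msg <- c(msg, "control sample set is empty")
  if (length(intersect(object@testSamples, object@controlSamples)))
    msg <- c(msg, "test and control sample sets overlap")
  if (anyDuplicated(object@testSamples) || anyDuplicated(object@controlSamples))
    msg <- c(msg, "duplicated sample ids within a role")
  if (length(msg)) msg else TRUE
})

#' Variant quality-control configuration
#'
#' Defaults reproduce a standard WGS hard-filter set: MAF >= 0.05, complete
#' genotype calls (\code{maxMissing = 0}, the \code{--max-missing 1.0}
#' idiom), exact Hardy-Weinberg p >= 1e-6 on the pooled sample, and an
#' autosome whitelist. An empty \code{autosomeLabels} means every chromosome
#' label is accepted.
#'
#' @slot mafMin minimum minor allele frequency (kept iff MAF >= mafMin).
#' @slot maxMissing maximum allowed fraction of missing genotypes per site.
#' @slot hwePMin minimum exact-test p-value (kept iff p >= hwePMin).
#' @slot autosomeLabels chromosome labels that count as autosomal.
#' @export
setClass("QcConfig",
  slots = c(
    mafMin         = "numeric",
    maxMissing     = "numeric",
    hwePMin        = "numeric",
    autosomeLabels = "character"
  )
)

setValidity("QcConfig", function(object) {
  msg <- character()
  if (object@mafMin < 0 || object@mafMin > 0.5)
    msg <- c(msg, "mafMin must be in [0, 0.5]")
  if (object@maxMissing < 0 || object@maxMissing > 1)
    msg <- c(msg, "maxMissing must be in [0, 1]")
  if (object@hwePMin <= 0 || object@hwePMin >= 1)
    msg <- c(msg, "hwePMin must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname QcConfig-class
#' @param mafMin,maxMissing,hwePMin,autosomeLabels see slot documentation.
#' @return A \code{QcConfig} object.
#' @export
qcConfig <- function(mafMin = 0.05, maxMissing = 0, hwePMin = 1e-6,
                     autosomeLabels = character()) {
  new("QcConfig", mafMin = mafMin, maxMissing = maxMissing,
      hwePMin = hwePMin, autosomeLabels = autosomeLabels)
}

#' Variant quality-control report
#'
#' Each input variant is attributed to exactly one outcome; the attribution
#' order is fixed (multiallelic, non-autosomal, missingness, MAF, HWE) so the
#' counts are deterministic and conserve the input total.
#' @slot nInput,nRemovedMultiallelic,nRemovedNonautosomal,nRemovedMissing,nRemovedMaf,nRemovedHwe,nRetained integer counts.
#' @export
setClass("QcReport",
  slots = c(
    nInput               = "integer",
    nRemovedMultiallelic = "integer",
    nRemovedNonautosomal = "integer",
    nRemovedMissing      = "integer",
    nRemovedMaf          = "integer",
    nRemovedHwe          = "integer",
    nRetained            = "integer"
  )
)

setValidity("QcReport", function(object) {
  tot <- object@nRemovedMultiallelic + object@nRemovedNonautosomal +
    object@nRemovedMissing + object@nRemovedMaf + object@nRemovedHwe +
    object@nRetained
  if (tot != object@nInput) "removal counts plus retained must equal nInput" else TRUE
})

#' Empirical outlier set for one statistic
#'
#' Holds the top-tail SNPs of one genome-wide statistic: the threshold (the
#' value at rank \code{ceiling(q * N)} from the top among eligible values)
#' and the indices of every variant at or above it (ties included).
#'
#' @slot statistic statistic label (\code{"fst"}, \code{"xpehh"}, \code{"pi_ratio"}).
#' @slot threshold inclusion threshold.
#' @slot indices variant indices (into the scanned matrix) in the set.
#' @slot nEligible number of eligible (non-missing; for XP-EHH, positive) values.
#' @slot q tail fraction used.
#' @export
setClass("OutlierSet",
  slots = c(
    statistic = "character",
    threshold = "numeric",
    indices   = "integer",
    nEligible = "integer",
    q         = "numeric"
  )
)

## ---- show methods -----------------------------------------------------

setMethod("show", "HaplotypeMatrix", function(object) {
  cat(sprintf("HaplotypeMatrix: %d haplotypes (%d samples) x %d variants, %s\n",
              nrow(object@alleles), length(object@sampleIds),
              ncol(object@alleles),
              if (object@phased) "phased" else "unphased"))
  if (nrow(object@variants)) {
    ch <- unique(object@variants$chrom)
    cat(sprintf("  chromosomes: %s\n",
                paste(head(ch, 5), collapse = ", ")))
  }
  nm <- sum(is.na(object@alleles))
  if (nm) cat(sprintf("  missing alleles: %d\n", nm))
})

setMethod("show", "GroupContrast", function(object) {
  cat(sprintf("GroupContrast '%s': %d test vs %d control samples\n",
              object@name, length(object@testSamples),
              length(object@controlSamples)))
})

setMethod("show", "QcConfig", function(object) {
  cat(sprintf("QcConfig: MAF >= %g, missing fraction <= %g, HWE p >= %g, %s\n",
              object@mafMin, object@maxMissing, object@hwePMin,
              if (length(object@autosomeLabels))
                sprintf("autosomes = {%s}", paste(object@autosomeLabels, collapse = ","))
              else "all chromosomes treated as autosomal"))
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:\n")
  df <- as.data.frame(object)
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-22s %d\n", df$step[i], df$count[i]))
})

setMethod("show", "OutlierSet", function(object) {
  cat(sprintf("OutlierSet '%s': %d of %d eligible SNPs (q = %g, threshold = %.6g)\n",
              object@statistic, length(object@indices), object@nEligible,
              object@q, object@threshold))
})

#' @describeIn QcReport-class tabular form (step/count), suitable for TSV export.
#' @param x a \code{QcReport}.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.QcReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    step = c("input", "removed_multiallelic", "removed_nonautosomal",
             "removed_missing", "removed_maf", "removed_hwe", "retained"),
    count = c(x@nInput, x@nRemovedMultiallelic, x@nRemovedNonautosomal,
              x@nRemovedMissing, x@nRemovedMaf, x@nRemovedHwe, x@nRetained),
    stringsAsFactors = FALSE
  )
}
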