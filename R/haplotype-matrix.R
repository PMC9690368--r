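#' Construct a HaplotypeMatrix
#'
#' Variants are reordered by position within each chromosome (chromosome
#' blocks keep their order of first appearance); allele columns are permuted
#' accordingly.
#'
#' @param alleles numeric/integer matrix of 0/1/NA, rows = haplotypes
#'   (two consecutive rows per sample), columns = variants.
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally \code{id}.
#' @param sampleIds character vector, length \code{nrow(alleles) / 2}.
#' @param phased logical; whether rows are true haplotypes.
#' @param metadata optional provenance list.
#' @return A \linkS4class{HaplotypeMatrix}.
#' @export
HaplotypeMatrix <- function(alleles, variants, sampleIds, phased = TRUE,
                            metadata = list()) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(variants$id)) variants$id <- rep(NA_character_, nrow(variants))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  ord <- order(match(variants$chrom, unique(variants$chrom)), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  alleles <- alleles[, ord, drop = FALSE]
  dimnames(alleles) <- NULL
  new("HaplotypeMatrix", alleles = alleles, variants = variants,
      sampleIds = as.character(sampleIds), phased = isTRUE(phased),
      metadata = metadata)
}

#' @rdname HaplotypeMatrix
#' @param x a \code{HaplotypeMatrix}.
#' @export
nSamples <- function(x) length(x@sampleIds)

#' @rdname HaplotypeMatrix
#' @export
nVariants <- function(x) ncol(x@alleles)

#' @rdname HaplotypeMatrix
#' @export
sampleIds <- function(x) x@sampleIds

#' @rdname HaplotypeMatrix
#' @export
variantTable <- function(x) x@variants

#' @rdname HaplotypeMatrix
#' @export
alleleMatrix <- function(x) x@alleles

#' @rdname HaplotypeMatrix
#' @export
isPhased <- function(x) x@phased

#' Haplotype row indices for a set of samples
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param ids sample IDs present in \code{x}.
#' @return Integer vector of allele-matrix row indices (two per sample,
#'   in the order given by \code{ids}).
#' @export
hapRows <- function(x, ids) {
  idx <- match(ids, x@sampleIds)
  if (anyNA(idx))
    stop("unknown sample id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  as.integer(rbind(2L * idx - 1L, 2L * idx))
}

#' Subset a HaplotypeMatrix
#'
#' \code{i} selects samples (by index or ID), \code{j} selects variants by
#' index. Both haplotype rows of each selected sample are kept.
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param i sample selector (integer/logical index or character IDs).
#' @param j variant selector (integer/logical index).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@sampleIds)
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (is.logical(i)) i <- which(i)
  if (anyNA(i)) stop("unknown sample selector")
  if (missing(j)) j <- seq_len(ncol(x@alleles))
  if (is.logical(j)) j <- which(j)
  rows <- as.integer(rbind(2L * i - 1L, 2L * i))
  new("HaplotypeMatrix",
      alleles = x@alleles[rows, j, drop = FALSE],
      variants = {
        v <- x@variants[j, , drop = FALSE]; rownames(v) <- NULL; v
      },
      sampleIds = x@sampleIds[i],
      phased = x@phased,
      metadata = x@metadata)
})

#' Per-group diploid genotype summaries at every site
#'
#' Collapses haplotype pairs to genotypes and tabulates, per variant:
#' complete-genotype count, alt-allele frequency (from non-missing alleles of
#' complete genotypes), and observed heterozygote proportion. A genotype is
#' missing if either of its two alleles is missing.
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param ids samples to summarise (default: all).
#' @return data.frame with columns \code{n} (complete genotypes),
#'   \code{nAlt} (alt alleles among them), \code{p} (alt frequency),
#'   \code{het} (observed heterozygote proportion), \code{nHet},
#'   \code{nHomRef}, \code{nHomAlt}.
#' @export
genotypeSummary <- function(x, ids = sampleIds(x)) {
  rows <- hapRows(x, ids)
  a1 <- x@alleles[rows[c(TRUE, FALSE)], , drop = FALSE]
  a2 <- x@alleles[rows[c(FALSE, TRUE)], , drop = FALSE]
  miss <- is.na(a1) | is.na(a2)
  g <- a1 + a2
  g[miss] <- NA_integer_
  n <- colSums(!miss)
  nAlt <- colSums(g, na.rm = TRUE)
  nHet <- colSums(g == 1L, na.rm = TRUE)
  nHomAlt <- colSums(g == 2L, na.rm = TRUE)
  data.frame(
    n = n,
    nAlt = nAlt,
    p = ifelse(n > 0, nAlt / (2 * n), NA_real_),
    het = ifelse(n > 0, nHet / n, NA_real_),
    nHet = nHet,
    nHomRef = n - nHet - nHomAlt,
    nHomAlt = nHomAlt
  )
}

#' Per-group haplotype allele counts at every site
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param ids samples to count over (default: all).
#' @return data.frame with \code{nHap} (non-missing haplotypes) and
#'   \code{nAlt} (alt alleles among them).
#' @export
alleleCounts <- function(x, ids = sampleIds(x)) {
  rows <- hapRows(x, ids)
  a <- x@alleles[rows, , drop = FALSE]
  data.frame(nHap = colSums(!is.na(a)), nAlt = colSums(a, na.rm = TRUE))
}

#' Construct a GroupContrast
#'
#' @param name contrast label.
#' @param testSamples,controlSamples disjoint, nonempty sample-ID vectors.
#' @param description free text.
#' @param matrix optional \code{HaplotypeMatrix}; when given, membership is
#'   validated against its sample IDs.
#' @return A \linkS4class{GroupContrast}.
#' @export
GroupContrast <- function(name, testSamples, controlSamples,
                          description = "", matrix = NULL) {
  gc <- new("GroupContrast", name = name,
            testSamples = as.character(testSamples),
            controlSamples = as.character(controlSamples),
            description = description)
  if (!is.null(matrix)) validateContrast(gc, matrix)
  gc
}

#' @rdname GroupContrast
#' @param contrast a \code{GroupContrast} to check against \code{matrix}'s samples.
#' @export
validateContrast <- function(contrast, matrix) {
  missing <- setdiff(c(contrast@testSamples, contrast@controlSamples),
                     sampleIds(matrix))
  if (length(missing))
    stop(sprintf("contrast '%s' names samples absent from the matrix: %s",
                 contrast@name, paste(missing, collapse = ", ")))
  invisible(TRUE)
}
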