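#' Empirical top-tail outlier set
#'
#' Selects the top fraction \code{q} of a genome-wide statistic. The
#' threshold is the value at rank \code{ceiling(q * N)} from the top among
#' eligible values (non-missing; additionally positive when
#' \code{positiveOnly = TRUE}, the convention for normalized XP-EHH); every
#' eligible value at or above the threshold is included, so ties make the
#' set a superset of exactly q * N.
#'
#' @param values numeric per-SNP statistic, indexed by variant.
#' @param q tail fraction (default 0.01).
#' @param positiveOnly restrict eligibility to values > 0.
#' @param statistic label stored in the result.
#' @return An \linkS4class{OutlierSet}.
#' @export
topQuantile <- function(values, q = 0.01, positiveOnly = FALSE,
                        statistic = "stat") {
  if (q <= 0 || q >= 0.5) stop("q must be in (0, 0.5)")
  eligible <- which(!is.na(values) & (!positiveOnly | values > 0))
  if (!length(eligible))
    stop(sprintf("no eligible values for '%s' (positiveOnly = %s)",
                 statistic, positiveOnly))
  N <- length(eligible)
  if (N < 100 / q)
    warning(sprintf("only %d eligible values for '%s'; top-%g%% threshold is noisy",
                    N, statistic, 100 * q))
  k <- ceiling(q * N)
  thr <- sort(values[eligible], decreasing = TRUE)[k]
  idx <- eligible[values[eligible] >= thr]
  new("OutlierSet", statistic = statistic, threshold = thr,
      indices = sort(as.integer(idx)), nEligible = as.integer(N),
      q = q)
}

#' Intersect outlier sets across statistics
#'
#' @param sets list of \code{OutlierSet} over the same variant universe
#'   (2 sets for the Fst/XP-EHH tier, 3 when the diversity ratio is added).
#' @return sorted integer vector of variant indices in every set.
#' @export
intersectOutliers <- function(sets) {
  stopifnot(length(sets) >= 1)
  sort(Reduce(intersect, lapply(sets, function(s) s@indices)))
}

#' Flanking-window candidate regions around outlier SNPs
#'
#' Each SNP contributes the window \code{[pos - flank, pos + flank]},
#' clipped to \code{[1, chromosome end]}; overlapping or book-ended windows
#' on one chromosome are merged. Source SNP positions are preserved per
#' merged region. With the default 5-kb flank, an isolated SNP yields a
#' region with \code{end - start = 10000}.
#'
#' @param chrom,pos chromosome label and 1-based position per SNP (sorted
#'   by chrom, pos).
#' @param flank flank size in bp (default 5000).
#' @param chromBounds optional named vector of chromosome lengths for
#'   right-clipping (names = chromosome labels); unlisted chromosomes are
#'   not right-clipped.
#' @return \code{GRanges} with metadata column \code{source_snps}
#'   (IntegerList of contributing SNP positions).
#' @export
snpsToRegions <- function(chrom, pos, flank = 5000, chromBounds = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  if (!length(pos))
    return(GenomicRanges::GRanges(source_snps = IRanges::IntegerList()))
  start <- pmax(pos - flank, 1)
  end <- pos + flank
  if (!is.null(chromBounds)) {
    hit <- chrom %in% names(chromBounds)
    end[hit] <- pmin(end[hit], chromBounds[chrom[hit]])
  }
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  merged <- GenomicRanges::reduce(win, with.revmap = TRUE)
  src <- IRanges::extractList(as.integer(pos), merged$revmap)
  out <- GenomicRanges::granges(merged)
  S4Vectors::mcols(out)$source_snps <- src
  sort(out)
}

#' Annotate candidate regions with overlapping genes
#'
#' Assigns a gene to a region when the two closed 1-based intervals share
#' at least one base pair (the default intersect semantics of interval
#' tools); a gene ending exactly at a region's start is assigned. Genes can
#' annotate several regions; regions may end up with empty gene lists.
#'
#' @param regions \code{GRanges} of candidate regions.
#' @param genes \code{GRanges} of gene spans with a \code{gene_id} column
#'   (see \code{\link{readGeneModels}}).
#' @return \code{regions} with an added \code{genes} metadata column
#'   (CharacterList of gene IDs).
#' @export
annotateRegions <- function(regions, genes) {
  hits <- GenomicRanges::findOverlaps(regions, genes, minoverlap = 1L)
  lst <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits), levels = seq_along(regions)))
  S4Vectors::mcols(regions)$genes <-
    IRanges::CharacterList(unname(lst))
  regions
}

#' Candidate-region summary table
#'
#' Flattens annotated regions into the reporting layout used for published
#' sweep tables: chromosome, \code{start-end} span, contrast, gene list.
#'
#' @param regions annotated \code{GRanges} (with \code{contrast},
#'   \code{support}, \code{genes}, \code{source_snps} columns as
#'   available).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{span}, \code{contrast}, \code{support}, \code{n_snps},
#'   \code{genes}.
#' @export
regionTable <- function(regions) {
  if (!length(regions)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), span = character(),
                      contrast = character(), support = character(),
                      n_snps = integer(), genes = character(),
                      stringsAsFactors = FALSE))
  }
  mc <- S4Vectors::mcols(regions)
  getcol <- function(nm, default) {
    if (nm %in% names(mc)) mc[[nm]] else default
  }
  genes <- if ("genes" %in% names(mc)) .collapseGenes(mc$genes) else ""
  nsnps <- if ("source_snps" %in% names(mc))
    lengths(mc$source_snps) else rep(NA_integer_, length(regions))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions),
    end = GenomicRanges::end(regions),
    span = sprintf("%d-%d", GenomicRanges::start(regions),
                   GenomicRanges::end(regions)),
    contrast = as.character(getcol("contrast", rep(NA_character_, length(regions)))),
    support = as.character(getcol("support", rep(NA_character_, length(regions)))),
    n_snps = as.integer(nsnps),
    genes = ifelse(genes == "", ".", genes),
    stringsAsFactors = FALSE)
}
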