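#' Read phased haplotypes from a VCF file
#'
#' Loads a multi-sample VCF (via \pkg{vcfR}) and decodes GT fields into a
#' \linkS4class{HaplotypeMatrix}. Only biallelic single-nucleotide records
#' are kept; multiallelic, indel or symbolic records are dropped and counted
#' in a per-reason rejection report stored under
#' \code{metadata(x)$rejections}. Sample order is preserved.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param requirePhased if \code{TRUE} (default), any non-missing unphased
#'   genotype (\code{"/"} separator) is an error naming the record and
#'   sample. Missing genotypes (\code{.}, \code{./.}, \code{.|.}) are
#'   accepted either way and decoded to \code{NA}.
#' @return A \code{HaplotypeMatrix}; \code{metadata} carries the rejection
#'   report and any \code{##contig} lengths found in the header.
#' @export
readHaplotypes <- function(path, requirePhased = TRUE) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no variant records: ", path)
  samples <- colnames(vcf@gt)[-1L]
  if (!length(samples)) stop("VCF has no sample columns: ", path)

  bases <- c("A", "C", "G", "T")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snv <- !multi & fix$REF %in% bases & fix$ALT %in% bases
  rejections <- data.frame(
    reason = c("multiallelic", "non_snv"),
    count = c(sum(multi), sum(!multi & !snv)),
    stringsAsFactors = FALSE
  )
  keep <- which(snv)
  if (!length(keep))
    stop("no biallelic SNV records remain after filtering: ", path)

  gt <- vcf@gt[keep, -1L, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # strip any trailing FORMAT subfields: GT is always first per VCF spec
  dims <- dim(gt)
  gt <- sub(":.*$", "", gt)
  dim(gt) <- dims
  missingGt <- gt %in% c(".", "./.", ".|.", ".|", "./")
  if (requirePhased) {
    bad <- matrix(grepl("/", gt, fixed = TRUE) & !missingGt, nrow = dims[1L])
    if (any(bad)) {
      w <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "unphased genotype '%s' at %s:%s for sample '%s' (requirePhased = TRUE)",
        gt[w[1L], w[2L]], fix$CHROM[w[1L]], fix$POS[w[1L]], samples[w[2L]]))
    }
  }

  m <- length(keep); ns <- length(samples)
  alleles <- matrix(NA_integer_, nrow = 2L * ns, ncol = m)
  split1 <- sub("[/|].*$", "", gt)   # first allele
  split2 <- sub("^[^/|]*[/|]", "", gt)  # second allele ("" if haploid call)
  split2[!grepl("[/|]", gt)] <- NA_character_
  dec <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "0"] <- 0L
    out[x == "1"] <- 1L
    bad <- !(x %in% c("0", "1", ".", NA_character_))
    if (any(bad))
      stop("unexpected allele code(s) in GT field: ",
           paste(unique(x[bad]), collapse = ", "))
    out
  }
  for (s in seq_len(ns)) {
    alleles[2L * s - 1L, ] <- dec(split1[, s])
    alleles[2L * s, ] <- dec(split2[, s])
  }

  contigLengths <- .parseContigLengths(vcf@meta)
  HaplotypeMatrix(
    alleles = alleles,
    variants = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                          ref = fix$REF, alt = fix$ALT,
                          id = ifelse(fix$ID == ".", NA_character_, fix$ID),
                          stringsAsFactors = FALSE),
    sampleIds = samples,
    phased = TRUE,
    metadata = list(rejections = rejections, contigLengths = contigLengths,
                    source = path)
  )
}

.parseContigLengths <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  id <- sub('.*ID=([^,>]+).*', "\\1", ln)
  has <- grepl("length=", ln)
  len <- rep(NA_integer_, length(ln))
  len[has] <- as.integer(sub(".*length=([0-9]+).*", "\\1", ln[has]))
  setNames(len, id)
}

#' Write a HaplotypeMatrix as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with GT-only genotypes. Phased
#' matrices use \code{|}, unphased \code{/}; missing alleles become
#' \code{.}. Contig header lines are written from
#' \code{metadata(x)$contigLengths} when present, else from observed
#' chromosome labels.
#'
#' @param x a \code{HaplotypeMatrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHaplotypesVcf <- function(x, path) {
  v <- x@variants
  sep <- if (x@phased) "|" else "/"
  lens <- x@metadata$contigLengths
  chroms <- unique(v$chrom)
  contig <- vapply(chroms, function(ch) {
    if (!is.null(lens) && ch %in% names(lens) && !is.na(lens[[ch]]))
      sprintf("##contig=<ID=%s,length=%d>", ch, lens[[ch]])
    else sprintf("##contig=<ID=%s>", ch)
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=haploSweep",
    contig,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x@sampleIds), collapse = "\t")
  )
  a <- x@alleles
  achar <- matrix(as.character(a), nrow = nrow(a))
  achar[is.na(a)] <- "."
  ns <- length(x@sampleIds)
  gtcols <- vapply(seq_len(ns), function(s) {
    paste0(achar[2L * s - 1L, ], sep, achar[2L * s, ])
  }, character(ncol(a)))
  if (ncol(a) == 1L) gtcols <- matrix(gtcols, nrow = 1L)
  body <- paste(
    v$chrom, v$pos, ifelse(is.na(v$id), ".", v$id), v$ref, v$alt,
    ".", ".", ".", "GT",
    apply(gtcols, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
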