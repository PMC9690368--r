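#' Read sample-to-group assignments
#'
#' Parses a TSV with header \code{sample_id  contrast  role} (role is
#' \code{test} or \code{control}) into one \linkS4class{GroupContrast} per
#' distinct contrast, validated against the matrix's sample IDs.
#'
#' @param path TSV file.
#' @param matrix a \code{HaplotypeMatrix} whose samples define the universe.
#' @return Named list of \code{GroupContrast} objects (contrast order of
#'   first appearance).
#' @export
readGroupContrasts <- function(path, matrix) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "contrast", "role")
  if (!all(need %in% names(df)))
    stop("group table must have columns: ", paste(need, collapse = ", "))
  badRole <- setdiff(unique(df$role), c("test", "control"))
  if (length(badRole))
    stop("unknown role(s): ", paste(badRole, collapse = ", "))
  unknown <- setdiff(df$sample_id, sampleIds(matrix))
  if (length(unknown))
    stop("group table names samples absent from the matrix: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (cn in unique(df$contrast)) {
    sub <- df[df$contrast == cn, , drop = FALSE]
    test <- unique(sub$sample_id[sub$role == "test"])
    ctrl <- unique(sub$sample_id[sub$role == "control"])
    both <- intersect(test, ctrl)
    if (length(both))
      stop(sprintf("contrast '%s': sample(s) listed as both test and control: %s",
                   cn, paste(both, collapse = ", ")))
    out[[cn]] <- GroupContrast(cn, test, ctrl, matrix = matrix)
  }
  out
}

#' Write a group table
#'
#' Inverse of \code{readGroupContrasts}; used by the fixture writer.
#' @param contrasts list of \code{GroupContrast}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeGroupContrasts <- function(contrasts, path) {
  rows <- do.call(rbind, lapply(contrasts, function(gc) {
    data.frame(
      sample_id = c(gc@testSamples, gc@controlSamples),
      contrast = gc@name,
      role = rep(c("test", "control"),
                 c(length(gc@testSamples), length(gc@controlSamples))),
      stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and keeps features of type \code{gene} as a
#' \code{GRanges} (1-based inclusive, per GFF3) with a \code{gene_id}
#' metadata column taken from the first available of the \code{gene_id},
#' \code{ID} or \code{Name} attributes. All other feature types (mRNA,
#' exon, ...) are ignored.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} of gene spans with \code{mcols} column \code{gene_id}.
#' @export
readGeneModels <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]]) else
    rep(NA_character_, length(gr))
  gid <- pick("gene_id")
  gid <- ifelse(is.na(gid), pick("ID"), gid)
  gid <- ifelse(is.na(gid), pick("Name"), gid)
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$gene_id <- gid
  out
}

#' Write gene models as GFF3
#'
#' @param genes \code{GRanges} with a \code{gene_id} metadata column.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(genes)),
    source = "haploSweep",
    type = "gene",
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    score = ".",
    strand = ifelse(as.character(GenomicRanges::strand(genes)) == "*", ".",
                    as.character(GenomicRanges::strand(genes))),
    phase = ".",
    attributes = sprintf("ID=%s;gene_id=%s", genes$gene_id, genes$gene_id),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write candidate regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open, so each row has \code{start - 1} and \code{end}. Two custom
#' columns follow BED3: the contrast name and a comma-separated gene list
#' (\code{.} if none). The writer never merges rows.
#'
#' @param regions \code{GRanges} of candidate regions with metadata columns
#'   \code{contrast} and (optionally) \code{genes} (CharacterList or
#'   character).
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  if (!length(regions)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(regions)
  genes <- if ("genes" %in% names(mc)) .collapseGenes(mc$genes) else
    rep(".", length(regions))
  contrast <- if ("contrast" %in% names(mc)) as.character(mc$contrast) else
    rep(".", length(regions))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = GenomicRanges::start(regions) - 1L,
    end = GenomicRanges::end(regions),
    contrast = contrast,
    genes = ifelse(genes == "", ".", genes),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.collapseGenes <- function(g) {
  if (is.character(g)) return(g)
  vapply(as.list(g), function(v) paste(v, collapse = ","), character(1))
}

#' Read a candidate-region BED file
#'
#' Inverse of \code{writeRegionsBed}: restores 1-based inclusive spans and
#' the contrast/genes columns.
#'
#' @param path BED file written by \code{writeRegionsBed}.
#' @return \code{GRanges} with \code{contrast} and \code{genes} columns.
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed",
                            extraCols = c(contrast = "character",
                                          genes = "character"))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$contrast <- gr$contrast
  S4Vectors::mcols(out)$genes <- gr$genes
  out
}
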