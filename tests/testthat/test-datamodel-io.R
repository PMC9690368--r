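test_that("VCF genotypes decode to haplotype rows in sample order", {
  path <- writeVcfLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsampleA\tsampleB",
    "chr1\t500\t.\tA\tG\t.\t.\t.\tGT\t0|1\t1|1"))
  hm <- readHaplotypes(path)
  expect_equal(as.vector(alleleMatrix(hm)), c(0L, 1L, 1L, 1L))
  expect_equal(sampleIds(hm), c("sampleA", "sampleB"))
  expect_equal(variantTable(hm)$pos, 500L)
  expect_equal(hm@metadata$contigLengths, c(chr1 = 100000L))
})

test_that("multiallelic and non-SNV records are rejected and counted", {
  path <- writeVcfLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0|1\t1|1",
    "chr1\t200\t.\tA\tC,T\t.\t.\t.\tGT\t0|1\t1|2",
    "chr1\t300\t.\tAT\tA\t.\t.\t.\tGT\t0|1\t0|0"))
  hm <- readHaplotypes(path)
  expect_equal(nVariants(hm), 1L)
  rej <- hm@metadata$rejections
  expect_equal(rej$count[rej$reason == "multiallelic"], 1L)
  expect_equal(rej$count[rej$reason == "non_snv"], 1L)
})

test_that("unphased genotypes error under requirePhased and name the culprit", {
  path <- writeVcfLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t0|1\t0/1"))
  expect_error(readHaplotypes(path, requirePhased = TRUE),
               "unphased.*chr1:100.*s2")
  hm <- readHaplotypes(path, requirePhased = FALSE)
  expect_equal(as.vector(alleleMatrix(hm)), c(0L, 1L, 0L, 1L))
})

test_that("missing genotypes decode to NA without phasing errors", {
  path <- writeVcfLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\t.\t.\tGT\t.|.\t./."))
  hm <- readHaplotypes(path, requirePhased = TRUE)
  expect_true(all(is.na(alleleMatrix(hm))))
})

test_that("VCF round trip preserves alleles, positions and sample order", {
  hm <- randomMatrix(5, 40, seed = 7, missingRate = 0.05)
  path <- tempfile(fileext = ".vcf")
  writeHaplotypesVcf(hm, path)
  back <- readHaplotypes(path)
  expect_identical(alleleMatrix(back), alleleMatrix(hm))
  expect_equal(variantTable(back)$pos, variantTable(hm)$pos)
  expect_identical(sampleIds(back), sampleIds(hm))
})

test_that("group table parses into validated contrasts", {
  hm <- randomMatrix(4, 5)
  path <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcontrast\trole",
               "S01\tnap_size\ttest", "S02\tnap_size\ttest",
               "S03\tnap_size\tcontrol", "S04\tnap_size\tcontrol"), path)
  gcs <- readGroupContrasts(path, hm)
  expect_length(gcs, 1)
  expect_equal(gcs$nap_size@testSamples, c("S01", "S02"))
  expect_equal(gcs$nap_size@controlSamples, c("S03", "S04"))

  writeLines(c("sample_id\tcontrast\trole",
               "S01\tc1\ttest", "S01\tc1\tcontrol", "S02\tc1\tcontrol"), path)
  expect_error(readGroupContrasts(path, hm), "both test and control")

  writeLines(c("sample_id\tcontrast\trole", "S01\tc1\ttest"), path)
  expect_error(readGroupContrasts(path, hm), "empty|control")

  writeLines(c("sample_id\tcontrast\trole", "ghost\tc1\ttest",
               "S02\tc1\tcontrol"), path)
  expect_error(readGroupContrasts(path, hm), "absent.*ghost")
})

test_that("GFF3 reader keeps gene features only, 1-based inclusive", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr3\ttest\tgene\t100\t200\t.\t+\t.\tID=geneA",
    "chr3\ttest\tmRNA\t100\t200\t.\t+\t.\tID=tx1;Parent=geneA",
    "chr3\ttest\texon\t100\t150\t.\t+\t.\tParent=tx1",
    "chr5\ttest\tgene\t5000\t9000\t.\t-\t.\tID=geneB"), path)
  genes <- readGeneModels(path)
  expect_length(genes, 2)
  expect_equal(genes$gene_id, c("geneA", "geneB"))
  expect_equal(GenomicRanges::start(genes), c(100L, 5000L))
  expect_equal(GenomicRanges::end(genes), c(200L, 9000L))

  writeLines(c("##gff-version 3",
               "chr3\ttest\tmRNA\t100\t200\t.\t+\t.\tID=tx1"), path)
  expect_length(readGeneModels(path), 0)
})

test_that("gene-model round trip through GFF3 preserves inclusive spans", {
  genes <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(c(101, 5001), c(300, 7000)),
    gene_id = c("g1", "g2"))
  path <- tempfile(fileext = ".gff3")
  writeGeneModels(genes, path)
  back <- readGeneModels(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(genes))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(genes))
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("BED export is 0-based half-open and round trips", {
  regions <- GenomicRanges::GRanges(
    "chr8", IRanges::IRanges(26111849, 26121849),
    contrast = "nap_size", genes = "CCM2L")
  path <- tempfile(fileext = ".bed")
  writeRegionsBed(regions, path)
  row <- strsplit(readLines(path), "\t")[[1]]
  expect_equal(as.integer(row[2]), 26111848L)  # start - 1
  expect_equal(as.integer(row[3]), 26121849L)  # inclusive end unchanged
  back <- readRegionsBed(path)
  expect_equal(GenomicRanges::start(back), 26111849L)
  expect_equal(GenomicRanges::end(back), 26121849L)
  expect_equal(back$contrast, "nap_size")
  expect_equal(back$genes, "CCM2L")
})

test_that("empty region list writes an empty BED; writer never merges", {
  path <- tempfile(fileext = ".bed")
  writeRegionsBed(GenomicRanges::GRanges(), path)
  expect_length(readLines(path), 0)

  # overlapping rows on different contrasts stay distinct rows
  regions <- GenomicRanges::GRanges(
    c("chr1", "chr1"), IRanges::IRanges(c(100, 150), c(200, 250)),
    contrast = c("a", "b"), genes = c(".", "."))
  writeRegionsBed(regions, path)
  expect_length(readLines(path), 2)
})

test_that("HaplotypeMatrix validity rejects malformed objects", {
  hm <- randomMatrix(3, 10)
  expect_error(toyMatrix(matrix(0L, 3, 2)), "2 \\* number of samples")
  v <- variantTable(hm)
  expect_error(HaplotypeMatrix(alleleMatrix(hm)[, 1:2],
                               data.frame(chrom = "chr1", pos = c(5, 5),
                                          ref = "A", alt = "G"),
                               sampleIds(hm)),
               "strictly increasing")
  a <- alleleMatrix(hm); a[1, 1] <- 7L
  expect_error(toyMatrix(a), "alleles must be 0, 1 or NA")
})

test_that("contrast invariants are enforced", {
  expect_error(GroupContrast("c", c("a", "b"), c("b", "c")), "overlap")
  expect_error(GroupContrast("c", character(), "b"), "empty")
  hm <- randomMatrix(2, 5)
  expect_error(GroupContrast("c", "S01", "ghost", matrix = hm), "absent")
})
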