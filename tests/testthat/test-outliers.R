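test_that("top-quantile threshold, ties and eligibility rules", {
  vals <- as.numeric(1:1000)
  set <- suppressWarnings(topQuantile(vals, q = 0.01))
  expect_equal(set@threshold, 991)
  expect_length(set@indices, 10)
  expect_setequal(set@indices, 991:1000)

  # 15 values tied at the rank-10 value are all kept
  vals2 <- c(as.numeric(1:985), rep(986, 15))
  set2 <- suppressWarnings(topQuantile(vals2, q = 0.01))
  expect_length(set2@indices, 15)

  # positive_only with no positive values errors
  expect_error(suppressWarnings(
    topQuantile(c(-3, -2, -1), q = 0.01, positiveOnly = TRUE)),
    "no eligible")

  # NA values are never eligible
  vals3 <- c(vals, rep(NA_real_, 50))
  set3 <- suppressWarnings(topQuantile(vals3, q = 0.01))
  expect_equal(set3@nEligible, 1000L)
  expect_setequal(set3@indices, 991:1000)
})

test_that("every excluded eligible value is below the threshold; monotone in q", {
  set.seed(81)
  vals <- rnorm(2000)
  s1 <- suppressWarnings(topQuantile(vals, q = 0.01))
  s5 <- suppressWarnings(topQuantile(vals, q = 0.05))
  excluded <- setdiff(seq_along(vals), s1@indices)
  expect_true(all(vals[excluded] < s1@threshold))
  expect_true(all(s1@indices %in% s5@indices))
})

test_that("outlier intersection is plain set intersection", {
  mk <- function(idx) new("OutlierSet", statistic = "s", threshold = 0,
                          indices = as.integer(idx),
                          nEligible = 100L, q = 0.01)
  expect_equal(intersectOutliers(list(mk(c(1, 2, 3)), mk(c(2, 3, 4)))),
               c(2L, 3L))
  expect_length(intersectOutliers(list(mk(1:3), mk(7:9))), 0)
  expect_equal(intersectOutliers(list(mk(1:10), mk(5:12), mk(8:20))),
               c(8L, 9L, 10L))
})

test_that("single-SNP regions span pos +/- 5 kb; windows merge; bounds clip", {
  r <- snpsToRegions("chr8", 26116849)
  expect_equal(GenomicRanges::start(r), 26111849L)
  expect_equal(GenomicRanges::end(r), 26121849L)
  expect_equal(GenomicRanges::end(r) - GenomicRanges::start(r), 10000L)

  r2 <- snpsToRegions(c("chr1", "chr1"), c(10000, 12000))
  expect_length(r2, 1)
  expect_equal(GenomicRanges::start(r2), 5000L)
  expect_equal(GenomicRanges::end(r2), 17000L)
  expect_equal(unlist(r2$source_snps), c(10000L, 12000L))

  r3 <- snpsToRegions("chr1", 2000)
  expect_equal(GenomicRanges::start(r3), 1L)
  expect_equal(GenomicRanges::end(r3), 7000L)

  r4 <- snpsToRegions("chr1", 999900, chromBounds = c(chr1 = 1000000))
  expect_equal(GenomicRanges::end(r4), 1000000L)

  # same positions on different chromosomes never merge
  r5 <- snpsToRegions(c("chr1", "chr2"), c(10000, 10000))
  expect_length(r5, 2)
})

test_that("region construction is idempotent and coverage bounded", {
  set.seed(83)
  pos <- sort(sample.int(2e6, 200))
  r <- snpsToRegions(rep("chr1", 200), pos)
  again <- GenomicRanges::reduce(r)
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(r))
  expect_equal(GenomicRanges::end(again), GenomicRanges::end(r))
  expect_lte(sum(GenomicRanges::width(r)), 200 * 10001)
  expect_equal(sum(lengths(r$source_snps)), 200L)
})

test_that("gene annotation matches a brute-force all-pairs overlap check", {
  set.seed(85)
  chroms <- c("chr1", "chr2")
  rstart <- sample.int(1e6, 120)
  regions <- GenomicRanges::GRanges(
    sample(chroms, 120, TRUE), IRanges::IRanges(rstart, rstart + 9999))
  gstart <- sample.int(1e6, 300)
  genes <- GenomicRanges::GRanges(
    sample(chroms, 300, TRUE),
    IRanges::IRanges(gstart, gstart + sample.int(50000, 300)),
    gene_id = sprintf("g%03d", 1:300))
  ann <- annotateRegions(regions, genes)
  for (i in seq_along(regions)) {
    want <- character()
    for (k in seq_along(genes)) {
      sameChrom <- as.character(GenomicRanges::seqnames(regions)[i]) ==
        as.character(GenomicRanges::seqnames(genes)[k])
      if (sameChrom &&
          GenomicRanges::start(genes)[k] <= GenomicRanges::end(regions)[i] &&
          GenomicRanges::end(genes)[k] >= GenomicRanges::start(regions)[i])
        want <- c(want, genes$gene_id[k])
    }
    expect_setequal(unlist(ann$genes[[i]]), want)
  }
})

test_that("boundary and chromosome rules for gene assignment", {
  region <- GenomicRanges::GRanges("chr3",
                                   IRanges::IRanges(182662938, 182672938))
  genes <- GenomicRanges::GRanges(
    c("chr3", "chr3", "chr4"),
    IRanges::IRanges(c(182662938, 182662838, 182662938),
                     c(182685570, 182662938, 182685570)),
    gene_id = c("inside", "bookend", "wrongchrom"))
  ann <- annotateRegions(region, genes)
  got <- unlist(ann$genes[[1]])
  expect_true("inside" %in% got)     # overlapping span assigned
  expect_true("bookend" %in% got)    # 1-bp closed-interval overlap counts
  expect_false("wrongchrom" %in% got)
})

test_that("region tables are deterministic for identical inputs", {
  mk <- function() {
    r <- snpsToRegions(rep("chr1", 3), c(10000, 12000, 50000))
    S4Vectors::mcols(r)$contrast <- "c"
    S4Vectors::mcols(r)$support <- "3way"
    annotateRegions(r, GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(9000, 11000), gene_id = "gA"))
  }
  t1 <- regionTable(mk()); t2 <- regionTable(mk())
  expect_identical(t1, t2)
  expect_equal(t1$span[1], "5000-17000")
  expect_equal(t1$genes[1], "gA")
  expect_equal(t1$genes[2], ".")
})
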