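test_that("EHH examples: core value, group partition, degenerate identity", {
  # 4 haplotypes, identical at core; at the next site they split {2,1,1}
  haps <- rbind(c(0, 0), c(0, 0), c(0, 1), c(0, NA))
  cv <- ehhAtCore(haps, 1, c(1000, 2000))
  expect_equal(cv$right$ehh[1], 1)          # offset 0 by definition
  expect_equal(cv$right$ehh[2], 1 / 6)      # one identical pair of C(4,2)

  # all haplotypes identical over the whole chromosome
  haps <- matrix(1L, nrow = 6, ncol = 5)
  pos <- c(0, 2500, 5000, 7500, 10000) + 1
  cv <- ehhAtCore(haps, 1, pos)
  expect_true(all(cv$right$ehh == 1))
  expect_equal(integrateEhh(cv), 10000)     # iHH = chromosome span
})

test_that("EHH equals the pair-enumeration oracle on small matrices", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    m <- sample(5:15, 1)
    haps <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    if (rep %% 4 == 0) haps[sample(length(haps), 3)] <- NA
    pos <- sort(sample.int(50000, m))
    core <- sample(m, 1)
    cv <- ehhAtCore(haps, core, pos, cutoff = 0, maxGap = Inf)
    for (k in seq_len(nrow(cv$right))[-1]) {
      j <- core + k - 1
      expect_equal(cv$right$ehh[k], ehhPairOracle(haps, core:j))
    }
    for (k in seq_len(nrow(cv$left))[-1]) {
      j <- core - k + 1
      expect_equal(cv$left$ehh[k], ehhPairOracle(haps, j:core))
    }
  }
})

test_that("EHH is non-increasing with distance and within [0,1]", {
  set.seed(43)
  for (rep in 1:10) {
    haps <- matrix(rbinom(10 * 20, 1, 0.5), nrow = 10)
    cv <- ehhAtCore(haps, 10, sort(sample.int(1e5, 20)), cutoff = 0,
                    maxGap = Inf)
    for (arm in list(cv$left, cv$right)) {
      expect_true(all(diff(arm$ehh) <= 1e-12))
      expect_true(all(arm$ehh >= 0 & arm$ehh <= 1))
    }
  }
})

test_that("integration truncates at the cutoff crossing and at gaps", {
  # plateau at 1 over 10 kb then sharp drop below cutoff
  curve <- structure(list(
    core_index = 1, core_pos = 0,
    left = data.frame(pos = 0, offset = 0, ehh = 1),
    right = data.frame(pos = c(0, 10000, 10001),
                       offset = c(0, 10000, 10001),
                       ehh = c(1, 1, 0))), class = "EhhCurve")
  expect_equal(integrateEhh(curve, cutoff = 0.05), 10000.5, tolerance = 1e-3)

  # two sites 250 kb apart with max-gap 200 kb: arm stops at first site
  gapped <- structure(list(
    core_index = 1, core_pos = 0,
    left = data.frame(pos = 0, offset = 0, ehh = 1),
    right = data.frame(pos = c(0, 1000, 251000),
                       offset = c(0, 1000, 251000),
                       ehh = c(1, 0.9, 0.8))), class = "EhhCurve")
  expect_equal(integrateEhh(gapped, maxGap = 200000, cutoff = 0.05),
               1000 * (1 + 0.9) / 2)

  # linear decay 1 -> 0 over 10 kb against a dense numerical oracle
  off <- seq(0, 10000, by = 500)
  lin <- structure(list(
    core_index = 1, core_pos = 0,
    left = data.frame(pos = 0, offset = 0, ehh = 1),
    right = data.frame(pos = off, offset = off, ehh = 1 - off / 10000)),
    class = "EhhCurve")
  f <- function(x) pmax(1 - x / 10000, 0)
  xs <- seq(0, 9500, length.out = 20001)  # crossing at EHH = 0.05
  oracle <- sum((f(xs[-1]) + f(xs[-length(xs)])) / 2 * diff(xs))
  expect_equal(integrateEhh(lin, cutoff = 0.05), oracle, tolerance = 1e-3)
})

test_that("compiled XP-EHH scan matches the pair-enumeration oracle", {
  set.seed(47)
  for (rep in 1:5) {
    hm <- randomMatrix(6, 25, seed = 100 + rep)
    gc <- twoGroupContrast(hm)
    res <- xpehhScan(hm, gc, maxGap = 50000, cutoff = 0.05)
    haps <- alleleMatrix(hm)
    pos <- variantTable(hm)$pos
    for (core in c(1, 5, 13, 25)) {
      want <- xpehhSiteOracle(haps, 1:6, 7:12, core, pos,
                              maxGap = 50000, cutoff = 0.05)
      expect_equal(res$ihh_test[core], unname(want["ihh_test"]),
                   tolerance = 1e-10)
      expect_equal(res$ihh_control[core], unname(want["ihh_control"]),
                   tolerance = 1e-10)
    }
  }
})

test_that("XP-EHH is antisymmetric under swapping test and control", {
  hm <- randomMatrix(8, 40, seed = 53)
  ids <- sampleIds(hm)
  ab <- xpehhScan(hm, GroupContrast("ab", ids[1:4], ids[5:8]))
  ba <- xpehhScan(hm, GroupContrast("ba", ids[5:8], ids[1:4]))
  ok <- !is.na(ab$xpehh_raw) & !is.na(ba$xpehh_raw)
  expect_gt(sum(ok), 0)
  expect_equal(ab$xpehh_raw[ok], -ba$xpehh_raw[ok], tolerance = 1e-12)
})

test_that("identical haplotype sets in both groups give XP-EHH of zero", {
  block <- matrix(rbinom(4 * 30, 1, 0.5), nrow = 4)
  haps <- rbind(block, block)     # test == control haplotypes
  hm <- toyMatrix(haps)
  gc <- twoGroupContrast(hm)
  res <- xpehhScan(hm, gc)
  ok <- !is.na(res$xpehh_raw)
  expect_true(all(abs(res$xpehh_raw[ok]) < 1e-12))
})

test_that("unphased matrices are rejected by the XP-EHH scan", {
  hm <- randomMatrix(6, 10, seed = 59)
  hm@phased <- FALSE
  expect_error(xpehhScan(hm, twoGroupContrast(hm)), "phased")
})

test_that("normalization yields mean 0 and sd 1; degenerate input errors", {
  df <- data.frame(xpehh_raw = c(-1, 0, 1))
  norm <- normalizeXpehh(df)
  expect_equal(norm$xpehh_norm, c(-1, 0, 1))   # sample sd is already 1

  hm <- randomMatrix(8, 200, seed = 61)
  res <- normalizeXpehh(xpehhScan(hm, twoGroupContrast(hm)))
  ok <- !is.na(res$xpehh_norm)
  expect_equal(mean(res$xpehh_norm[ok]), 0, tolerance = 1e-9)
  expect_equal(sd(res$xpehh_norm[ok]), 1, tolerance = 1e-9)

  expect_error(normalizeXpehh(data.frame(xpehh_raw = c(2, 2, 2))),
               "constant")
  expect_error(normalizeXpehh(data.frame(xpehh_raw = c(1, NA))),
               "at least 2")
})

test_that("a full-frequency sweep maximizes XP-EHH inside the sweep span", {
  sim <- simulateSweepData(simConfig(
    seed = 67, nChrom = 1, nSnpsPerChrom = 1200, chromLength = 12e6,
    sweep = list(chrom = "chr1", pos = 6e6, carrierFreq = 1, span = 5e5)))
  hm <- applyQc(sim$haplotypes)$matrix
  res <- suppressWarnings(
    normalizeXpehh(xpehhScan(hm, sim$contrast)))
  top <- which.max(res$xpehh_norm)
  iv <- sim$truth$sweep$interval
  expect_gte(res$pos[top], iv[1])
  expect_lte(res$pos[top], iv[2])
  # carrier haplotypes are identical across the span
  spanIdx <- which(variantTable(sim$haplotypes)$pos >= iv[1] &
                     variantTable(sim$haplotypes)$pos <= iv[2])
  carriers <- alleleMatrix(sim$haplotypes)[sim$truth$sweep$carrierRows,
                                           spanIdx]
  expect_true(all(apply(carriers, 2, function(col) length(unique(col)) == 1)))
})
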