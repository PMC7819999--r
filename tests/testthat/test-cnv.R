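normalizedCohort <- function(...) {
  co <- makeCohort(...)
  dyeBiasCorrect(backgroundCorrect(co))
}

test_that("log2 ratios are centred for neutral samples and see injected gains", {
  co <- makeCohort(nClasses = 2, samplesPerClass = 8, nProbes = 1200,
                   nInformative = 20, concentration = 100, seed = 111)
  # events span all of chr1 (~55 probes)
  gained <- injectCNV(co, "S001", "chr1", 1, 6e5, copyState = 3, purity = 1)
  norm <- dyeBiasCorrect(backgroundCorrect(gained))
  # neutral sample: ratios centred at 0
  lr_neutral <- log2Ratio(norm, "S005")
  expect_lt(abs(median(lr_neutral$ratios)), 0.05)
  # in-region mean close to log2(1.5); half-copy loss scale at purity 0.5
  lr <- log2Ratio(norm, "S001")
  in_region <- lr$info$chromosome == "chr1"
  expect_gt(sum(in_region), 10)
  expect_lt(abs(mean(lr$ratios[in_region]) - log2(1.5)), 0.05)

  lost <- injectCNV(co, "S002", "chr1", 1, 6e5, copyState = 1, purity = 0.5)
  norm2 <- dyeBiasCorrect(backgroundCorrect(lost))
  lr2 <- log2Ratio(norm2, "S002")
  expect_lt(abs(mean(lr2$ratios[in_region]) - log2(0.75)), 0.05)
  expect_error(log2Ratio(norm, "nope"), "unknown sample")
})

test_that("binning groups probes like a brute-force grouped mean", {
  set.seed(3)
  info <- data.frame(probe_id = sprintf("p%03d", 1:60),
                     chromosome = rep(c("chr1", "chr2"), each = 30),
                     position = rep(seq(5000, 295000, by = 10000), 2))
  ratios <- setNames(rnorm(60), info$probe_id)
  # 10 probes per 100kb bin exactly
  bins <- binGenome(ratios, info, minProbesPerBin = 5, targetBinBp = 100000)
  expect_equal(nrow(bins), 6)
  expect_equal(bins$n_probes, rep(10, 6))
  oracle <- as.vector(vapply(split(ratios, rep(1:6, each = 10)), mean,
                             numeric(1)))
  expect_equal(bins$mean_ratio, oracle)
  # a trailing bin below the minimum merges into its left neighbour
  short <- info[info$position <= 120000 & info$chromosome == "chr1", ]
  r2 <- ratios[short$probe_id]
  b2 <- binGenome(r2, short, minProbesPerBin = 5, targetBinBp = 100000)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_probes, 12)
  expect_equal(b2$mean_ratio, mean(r2))
  # bins tile without overlap
  expect_true(all(bins$start[bins$chromosome == "chr1"] ==
                    c(0, 100000, 200000)))
})

test_that("segmentation finds exact change points and respects the penalty", {
  # noiseless step: exactly two segments with the true breakpoint
  bins <- data.frame(chromosome = "chr1",
                     start = seq(0, 1900000, by = 100000),
                     end = seq(100000, 2e6, by = 100000),
                     mean_ratio = rep(c(0, 0.585), each = 10),
                     n_probes = 10)
  segs <- segmentBins(bins, penalty = 0.01)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], 1000000)
  expect_equal(segs$mean_ratio, c(0, 0.585))
  # flat noise with a high penalty: one segment per chromosome
  set.seed(9)
  bins$mean_ratio <- rnorm(20, 0, 0.05)
  one <- segmentBins(bins, penalty = 10)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_bins, 20)
  # conservation: bin-weighted mean of segment means equals the bin mean
  set.seed(10)
  bins$mean_ratio <- rnorm(20, 0, 0.3)
  segs2 <- segmentBins(bins, penalty = 0.05)
  expect_equal(sum(segs2$mean_ratio * segs2$n_bins) / sum(segs2$n_bins),
               mean(bins$mean_ratio), tolerance = 1e-9)
})

test_that("two events on one chromosome are recovered within 0.1", {
  hits <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    truth <- rep(0, 40)
    truth[11:20] <- 0.585
    truth[31:38] <- -0.415
    bins <- data.frame(chromosome = "chr1",
                       start = seq(0, 39) * 1e5, end = seq(1, 40) * 1e5,
                       mean_ratio = truth + rnorm(40, 0, 0.1), n_probes = 10)
    segs <- segmentBins(bins)
    gain <- segs[segs$mean_ratio > 0.3, ]
    loss <- segs[segs$mean_ratio < -0.2, ]
    if (nrow(segs) >= 3 && nrow(gain) >= 1 && nrow(loss) >= 1 &&
        abs(gain$mean_ratio[1] - 0.585) < 0.1 &&
        abs(loss$mean_ratio[1] + 0.415) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("per-class summaries count gains and losses per bin", {
  co <- makeCohort(nClasses = 2, samplesPerClass = 6, nProbes = 600,
                   nInformative = 20, concentration = 100, seed = 121)
  half <- sprintf("S%03d", 1:3)  # half of class01 carries the gain
  for (s in half)
    co <- injectCNV(co, s, "chr1", 1, 4e5, copyState = 3, purity = 1)
  norm <- dyeBiasCorrect(backgroundCorrect(co))
  base <- cnvBaseline(norm)
  cls1 <- sampleSheet(co)$sample_id[classLabelsOf(co) == "class01"]
  profiles <- lapply(cls1, function(s)
    cnvProfile(norm, s, baseline = base, minProbesPerBin = 3,
               targetBinBp = 100000))
  summ <- summarizeClass(profiles)
  in_region <- summ$chromosome == "chr1"
  expect_true(all(summ$gain_freq[in_region] == 0.5))
  out_region <- !in_region
  expect_true(all(summ$gain_freq[out_region] <= 1 / 6))
  expect_true(all(summ$loss_freq < 0.5))
  expect_equal(summ$n_samples[1], 6)
  # SEG export round-trips the segment table
  f <- tempfile(fileext = ".seg")
  writeSEG(profiles[[1]], f)
  seg <- read.delim(f)
  expect_equal(nrow(seg), nrow(cnvSegments(profiles[[1]])))
  expect_true(all(c("ID", "chrom", "seg.mean") %in% colnames(seg)))
})

test_that("CNV injection leaves classification inputs untouched end-to-end", {
  co <- makeCohort(nClasses = 2, samplesPerClass = 6, nProbes = 300,
                   nInformative = 30, separation = 0.5, concentration = 150,
                   seed = 131)
  with_cnv <- injectCNV(co, "S001", "chr1", 1, 250000, copyState = 4,
                        purity = 0.8)
  b0 <- SummarizedExperiment::assay(preprocessCohort(co))
  b1 <- SummarizedExperiment::assay(preprocessCohort(with_cnv))
  # beta perturbation is bounded by the offset term at these intensities
  expect_lt(max(abs(b0 - b1)), 0.02)
  cfg <- forestConfig(nTrees = 100, seed = 3)
  m0 <- trainForest(b0, classLabelsOf(co), rownames(b0), cfg)
  expect_identical(colnames(rawScores(m0, b1))[apply(rawScores(m0, b1), 1, which.max)],
                   colnames(rawScores(m0, b0))[apply(rawScores(m0, b0), 1, which.max)])
})
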