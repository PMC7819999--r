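test_that("annotation composition matches the requested fractions exactly", {
  ann <- simulateAnnotation(10, fracXY = 0.2, fracSNP = 0.1,
                            fracNonunique = 0.1, frac450kOnly = 0.1,
                            nControlsPerType = 2, seed = 7)
  meas <- ann[ann$control_type == "none", ]
  expect_equal(nrow(meas), 10)
  expect_equal(sum(meas$chromosome %in% c("chrX", "chrY")), 2)
  expect_equal(sum(meas$snp_within_5bp), 1)
  expect_equal(sum(!meas$maps_uniquely), 1)
  expect_equal(sum(!meas$on_epic), 1)
  # the four exclusion sets are disjoint, so exactly 5 probes survive
  surv <- meas$chromosome %in% paste0("chr", 1:22) & !meas$snp_within_5bp &
    meas$maps_uniquely & meas$on_450k & meas$on_epic
  expect_equal(sum(surv), 5)
  # no exclusion flags -> everything survives
  clean <- simulateAnnotation(20, 0, 0, 0, 0, nControlsPerType = 1, seed = 1)
  cm <- clean[clean$control_type == "none", ]
  expect_true(all(cm$chromosome %in% paste0("chr", 1:22) & !cm$snp_within_5bp &
                    cm$maps_uniquely & cm$on_450k & cm$on_epic))
})

test_that("annotation invariants hold and generation is deterministic", {
  a1 <- simulateAnnotation(100, seed = 42)
  a2 <- simulateAnnotation(100, seed = 42)
  expect_identical(a1, a2)
  expect_false(anyDuplicated(a1$probe_id) > 0)
  ctl <- a1$control_type != "none"
  expect_true(all(is.na(a1$chromosome[ctl])))
  expect_true(all(!is.na(a1$chromosome[!ctl])))
  expect_true(all(a1$position[!ctl] > 0))
  # positions ascend within each chromosome
  for (cc in unique(a1$chromosome[!ctl]))
    expect_true(!is.unsorted(a1$position[!ctl][a1$chromosome[!ctl] == cc]))
  expect_error(simulateAnnotation(5), "at least 10")
  expect_error(simulateAnnotation(100, fracXY = 0.5, fracSNP = 0.6),
               "sum to less than 1")
})

test_that("noiseless pure samples recover the class archetypes exactly", {
  co <- makeCohort(nClasses = 2, samplesPerClass = 3, nProbes = 100,
                   nInformative = 10, concentration = Inf,
                   purityRange = c(1, 1), batch = 0, background = 0, seed = 3)
  arch <- S4Vectors::metadata(co)$archetypes
  beta <- methylated(co) / (methylated(co) + unmethylated(co))
  for (k in colnames(arch)) {
    cols <- classLabelsOf(co) == k
    expect_true(max(abs(beta[, cols] - arch[, k])) < 1e-6)
  }
})

test_that("cohort generation is deterministic and purity mixing is affine", {
  co1 <- makeCohort(seed = 11)
  co2 <- makeCohort(seed = 11)
  expect_identical(methylated(co1), methylated(co2))
  expect_identical(sampleSheet(co1), sampleSheet(co2))

  # two classes, separation 0.6: mean |class-mean difference| at informative
  # probes is separation * mean(purity) (closed form of the mixing model)
  co <- makeCohort(nClasses = 2, samplesPerClass = 20, nProbes = 500,
                   nInformative = 50, separation = 0.6, concentration = 500,
                   purityRange = c(0.3, 1), background = 0, seed = 5)
  ss <- sampleSheet(co)
  beta <- methylated(co) / (methylated(co) + unmethylated(co))
  inf <- S4Vectors::metadata(co)$informative
  m1 <- rowMeans(beta[inf, ss$class_label == "class01"])
  m2 <- rowMeans(beta[inf, ss$class_label == "class02"])
  expected <- 0.6 * mean(ss$purity)
  expect_lt(abs(mean(abs(m1 - m2)) - expected), 0.03)

  # regression of per-sample mean informative beta on purity: slope matches
  # the archetype-leukocyte contrast within 3 standard errors, per class
  arch <- S4Vectors::metadata(co)$archetypes
  leuk <- S4Vectors::metadata(co)$leukocyte
  inf_idx <- match(inf, rownames(co))
  for (k in colnames(arch)) {
    cols <- ss$class_label == k
    y <- colMeans(beta[inf, cols])
    fit <- summary(lm(y ~ ss$purity[cols]))$coefficients
    slope_expected <- mean(arch[inf_idx, k] - leuk[inf_idx])
    expect_lt(abs(fit[2, 1] - slope_expected), 3 * fit[2, 2])
  }
})

test_that("purity zero collapses all classes onto the leukocyte archetype", {
  co <- makeCohort(nClasses = 3, samplesPerClass = 5, nProbes = 200,
                   nInformative = 20, concentration = Inf,
                   purityRange = c(0, 0), batch = 0, background = 0, seed = 9)
  beta <- methylated(co) / (methylated(co) + unmethylated(co))
  leuk <- S4Vectors::metadata(co)$leukocyte
  expect_true(max(abs(beta - leuk)) < 1e-6)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nInformative = 100, nProbes = 50), "exceed")
  expect_error(cohortConfig(archetypeSeparation = 1.2), "outside")
  expect_error(cohortConfig(samplesPerClass = 3), "at least 7")
})

test_that("CNV injection scales totals but conserves beta", {
  co <- makeCohort(nClasses = 2, samplesPerClass = 2, nProbes = 100,
                   nInformative = 10, background = 0, seed = 21)
  ann <- as.data.frame(SummarizedExperiment::rowData(co))
  on_chr1 <- ann$chromosome == "chr1" & ann$position <= 100000
  expect_gt(sum(on_chr1), 0)
  beta0 <- methylated(co) / (methylated(co) + unmethylated(co))
  tot0 <- methylated(co) + unmethylated(co)

  # copy state 3 at purity 1: totals x1.5; expected log2 ratio ~ 0.585
  g <- injectCNV(co, "S001", "chr1", 1, 100000, copyState = 3, purity = 1)
  tot1 <- methylated(g) + unmethylated(g)
  expect_equal(tot1[on_chr1, "S001"] / tot0[on_chr1, "S001"],
               rep(1.5, sum(on_chr1)), ignore_attr = TRUE)
  beta1 <- methylated(g) / (methylated(g) + unmethylated(g))
  expect_lt(max(abs(beta1 - beta0)), 1e-12)

  # copy state 4 at purity 0.5: scale = 0.5*2 + 0.5 = 1.5
  h <- injectCNV(co, "S002", "chr1", 1, 100000, copyState = 4, purity = 0.5)
  tot2 <- methylated(h) + unmethylated(h)
  expect_equal(tot2[on_chr1, "S002"] / tot0[on_chr1, "S002"],
               rep(1.5, sum(on_chr1)), ignore_attr = TRUE)

  # neutral state leaves the sample unchanged
  n <- injectCNV(co, "S001", "chr1", 1, 100000, copyState = 2, purity = 1)
  expect_equal(methylated(n), methylated(co))

  # empty region: warning, unchanged
  expect_warning(z <- injectCNV(co, "S001", "chr21", 99e6, 100e6, 3),
                 "no probe")
  expect_equal(methylated(z), methylated(co))
  expect_error(injectCNV(co, "S001", "chr1", 1, 100000, copyState = 0),
               "positive")
})
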