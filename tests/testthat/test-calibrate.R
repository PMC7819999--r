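oofFixture <- function(seed = 71, nClasses = 3, spc = 9, conc = 150,
                       sep = 0.5, nTrees = 150) {
  co <- makeCohort(nClasses = nClasses, samplesPerClass = spc,
                   nProbes = 300, nInformative = 30, separation = sep,
                   concentration = conc, seed = seed)
  beta <- SummarizedExperiment::assay(preprocessCohort(co))
  labels <- classLabelsOf(co)
  oof <- oofRawScores(beta, labels, forestConfig(nTrees = nTrees, seed = seed),
                      nFolds = 3, seed = seed)
  list(beta = beta, labels = labels, oof = oof)
}

test_that("out-of-fold scores honour the cross-validation contract", {
  fx <- oofFixture(seed = 71)
  expect_false(anyNA(fx$oof))
  expect_lt(max(abs(rowSums(fx$oof) - 1)), 1e-9)
  folds <- attr(fx$oof, "fold")
  expect_setequal(unique(folds), 1:3)
  # stratification: every class appears in every fold
  expect_true(all(table(fx$labels, folds) > 0))
  # separable fixture: out-of-fold argmax is essentially perfect
  pred <- colnames(fx$oof)[apply(fx$oof, 1, which.max)]
  expect_gte(mean(pred == fx$labels), 0.95)
  expect_error(oofRawScores(fx$beta, rep(c("a", "b", "c"), c(13, 13, 1)),
                            forestConfig(nTrees = 50), nFolds = 3),
               "smaller than the number of folds")
})

test_that("leave-one-out folds equal an explicit per-sample loop", {
  co <- makeCohort(nClasses = 3, samplesPerClass = 3, nProbes = 150,
                   nInformative = 15, separation = 0.5, concentration = 200,
                   seed = 73)
  b <- SummarizedExperiment::assay(preprocessCohort(co))
  y <- factor(classLabelsOf(co))
  cfg <- forestConfig(nTrees = 60, seed = 5)
  loo <- oofRawScores(b, y, cfg, nFolds = ncol(b), seed = 1)
  for (i in seq_len(ncol(b))) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    ranked <- rankProbesByImportance(b[, -i], y[-i], cfg_i)
    sel <- ranked[seq_len(min(cfg_i$nSelectedCpGs, length(ranked)))]
    m <- trainForest(b[, -i], y[-i], sel, cfg_i)
    expect_equal(unname(loo[i, ]),
                 unname(rawScores(m, b[, i, drop = FALSE])[1, ]))
  }
})

test_that("calibration fit matches an independent ridge-regression solver", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  n <- 60
  x <- cbind(a = runif(n), b = runif(n))
  x <- x / rowSums(x)
  y <- ifelse(x[, "a"] + rnorm(n, 0, 0.2) > 0.5, "a", "b")
  lam <- 0.5
  fit <- fitCalibration(x, y, lam)
  p_mine <- calibrateScores(fit, x)[, "b"]
  # same objective in glmnet's parameterization: binary ridge logistic
  # with lambda/(2n) (symmetric two-row softmax doubles the penalty on the
  # effective coefficient, glmnet divides the log-likelihood by n)
  g <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                      lambda = lam / (2 * n), thresh = 1e-14,
                      standardize = FALSE)
  p_glmnet <- predict(g, newx = x, type = "response")[, 1]
  expect_lt(max(abs(p_mine - p_glmnet)), 1e-5)
})

test_that("calibration limits: heavy penalty gives class frequencies, light keeps argmax", {
  fx <- oofFixture(seed = 79)
  freq <- as.numeric(table(factor(fx$labels)) / length(fx$labels))
  heavy <- fitCalibration(fx$oof, fx$labels, 1e6)
  cal_heavy <- calibrateScores(heavy, fx$oof)
  expect_equal(unname(cal_heavy[1, ]), freq, tolerance = 1e-3)
  expect_equal(unname(cal_heavy[10, ]), freq, tolerance = 1e-3)

  light <- fitCalibration(fx$oof, fx$labels, 0.01)
  cal_light <- calibrateScores(light, fx$oof)
  expect_identical(apply(cal_light, 1, which.max),
                   apply(fx$oof, 1, which.max))
  expect_lt(max(abs(rowSums(cal_light) - 1)), 1e-9)
  expect_error(fitCalibration(fx$oof, fx$labels, -1), "non-negative")
})

test_that("zero coefficients calibrate everything to uniform rows", {
  model <- new("CalibrationModel",
               coefficients = matrix(0, 3, 4,
                                     dimnames = list(c("a", "b", "c"), NULL)),
               lambda = 1, classLabels = c("a", "b", "c"),
               convergence = list(grad_norm = 0, objective = 0))
  raw <- matrix(runif(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  raw <- raw / rowSums(raw)
  expect_equal(unname(calibrateScores(model, raw)),
               matrix(1 / 3, 4, 3), tolerance = 1e-12)
  expect_error(calibrateScores(model, raw[, c(2, 1, 3)]), "match")
})

test_that("Youden index equals hand-enumerated sensitivity and specificity", {
  # 6 samples: correct with scores .95 .85 .92, incorrect with .91 .70 .60
  ms <- c(0.95, 0.85, 0.92, 0.91, 0.70, 0.60)
  ok <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  # sens = 2/3 (two correct reach 0.9), spec = 2/3 (two incorrect below)
  expect_equal(youdenIndex(ms, ok, 0.9), 2 / 3 + 2 / 3 - 1)
  # perfect separation of the binary variable
  expect_equal(youdenIndex(c(0.95, 0.99, 0.2, 0.3),
                           c(TRUE, TRUE, FALSE, FALSE), 0.9), 1)
  # vacuous groups are perfect
  expect_equal(youdenIndex(c(0.95, 0.99), c(TRUE, TRUE), 0.9), 1)
})

test_that("lambda tuning maximizes the resampled Youden index at 0.9", {
  fx <- oofFixture(seed = 83)
  # grid of one: returned regardless of the scores
  one <- tuneLambda(fx$oof, fx$labels, lambdaGrid = 0.123, nReps = 2, seed = 4)
  expect_equal(as.numeric(one), 0.123)

  grid <- c(1e-3, 1e-1, 10)
  picked <- tuneLambda(fx$oof, fx$labels, lambdaGrid = grid, nReps = 10,
                       seed = 9)
  avg <- attr(picked, "youden")
  expect_length(avg, 3)
  expect_equal(as.numeric(picked), grid[which.max(avg)])

  # independent naive re-implementation of the whole procedure, same seeds
  y <- factor(fx$labels, levels = colnames(fx$oof))
  youden <- matrix(NA_real_, 10, length(grid))
  for (r in 1:10) {
    set.seed(9 + r)
    train <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      m <- min(length(idx) - 1, max(1, floor(0.7 * length(idx))))
      sample(idx, m)
    }))
    test <- setdiff(seq_along(y), train)
    for (j in seq_along(grid)) {
      f <- fitCalibration(fx$oof[train, ], y[train], grid[j])
      cal <- calibrateScores(f, fx$oof[test, ])
      mx <- apply(cal, 1, max)
      correct <- colnames(cal)[apply(cal, 1, which.max)] == as.character(y[test])
      sens <- if (any(correct)) mean(mx[correct] >= 0.9) else 1
      spec <- if (any(!correct)) mean(mx[!correct] < 0.9) else 1
      youden[r, j] <- sens + spec - 1
    }
  }
  expect_equal(as.numeric(picked), grid[which.max(colMeans(youden))])
  expect_equal(unname(avg), colMeans(youden))
})

test_that("MCF scores are exact sums and never exceed one", {
  set.seed(12)
  raw <- matrix(runif(40), 10, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  raw <- raw / rowSums(raw)
  mcf <- list(fam1 = c("a", "b"), fam2 = "c")
  fam <- aggregateMCF(raw, mcf)
  expect_equal(fam[, "fam1"], raw[, "a"] + raw[, "b"])
  expect_equal(fam[, "fam2"], raw[, "c"])  # single member: identical score
  expect_true(all(fam <= 1 + 1e-12))
  # all classes in one family: score exactly 1 by row-stochasticity
  all_in <- aggregateMCF(raw, list(all = c("a", "b", "c", "d")))
  expect_equal(unname(all_in[, 1]), rep(1, 10))
  expect_error(aggregateMCF(raw, list(f1 = c("a", "b"), f2 = c("b", "c"))),
               "overlapping")
  expect_error(aggregateMCF(raw, list(f1 = c("a", "zz"))), "not among")
  # a family can cross the cutoff though no member does
  two <- matrix(c(0.50, 0.45, 0.05), 1, 3,
                dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(aggregateMCF(two, list(f = c("a", "b")))[1, 1]), 0.95)
})

test_that("threshold predictions follow the 0.9 rule with family rescue", {
  cal <- rbind(s1 = c(a = 0.92, b = 0.05, c = 0.03),
               s2 = c(a = 0.89, b = 0.06, c = 0.05),
               s3 = c(a = 0.48, b = 0.47, c = 0.05))
  fam <- aggregateMCF(cal, list(ab = c("a", "b")))
  pred <- predictWithThreshold(cal, fam, cutoff = 0.9)
  expect_equal(pred$classifiable, c(TRUE, TRUE, TRUE))
  # s2 without family help stays below the cutoff
  pred_nf <- predictWithThreshold(cal, cutoff = 0.9)
  expect_equal(pred_nf$classifiable, c(TRUE, FALSE, FALSE))
  # family rescue keeps the member argmax as best_class
  expect_equal(pred$best_class[3], "a")
  expect_equal(pred$best_family[3], "ab")
  expect_equal(pred$family_score[3], 0.95)
  # ties at argmax break lexicographically
  tie <- matrix(c(0.5, 0.5, 0), 1, 3, dimnames = list(NULL, c("b", "a", "c")))
  expect_equal(predictWithThreshold(tie)$best_class, "a")
})

test_that("raising the cutoff only shrinks the classifiable set", {
  set.seed(31)
  cal <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  cal <- cal / rowSums(cal)
  fam <- aggregateMCF(cal, list(ab = c("a", "b")))
  prev <- rep(TRUE, 20)
  for (cut in seq(0, 1, by = 0.05)) {
    cur <- predictWithThreshold(cal, fam, cutoff = cut)$classifiable
    expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("calibration never worsens the Brier score of out-of-fold scores", {
  fx <- oofFixture(seed = 89, conc = 40, sep = 0.35)
  fit <- fitCalibration(fx$oof, fx$labels, 0.05)
  cal <- calibrateScores(fit, fx$oof)
  expect_lte(brierScore(cal, fx$labels), brierScore(fx$oof, fx$labels))
})
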