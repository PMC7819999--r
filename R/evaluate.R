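#' Misclassification rate of the argmax prediction
#'
#' @param scores samples x classes row-stochastic score matrix.
#' @param labels true class per sample.
#' @return fraction of samples whose argmax class differs from the truth.
#' @export
misclassificationRate <- function(scores, labels) {
  pred <- colnames(scores)[apply(scores, 1, which.max)]
  mean(pred != as.character(labels))
}

#' Confusion matrix of the argmax prediction
#'
#' @param scores samples x classes score matrix.
#' @param labels true class per sample.
#' @return K x K table, rows = true class, columns = predicted.
#' @export
confusionMatrix <- function(scores, labels) {
  cls <- colnames(scores)
  pred <- factor(cls[apply(scores, 1, which.max)], levels = cls)
  truth <- factor(as.character(labels), levels = cls)
  table(true = truth, predicted = pred)
}

# two-class AUC of score s: P(s_pos > s_neg) + 0.5 P(tie), by ranks
.pairAUC <- function(s_pos, s_neg) {
  r <- rank(c(s_pos, s_neg))
  n1 <- length(s_pos); n0 <- length(s_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multi-class AUC (Hand-Till construction)
#'
#' For every unordered class pair (i, j), the two-class AUC A(i|j) is the
#' probability that a random class-i sample receives a higher score for
#' class i than a random class-j sample; the pair's AUC is the average of
#' A(i|j) and A(j|i), and the overall measure averages over all pairs.
#' Pairs involving a class absent from the labels are skipped with a
#' message.
#'
#' @param scores samples x classes score matrix.
#' @param labels true class per sample.
#' @return scalar in [0, 1].
#' @export
multiclassAUC <- function(scores, labels) {
  cls <- colnames(scores)
  labels <- as.character(labels)
  present <- cls[cls %in% labels]
  if (length(present) < 2) stop("need at least two classes present in labels")
  skipped <- setdiff(cls, present)
  if (length(skipped))
    message("class(es) absent from labels, pairs skipped: ",
            paste(skipped, collapse = ", "))
  pairs <- utils::combn(present, 2)
  aucs <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    a_ij <- .pairAUC(scores[labels == i, i], scores[labels == j, i])
    a_ji <- .pairAUC(scores[labels == j, j], scores[labels == i, j])
    (a_ij + a_ji) / 2
  })
  mean(aucs)
}

#' Multi-class Brier score
#'
#' Mean over samples of the squared distance between the score vector and
#' the one-hot truth: \code{mean_i sum_k (p_ik - y_ik)^2}; ranges over
#' [0, 2].
#'
#' @param scores samples x classes row-stochastic score matrix.
#' @param labels true class per sample.
#' @return scalar Brier score.
#' @export
brierScore <- function(scores, labels) {
  Y <- matrix(0, nrow(scores), ncol(scores))
  Y[cbind(seq_len(nrow(scores)),
          match(as.character(labels), colnames(scores)))] <- 1
  mean(rowSums((scores - Y)^2))
}

# family-level argmax error: families score by their sum, singleton classes
# by themselves; a prediction is correct if it names the true class or the
# true class's family
.familyError <- function(calibrated, labels, mcf) {
  members <- unlist(mcf, use.names = FALSE)
  singles <- setdiff(colnames(calibrated), members)
  fam_scores <- cbind(aggregateMCF(calibrated, mcf),
                      calibrated[, singles, drop = FALSE])
  toFamily <- function(cl) {
    hit <- vapply(mcf, function(m) cl %in% m, logical(1))
    if (any(hit)) names(mcf)[which(hit)[1]] else cl
  }
  truth_fam <- vapply(as.character(labels), toFamily, character(1))
  pred_fam <- colnames(fam_scores)[apply(fam_scores, 1, which.max)]
  mean(pred_fam != truth_fam)
}

#' Nested cross-validation of the full classifier
#'
#' Outer stratified k-fold cross-validation of the Random-Forest
#' classifier with, inside every outer training set, an inner k-fold
#' loop generating independent out-of-fold raw scores on which the
#' calibration model is fitted (optionally after Youden-index lambda
#' tuning). Each outer test fold is scored by its fold's forest and
#' calibrated by its fold's calibration model; metrics are computed on
#' the pooled outer-test predictions.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment.
#' @param labels class label per sample.
#' @param forestCfg a \code{\link{forestConfig}}.
#' @param outerFolds,innerFolds fold counts (default 3/3).
#' @param lambdaGrid candidate calibration penalties; a single value skips
#'   tuning.
#' @param tuneReps resampling repetitions for \code{\link{tuneLambda}}.
#' @param cutoff reporting threshold used for tuning and the classifiable
#'   fraction.
#' @param mcf optional methylation-class-family configuration (named list)
#'   for the family-level error.
#' @param seed RNG seed.
#' @return list of class \code{"CVReport"}: per-sample table
#'   (\code{samples}), \code{raw_error}, \code{calibrated_error},
#'   \code{family_error} (NA without \code{mcf}), \code{auc},
#'   \code{brier}, \code{confusion}, \code{classifiable_fraction},
#'   \code{lambda} per outer fold, and the fold assignment.
#' @export
nestedCV <- function(beta, labels, forestCfg = forestConfig(),
                     outerFolds = 3, innerFolds = 3,
                     lambdaGrid = 10 ^ seq(-4, 1, length.out = 8),
                     tuneReps = 30, cutoff = 0.9, mcf = NULL, seed = 1) {
  b <- .betaMatrix(beta)
  y <- factor(labels)
  n <- ncol(b)
  folds <- .stratifiedFolds(y, outerFolds, seed)
  raw <- matrix(NA_real_, n, nlevels(y),
                dimnames = list(colnames(b), levels(y)))
  calibrated <- raw
  lambdas <- numeric(outerFolds)
  train_ids <- vector("list", outerFolds)
  for (f in seq_len(outerFolds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    train_ids[[f]] <- colnames(b)[train]
    cfg <- forestCfg
    cfg$seed <- forestCfg$seed + 100 * f

    ranked <- rankProbesByImportance(b[, train, drop = FALSE], y[train], cfg)
    sel <- ranked[seq_len(min(cfg$nSelectedCpGs, length(ranked)))]
    model <- trainForest(b[, train, drop = FALSE], y[train], sel, cfg)

    inner <- oofRawScores(b[, train, drop = FALSE], y[train], cfg,
                          nFolds = innerFolds, seed = seed + f)
    lam <- if (length(lambdaGrid) > 1)
      as.numeric(tuneLambda(inner, y[train], lambdaGrid = lambdaGrid,
                            nReps = tuneReps, cutoff = cutoff,
                            seed = seed + 1000 * f))
    else lambdaGrid
    lambdas[f] <- lam
    calib <- fitCalibration(inner, y[train], lam)

    raw[test, ] <- rawScores(model, b[, test, drop = FALSE])
    calibrated[test, ] <- calibrateScores(calib, raw[test, , drop = FALSE])
  }
  per_sample <- data.frame(
    sample_id = colnames(b), true = as.character(y), fold = folds,
    raw_argmax = colnames(raw)[apply(raw, 1, which.max)],
    calibrated_argmax = colnames(calibrated)[apply(calibrated, 1, which.max)],
    max_raw = apply(raw, 1, max),
    max_calibrated = apply(calibrated, 1, max),
    stringsAsFactors = FALSE)
  structure(list(
    samples = per_sample,
    raw_scores = raw, calibrated_scores = calibrated,
    raw_error = misclassificationRate(raw, y),
    calibrated_error = misclassificationRate(calibrated, y),
    family_error = if (is.null(mcf)) NA_real_
      else .familyError(calibrated, y, mcf),
    auc = multiclassAUC(calibrated, y),
    brier = brierScore(calibrated, y),
    confusion = confusionMatrix(calibrated, y),
    classifiable_fraction = mean(apply(calibrated, 1, max) >= cutoff),
    lambda = lambdas, fold = folds, train_ids = train_ids),
    class = "CVReport")
}

#' @export
print.CVReport <- function(x, ...) {
  cat("CVReport on", nrow(x$samples), "samples,",
      ncol(x$raw_scores), "classes\n")
  cat(sprintf("  raw error:        %.2f%%\n", 100 * x$raw_error))
  cat(sprintf("  calibrated error: %.2f%%\n", 100 * x$calibrated_error))
  if (!is.na(x$family_error))
    cat(sprintf("  family error:     %.2f%%\n", 100 * x$family_error))
  cat(sprintf("  multi-class AUC:  %.3f\n", x$auc))
  cat(sprintf("  Brier score:      %.3f\n", x$brier))
  cat(sprintf("  classifiable at 0.9: %.0f%%\n",
              100 * x$classifiable_fraction))
  invisible(x)
}
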