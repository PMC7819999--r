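#' Out-of-fold Random-Forest raw scores
#'
#' Class-stratified k-fold cross-validation producing, for every sample,
#' vote-fraction scores from a forest that never saw it. Probe selection
#' by importance is re-run inside each training fold, so no information
#' leaks from the held-out samples.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment.
#' @param labels class label per sample.
#' @param config a \code{\link{forestConfig}}.
#' @param nFolds number of folds (default 3).
#' @param seed RNG seed controlling the fold split.
#' @return samples x classes matrix of raw scores aligned to the input
#'   sample order, with the fold assignment in \code{attr(, "fold")}.
#' @export
oofRawScores <- function(beta, labels, config = forestConfig(), nFolds = 3,
                         seed = 1) {
  b <- .betaMatrix(beta)
  y <- factor(labels)
  # nFolds equal to the sample count is leave-one-out, which cannot be
  # class-stratified: each sample is its own fold
  folds <- if (nFolds == length(y)) seq_along(y)
  else .stratifiedFolds(y, nFolds, seed)
  classes <- levels(y)
  scores <- matrix(NA_real_, ncol(b), length(classes),
                   dimnames = list(colnames(b), classes))
  for (f in seq_len(nFolds)) {
    test <- which(folds == f)
    train <- which(folds != f)
    cfg <- config
    cfg$seed <- config$seed + f
    ranked <- rankProbesByImportance(b[, train, drop = FALSE], y[train], cfg)
    sel <- ranked[seq_len(min(cfg$nSelectedCpGs, length(ranked)))]
    model <- trainForest(b[, train, drop = FALSE], y[train], sel, cfg)
    scores[test, ] <- rawScores(model, b[, test, drop = FALSE])
  }
  attr(scores, "fold") <- folds
  scores
}

.stratifiedFolds <- function(y, nFolds, seed) {
  tab <- table(y)
  if (any(tab < nFolds))
    stop("class(es) smaller than the number of folds: ",
         paste(names(tab)[tab < nFolds], collapse = ", "))
  set.seed(seed)
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep(seq_len(nFolds), length.out = length(idx))
  }
  folds
}

# ---- penalized multinomial logistic regression ------------------------------

.softmax <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

# negative penalized log-likelihood and gradient; W is K x (K+1), first
# column intercepts (unpenalized), symmetric softmax parameterization
.calObjective <- function(W, X, Y, lambda) {
  P <- .softmax(X %*% t(W))
  f <- -sum(log(pmax(P[Y], 1e-300))) +
    lambda / 2 * sum(W[, -1, drop = FALSE]^2)
  Ymat <- matrix(0, nrow(X), nrow(W)); Ymat[Y] <- 1
  G <- t(P - Ymat) %*% X
  G[, -1] <- G[, -1] + lambda * W[, -1, drop = FALSE]
  list(f = f, G = G, P = P)
}

.calHessian <- function(W, X, P, lambda) {
  K <- nrow(W); d <- ncol(X)
  H <- matrix(0, K * d, K * d)
  for (k in seq_len(K)) for (l in seq_len(K)) {
    w <- P[, k] * ((k == l) - P[, l])
    blk <- crossprod(X, X * w)
    rows <- (k - 1) * d + seq_len(d)
    cols <- (l - 1) * d + seq_len(d)
    H[rows, cols] <- blk
  }
  pen <- rep(c(0, rep(lambda, d - 1)), K)
  H + diag(pen)
}

#' Fit the calibration model
#'
#' L2-penalized multinomial logistic regression taking the methylation
#' class as response and the Random-Forest raw scores as explanatory
#' variables: maximizes the multinomial log-likelihood minus
#' \code{lambda/2} times the squared norm of the non-intercept weights.
#' The ridge penalty stabilizes estimation when classes are perfectly
#' separable. Fitting must use independent (out-of-fold) scores --
#' see \code{\link{oofRawScores}}. Optimized by BFGS with Newton
#' polishing; errors out if the gradient norm at the reported optimum
#' exceeds 1e-6.
#'
#' @param oofScores samples x classes matrix of out-of-fold raw scores.
#' @param labels true class per sample.
#' @param lambda L2 penalty strength (>= 0).
#' @return a \linkS4class{CalibrationModel}.
#' @export
fitCalibration <- function(oofScores, labels, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  y <- factor(labels, levels = colnames(oofScores))
  if (any(is.na(y))) stop("labels contain classes absent from the score columns")
  K <- ncol(oofScores)
  if (K < 2) stop("need at least two classes")
  X <- cbind(1, unname(as.matrix(oofScores)))
  Yidx <- cbind(seq_along(y), as.integer(y))
  d <- ncol(X)

  fn <- function(par) .calObjective(matrix(par, K, d, byrow = TRUE),
                                    X, Yidx, lambda)$f
  gr <- function(par) as.vector(t(.calObjective(matrix(par, K, d, byrow = TRUE),
                                                X, Yidx, lambda)$G))
  opt <- stats::optim(rep(0, K * d), fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  W <- matrix(opt$par, K, d, byrow = TRUE)
  for (it in seq_len(100)) {
    ob <- .calObjective(W, X, Yidx, lambda)
    gnorm <- sqrt(sum(ob$G^2))
    if (gnorm < 1e-8) break
    H <- .calHessian(W, X, ob$P, lambda)
    # the common intercept shift is a null direction of H (probabilities
    # and penalty are invariant); regularize relative to H's scale
    eps <- 1e-8 * (max(diag(H)) + 1)
    step <- tryCatch(solve(H + diag(eps, nrow(H)), as.vector(t(ob$G))),
                     error = function(e) NULL)
    if (is.null(step)) break
    stepm <- matrix(step, K, d, byrow = TRUE)
    # accept any step that does not increase f beyond rounding noise: near
    # the optimum the true decrease of a full Newton step can sit below
    # double-precision resolution of f
    ftol <- 1e-9 * (1 + abs(ob$f))
    t_ <- 1
    repeat {
      W2 <- W - t_ * stepm
      f2 <- .calObjective(W2, X, Yidx, lambda)$f
      if (f2 <= ob$f + ftol || t_ < 1e-8) break
      t_ <- t_ / 2
    }
    if (f2 > ob$f + ftol) break
    W <- W2
  }
  ob <- .calObjective(W, X, Yidx, lambda)
  gnorm <- sqrt(sum(ob$G^2))
  if (gnorm >= 1e-6)
    stop("calibration fit did not converge: gradient norm ",
         format(gnorm, digits = 4), ", objective ", format(ob$f, digits = 8),
         ", lambda ", lambda)
  # centre intercepts: probabilities are invariant to a common shift
  W[, 1] <- W[, 1] - mean(W[, 1])
  dimnames(W) <- list(colnames(oofScores),
                      c("(Intercept)", colnames(oofScores)))
  new("CalibrationModel", coefficients = W, lambda = lambda,
      classLabels = colnames(oofScores),
      convergence = list(grad_norm = gnorm, objective = ob$f))
}

#' Calibrated class probabilities
#'
#' Applies the fitted multinomial map: softmax of the linear transform of
#' the raw scores. Rows sum to 1.
#'
#' @param model a \linkS4class{CalibrationModel}.
#' @param raw samples x classes matrix of raw scores with the model's
#'   class columns.
#' @return samples x classes matrix of calibrated probabilities.
#' @export
calibrateScores <- function(model, raw) {
  if (!identical(colnames(raw), model@classLabels))
    stop("raw score columns do not match the calibration model classes")
  X <- cbind(1, unname(as.matrix(raw)))
  P <- .softmax(X %*% t(model@coefficients))
  dimnames(P) <- dimnames(raw)
  P
}

#' Youden index of the classifiable rule at a score threshold
#'
#' Sensitivity + specificity - 1 of the binary rule "classifiable iff the
#' maximum calibrated score reaches the cutoff", evaluated against the
#' correctness of the argmax prediction (correct = the positive class).
#' A vacuous group contributes perfectly (no incorrect samples gives
#' specificity 1, no correct samples sensitivity 1).
#'
#' @param maxScore per-sample maximum calibrated score.
#' @param correct logical: argmax prediction agrees with the true class.
#' @param cutoff score threshold.
#' @return the Youden index, in [-1, 1].
#' @export
youdenIndex <- function(maxScore, correct, cutoff = 0.9) {
  pos <- correct; neg <- !correct
  sens <- if (any(pos)) mean(maxScore[pos] >= cutoff) else 1
  spec <- if (any(neg)) mean(maxScore[neg] < cutoff) else 1
  sens + spec - 1
}

#' Tune the calibration penalty by resampled Youden index
#'
#' Repeatedly splits the out-of-fold scores into a 70\% training and 30\%
#' evaluation part (stratified by class so every repetition retains all
#' classes), fits a calibration model per candidate lambda on the training
#' part, calibrates the held-out part, and labels each held-out sample
#' "classifiable" when its calibrated argmax agrees with the true class.
#' The Youden index (sensitivity + specificity - 1) of the decision rule
#' "maximum calibrated score >= cutoff" is averaged over repetitions, and
#' the lambda maximizing the average at the prespecified cutoff of 0.9 is
#' returned (ties go to the smallest lambda).
#'
#' @param oofScores samples x classes matrix of out-of-fold raw scores.
#' @param labels true class per sample.
#' @param lambdaGrid candidate penalties; default 50 values log-spaced
#'   between 1e-4 and 10.
#' @param nReps resampling repetitions.
#' @param trainFrac training fraction per repetition.
#' @param cutoff prespecified reporting threshold.
#' @param seed RNG seed; repetition r draws with seed \code{seed + r}.
#' @return the selected lambda, with the per-lambda mean Youden indices in
#'   \code{attr(, "youden")}.
#' @export
tuneLambda <- function(oofScores, labels,
                       lambdaGrid = 10 ^ seq(-4, 1, length.out = 50),
                       nReps = 500, trainFrac = 0.7, cutoff = 0.9,
                       seed = 1) {
  if (length(lambdaGrid) == 0) stop("lambdaGrid is empty")
  if (nReps < 1) stop("nReps must be at least 1")
  y <- factor(labels, levels = colnames(oofScores))
  youden <- matrix(NA_real_, nReps, length(lambdaGrid))
  for (r in seq_len(nReps)) {
    set.seed(seed + r)
    train <- unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      m <- min(length(idx) - 1, max(1, floor(trainFrac * length(idx))))
      sample(idx, m)
    }))
    test <- setdiff(seq_along(y), train)
    for (j in seq_along(lambdaGrid)) {
      fit <- fitCalibration(oofScores[train, , drop = FALSE], y[train],
                            lambdaGrid[j])
      cal <- calibrateScores(fit, oofScores[test, , drop = FALSE])
      mx <- apply(cal, 1, max)
      pred <- colnames(cal)[apply(cal, 1, which.max)]
      correct <- pred == as.character(y[test])
      youden[r, j] <- youdenIndex(mx, correct, cutoff)
    }
  }
  avg <- colMeans(youden)
  best <- lambdaGrid[which.max(avg)]
  attr(best, "youden") <- stats::setNames(avg, format(lambdaGrid))
  best
}

#' Aggregate calibrated scores into methylation class families
#'
#' The calibrated score of a methylation class family (MCF) is the exact
#' sum of the calibrated scores of its member classes. Families must be
#' disjoint and reference only known classes.
#'
#' @param calibrated samples x classes matrix of calibrated scores.
#' @param mcf named list mapping family name to member class labels.
#' @return samples x families matrix of family scores.
#' @export
aggregateMCF <- function(calibrated, mcf) {
  members <- unlist(mcf, use.names = FALSE)
  unknown <- setdiff(members, colnames(calibrated))
  if (length(unknown))
    stop("MCF members not among the classes: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(members))
    stop("overlapping families: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  out <- vapply(mcf, function(m)
    rowSums(calibrated[, m, drop = FALSE]), numeric(nrow(calibrated)))
  out <- matrix(out, nrow = nrow(calibrated),
                dimnames = list(rownames(calibrated), names(mcf)))
  out
}

#' Thresholded class predictions
#'
#' For each sample reports the argmax calibrated class (float ties broken
#' lexicographically), the best-scoring family (when an MCF configuration
#' is supplied), and the classifiable flag: a sample is classifiable iff
#' the maximum of its best class score and best family score reaches the
#' cutoff. Non-classifiable samples still report their argmax.
#'
#' @param calibrated samples x classes matrix of calibrated scores.
#' @param mcfScores optional samples x families matrix from
#'   \code{\link{aggregateMCF}}.
#' @param cutoff reporting threshold (default 0.9).
#' @return data.frame: \code{sample_id}, \code{best_class},
#'   \code{best_score}, \code{best_family}, \code{family_score},
#'   \code{classifiable}.
#' @export
predictWithThreshold <- function(calibrated, mcfScores = NULL, cutoff = 0.9) {
  cls <- colnames(calibrated)
  ord_cls <- order(cls)  # lexicographic tie-break
  best_idx <- apply(calibrated[, ord_cls, drop = FALSE], 1, which.max)
  best_class <- cls[ord_cls][best_idx]
  best_score <- calibrated[cbind(seq_len(nrow(calibrated)),
                                 match(best_class, cls))]
  if (!is.null(mcfScores)) {
    fam <- colnames(mcfScores)
    fam_idx <- apply(mcfScores[, order(fam), drop = FALSE], 1, which.max)
    best_family <- fam[order(fam)][fam_idx]
    family_score <- mcfScores[cbind(seq_len(nrow(mcfScores)),
                                    match(best_family, fam))]
  } else {
    best_family <- rep(NA_character_, nrow(calibrated))
    family_score <- rep(NA_real_, nrow(calibrated))
  }
  classifiable <- pmax(best_score, family_score, na.rm = TRUE) >= cutoff
  ids <- rownames(calibrated)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(calibrated)))
  data.frame(sample_id = ids, best_class = best_class,
             best_score = best_score, best_family = best_family,
             family_score = family_score, classifiable = classifiable,
             stringsAsFactors = FALSE, row.names = NULL)
}
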