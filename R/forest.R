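#' Random-Forest configuration
#'
#' @param nTrees trees in the main forest.
#' @param nSelectedCpGs CpGs retained after importance ranking (capped at
#'   the number of available probes).
#' @param downsample balance classes by drawing, per tree, an equal number
#'   of samples from every class (the smallest class count) without
#'   replacement.
#' @param mtry variables tried per split; default \code{floor(sqrt(p))}.
#' @param importance \code{"gini"} (mean decrease in node impurity) or
#'   \code{"permutation"}.
#' @param seed RNG seed.
#' @return list of class \code{"ForestConfig"}.
#' @export
forestConfig <- function(nTrees = 10000, nSelectedCpGs = 10000,
                         downsample = TRUE, mtry = NULL,
                         importance = c("gini", "permutation"), seed = 1) {
  importance <- match.arg(importance)
  if (nTrees < 1) stop("nTrees must be at least 1")
  structure(list(nTrees = nTrees, nSelectedCpGs = nSelectedCpGs,
                 downsample = downsample, mtry = mtry,
                 importance = importance, seed = seed),
            class = "ForestConfig")
}

.balancedSampsize <- function(labels, downsample) {
  tab <- table(labels)
  if (downsample) rep(min(tab), length(tab)) else as.integer(tab)
}

.fitRF <- function(x, y, config, ntree, want_importance = FALSE) {
  tab <- table(y)
  if (any(tab < 2))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  # randomForest's stratified no-replacement sampler loops forever when no
  # feature admits a split at all
  if (all(matrixStats::colVars(x) == 0))
    stop("all features are constant: no split is possible")
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    strata = y, sampsize = .balancedSampsize(y, config$downsample),
    replace = FALSE,
    importance = want_importance && config$importance == "permutation",
    keep.inbag = TRUE)
}

#' Rank CpGs by Random-Forest variable importance
#'
#' Fits a preliminary forest (one tenth of the configured tree count, same
#' class-balanced downsampling) on all probes and ranks them by the
#' configured importance measure, descending; ties are broken by probe id.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment.
#' @param labels class label per sample (>= 2 classes, >= 2 samples each).
#' @param config a \code{\link{forestConfig}}.
#' @return character vector of all probe ids in importance order.
#' @export
rankProbesByImportance <- function(beta, labels, config = forestConfig()) {
  b <- .betaMatrix(beta)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two classes")
  ids <- rownames(b)
  # degenerate case: every probe constant -> importance 0 for all, and the
  # lexicographic tie rule decides the whole ranking
  if (all(matrixStats::rowVars(b) == 0)) return(ids[order(ids)])
  set.seed(config$seed)
  ntree <- max(50, ceiling(config$nTrees / 10))
  rf <- .fitRF(t(b), y, config, ntree, want_importance = TRUE)
  imp <- if (config$importance == "permutation")
    rf$importance[, "MeanDecreaseAccuracy"]
  else
    rf$importance[, "MeanDecreaseGini"]
  ids <- rownames(b)
  ids[order(-imp, ids)]
}

#' Train the class-balanced Random-Forest classifier
#'
#' Grows \code{nTrees} binary decision trees on the selected CpGs; with
#' downsampling each tree is trained on a stratified draw of size equal to
#' the smallest class count from every class, without replacement, which
#' removes the prior bias toward large classes.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment.
#' @param labels class label per sample.
#' @param selected probe ids to train on (e.g. the head of
#'   \code{\link{rankProbesByImportance}}); defaults to the top
#'   \code{nSelectedCpGs} by importance.
#' @param config a \code{\link{forestConfig}}.
#' @return a \linkS4class{SarcomaClassifier}.
#' @export
trainForest <- function(beta, labels, selected = NULL,
                        config = forestConfig()) {
  b <- .betaMatrix(beta)
  y <- factor(labels)
  if (is.null(selected)) {
    ranked <- rankProbesByImportance(b, y, config)
    selected <- ranked[seq_len(min(config$nSelectedCpGs, length(ranked)))]
  }
  missing_probes <- setdiff(selected, rownames(b))
  if (length(missing_probes))
    stop("selected probes absent from beta matrix: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  set.seed(config$seed + 1L)
  rf <- .fitRF(t(b[selected, , drop = FALSE]), y, config, config$nTrees)
  fp <- sprintf("n=%d|p=%d|trees=%d|classes=%s|sum=%.6e",
                ncol(b), length(selected), config$nTrees,
                paste(levels(y), collapse = ","),
                sum(b[selected, , drop = FALSE]))
  new("SarcomaClassifier", selectedProbes = selected, forest = rf,
      classLabels = levels(y), config = unclass(config),
      fingerprint = fp)
}

#' Raw vote-fraction scores
#'
#' For each sample, the fraction of trees voting for each class; every row
#' sums to 1.
#'
#' @param model a \linkS4class{SarcomaClassifier}.
#' @param beta beta matrix (probes x samples) or SummarizedExperiment
#'   containing the model's selected probes.
#' @return samples x classes matrix of vote fractions.
#' @export
rawScores <- function(model, beta) {
  b <- .betaMatrix(beta)
  missing_probes <- setdiff(model@selectedProbes, rownames(b))
  if (length(missing_probes))
    stop("beta matrix lacks model probes: ",
         paste(utils::head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) sprintf(" (and %d more)",
                                                 length(missing_probes) - 5))
  x <- t(b[model@selectedProbes, , drop = FALSE])
  votes <- stats::predict(model@forest, newdata = x, type = "vote",
                          norm.votes = TRUE)
  votes <- votes[, model@classLabels, drop = FALSE]
  rownames(votes) <- colnames(b)
  stopifnot(max(abs(rowSums(votes) - 1)) < 1e-9)
  votes
}
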