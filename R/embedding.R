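#' Select the most variable probes
#'
#' Ranks probes by standard deviation (denominator n-1) or median absolute
#' deviation (scale factor 1.4826) across samples, descending; ties are
#' broken by probe id lexicographically for determinism.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment with
#'   a \code{"beta"} assay.
#' @param k number of probes to return.
#' @param statistic \code{"sd"} or \code{"mad"}.
#' @return character vector of exactly \code{k} probe ids.
#' @export
selectTopVariable <- function(beta, k, statistic = c("sd", "mad")) {
  statistic <- match.arg(statistic)
  b <- .betaMatrix(beta)
  if (k > nrow(b)) stop("k (", k, ") exceeds the number of probes (", nrow(b), ")")
  s <- switch(statistic,
              sd = matrixStats::rowSds(b),
              mad = matrixStats::rowMads(b))
  ids <- rownames(b)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(b)))
  ids[order(-s, ids)][seq_len(k)]
}

#' t-SNE embedding of a cohort
#'
#' Selects the \code{nTopSd} most variable probes by standard deviation and
#' embeds the samples in two dimensions with t-SNE (perplexity 30, 3000
#' iterations by default), initialized from the first two principal
#' components so the result is deterministic given the seed.
#'
#' @param beta beta matrix (probes x samples) or SummarizedExperiment.
#' @param nTopSd number of top-variance probes (capped at the probe count).
#' @param perplexity t-SNE perplexity; requires
#'   \code{nSamples >= 3 * perplexity + 2}.
#' @param iterations gradient-descent iterations.
#' @param seed RNG seed.
#' @return samples x 2 coordinate matrix with sample ids as rownames.
#' @export
runTSNE <- function(beta, nTopSd = 10000, perplexity = 30,
                    iterations = 3000, seed = 1) {
  b <- .betaMatrix(beta)
  n <- ncol(b)
  if (n < 3 * perplexity + 2)
    stop("too few samples (", n, ") for perplexity ", perplexity,
         ": need at least 3 * perplexity + 2 = ", 3 * perplexity + 2)
  top <- selectTopVariable(b, min(nTopSd, nrow(b)), "sd")
  x <- t(b[top, , drop = FALSE])
  set.seed(seed)
  pc <- stats::prcomp(x, rank. = 2)$x
  init <- pc / max(1e-12, stats::sd(pc[, 1])) * 1e-4
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      max_iter = iterations, Y_init = init,
                      pca = FALSE, check_duplicates = FALSE)
  coords <- fit$Y
  rownames(coords) <- colnames(b)
  colnames(coords) <- c("tsne1", "tsne2")
  coords
}

# majority class among the k nearest neighbours of each embedded sample
.knnPreservation <- function(coords, labels, k = 10) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(coords))
  hits <- vapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[2:(k + 1)]
    tab <- sort(table(labels[nn]), decreasing = TRUE)
    names(tab)[1] == labels[i]
  }, logical(1))
  mean(hits)
}

#' Stability of the t-SNE projection under subsampling
#'
#' Repeats the embedding on random subsamples (without replacement) and
#' reports, per repetition, the fraction of samples whose 10-nearest-
#' neighbour class majority in the embedding matches their own class -- a
#' concrete neighbourhood-preservation readout of projection stability.
#'
#' @param beta beta matrix or SummarizedExperiment.
#' @param labels class label per sample.
#' @param nReps number of subsampling repetitions.
#' @param subsampleFraction fraction of samples per repetition.
#' @param nTopSd,perplexity,iterations passed to \code{\link{runTSNE}}.
#' @param knn neighbourhood size of the readout.
#' @param seed RNG seed; repetition r subsamples with seed \code{seed + r}
#'   and embeds with \code{seed}, so \code{subsampleFraction = 1} makes
#'   every repetition identical to the full embedding.
#' @return numeric vector of per-repetition preservation scores.
#' @export
stabilityResample <- function(beta, labels, nReps = 500,
                              subsampleFraction = 0.9, nTopSd = 10000,
                              perplexity = 30, iterations = 3000,
                              knn = 10, seed = 1) {
  b <- .betaMatrix(beta)
  n <- ncol(b)
  m <- floor(subsampleFraction * n)
  vapply(seq_len(nReps), function(r) {
    set.seed(seed + r)
    idx <- sort(sample.int(n, m))
    coords <- runTSNE(b[, idx, drop = FALSE], nTopSd = nTopSd,
                      perplexity = perplexity, iterations = iterations,
                      seed = seed)
    .knnPreservation(coords, labels[idx], k = knn)
  }, numeric(1))
}

#' Hierarchical clustering of a cohort
#'
#' Agglomerative clustering with Ward's linkage on Euclidean distances
#' over the most variable probes by median absolute deviation, cut into
#' \code{kCut} clusters.
#'
#' @param beta beta matrix or SummarizedExperiment.
#' @param kCut number of clusters to cut the tree into.
#' @param nTopMad number of top-MAD probes (capped at the probe count).
#' @return integer cluster labels named by sample id; the fitted
#'   \code{hclust} tree is attached as \code{attr(, "tree")}.
#' @export
hierarchicalCluster <- function(beta, kCut, nTopMad = 20000) {
  b <- .betaMatrix(beta)
  if (kCut > ncol(b)) stop("kCut exceeds the number of samples")
  top <- selectTopVariable(b, min(nTopMad, nrow(b)), "mad")
  tree <- stats::hclust(stats::dist(t(b[top, , drop = FALSE])),
                        method = "ward.D2")
  labels <- stats::cutree(tree, k = kCut)
  attr(labels, "tree") <- tree
  labels
}
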