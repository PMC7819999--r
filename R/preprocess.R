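#' Background correction against negative control probes
#'
#' Per sample and colour channel, shifts intensities so that the 5th
#' percentile of the negative-control probes becomes exactly 0: that
#' percentile (linear interpolation between order statistics) is
#' subtracted from every measurement and control intensity of the channel.
#' The methylated signal lives in the green channel, the unmethylated
#' signal in the red channel.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @return the corrected cohort; per-sample shifts are appended to
#'   \code{metadata()$audit$background_shift}.
#' @export
backgroundCorrect <- function(cohort) {
  ctl <- cohort@controls
  neg <- ctl$info$control_type == "negative"
  if (!any(neg)) stop("no negative control probes: cannot background-correct ",
                      "either channel (grn, red)")
  a <- SummarizedExperiment::assays(cohort)
  shift_grn <- apply(ctl$grn[neg, , drop = FALSE], 2, stats::quantile,
                     probs = 0.05, names = FALSE)
  shift_red <- apply(ctl$red[neg, , drop = FALSE], 2, stats::quantile,
                     probs = 0.05, names = FALSE)
  a$meth <- sweep(a$meth, 2, shift_grn, "-")
  a$unmeth <- sweep(a$unmeth, 2, shift_red, "-")
  ctl$grn <- sweep(ctl$grn, 2, shift_grn, "-")
  ctl$red <- sweep(ctl$red, 2, shift_red, "-")
  SummarizedExperiment::assays(cohort) <- a
  cohort@controls <- ctl
  md <- S4Vectors::metadata(cohort)
  md$audit$background_shift <- data.frame(sample_id = colnames(cohort),
                                          grn = shift_grn, red = shift_red)
  S4Vectors::metadata(cohort) <- md
  cohort
}

#' Dye-bias correction against normalization control probes
#'
#' Per sample and colour channel, rescales all intensities so that the
#' mean of the normalization-control probes equals 10,000.
#' \code{\link{backgroundCorrect}} must be applied first.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @return the corrected cohort; per-sample scale factors are appended to
#'   \code{metadata()$audit$dye_scale}.
#' @export
dyeBiasCorrect <- function(cohort) {
  ctl <- cohort@controls
  norm <- ctl$info$control_type == "normalization"
  if (!any(norm)) stop("no normalization control probes")
  mean_grn <- colMeans(ctl$grn[norm, , drop = FALSE])
  mean_red <- colMeans(ctl$red[norm, , drop = FALSE])
  if (any(mean_grn <= 0) || any(mean_red <= 0))
    stop("non-positive normalization-control mean; was backgroundCorrect ",
         "applied to an already-clean channel?")
  scale_grn <- 10000 / mean_grn
  scale_red <- 10000 / mean_red
  a <- SummarizedExperiment::assays(cohort)
  a$meth <- sweep(a$meth, 2, scale_grn, "*")
  a$unmeth <- sweep(a$unmeth, 2, scale_red, "*")
  ctl$grn <- sweep(ctl$grn, 2, scale_grn, "*")
  ctl$red <- sweep(ctl$red, 2, scale_red, "*")
  SummarizedExperiment::assays(cohort) <- a
  cohort@controls <- ctl
  md <- S4Vectors::metadata(cohort)
  md$audit$dye_scale <- data.frame(sample_id = colnames(cohort),
                                   grn = scale_grn, red = scale_red)
  S4Vectors::metadata(cohort) <- md
  cohort
}

#' Remove material/array batch effects from log2 intensities
#'
#' Fits, per probe, a linear model of the log2 intensities on the material
#' (FFPE/frozen) and array (450k/EPIC) factors and removes the fitted
#' factor effects while retaining the intercept (grand-mean) structure.
#' This is the classical batch-removal linear model
#' (\code{limma::removeBatchEffect}); a factor with a single level is
#' skipped with a message.
#'
#' @param log2mat probes x samples matrix of log2 intensities.
#' @param material factor/character of tissue material per sample.
#' @param arrayType factor/character of array platform per sample.
#' @return the adjusted matrix.
#' @export
batchAdjust <- function(log2mat, material, arrayType) {
  material <- factor(material)
  arrayType <- factor(arrayType)
  use_mat <- nlevels(material) > 1
  use_arr <- nlevels(arrayType) > 1
  if (!use_mat) message("material has a single level; skipped")
  if (!use_arr) message("arrayType has a single level; skipped")
  if (!use_mat && !use_arr) return(log2mat)
  if (use_mat && use_arr)
    limma::removeBatchEffect(log2mat, batch = material, batch2 = arrayType)
  else if (use_mat)
    limma::removeBatchEffect(log2mat, batch = material)
  else
    limma::removeBatchEffect(log2mat, batch = arrayType)
}

#' Beta values from channel intensities
#'
#' \code{beta = M / (M + U + offset)} with the Illumina-recommended offset
#' of 100. Negative intensities (possible after background subtraction)
#' are clipped to 0 first, so the result always lies in [0, 1).
#'
#' @param M,U methylated/unmethylated intensities (vectors or matrices of
#'   equal shape).
#' @param offset stabilizing offset added to the denominator.
#' @return beta values with the shape of \code{M}.
#' @export
computeBeta <- function(M, U, offset = 100) {
  stopifnot(identical(dim(M), dim(U)), all(is.finite(M)), all(is.finite(U)))
  M <- pmax(M, 0)
  U <- pmax(U, 0)
  M / (M + U + offset)
}

#' Full preprocessing chain for a cohort
#'
#' Applies, in order: restriction to probes present on both the 450k and
#' EPIC arrays (platform harmonization), per-sample background correction,
#' per-sample dye-bias correction, log2 transform (flooring at 1),
#' material/array batch adjustment of the methylated and unmethylated
#' signals individually, retransformation, and beta-value computation with
#' an offset of 100. The order matters and is asserted by the pipeline:
#' dye-bias scaling is only meaningful after the background shift.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @param offset beta-value offset.
#' @return a \linkS4class{SummarizedExperiment} with assay \code{"beta"}
#'   (probes x samples, all values in [0, 1)), the harmonized probe
#'   annotation in \code{rowData}, the sample sheet in \code{colData}, and
#'   a normalization audit (background shifts, dye scales, batch levels)
#'   in \code{metadata()$audit}.
#' @export
preprocessCohort <- function(cohort, offset = 100) {
  keep <- SummarizedExperiment::rowData(cohort)$on_450k &
    SummarizedExperiment::rowData(cohort)$on_epic
  cohort <- cohort[keep, ]
  cohort <- backgroundCorrect(cohort)
  cohort <- dyeBiasCorrect(cohort)

  ss <- sampleSheet(cohort)
  adjust <- function(x) {
    lg <- log2(pmax(x, 1))
    adj <- batchAdjust(lg, ss$material, ss$array_type)
    2 ^ adj
  }
  M <- adjust(methylated(cohort))
  U <- adjust(unmethylated(cohort))
  beta <- computeBeta(M, U, offset = offset)

  audit <- S4Vectors::metadata(cohort)$audit
  audit$batch_levels <- list(material = levels(factor(ss$material)),
                             array_type = levels(factor(ss$array_type)))
  audit$offset <- offset
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    rowData = SummarizedExperiment::rowData(cohort),
    colData = SummarizedExperiment::colData(cohort))
  S4Vectors::metadata(se) <- c(S4Vectors::metadata(cohort)["informative"],
                               list(audit = audit))
  se
}

# Accepts a beta SummarizedExperiment or plain matrix; returns the matrix.
.betaMatrix <- function(beta) {
  if (is(beta, "SummarizedExperiment"))
    SummarizedExperiment::assay(beta, "beta")
  else as.matrix(beta)
}
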