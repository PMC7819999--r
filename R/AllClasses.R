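#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

#' Two-channel methylation array cohort
#'
#' A \linkS4class{SummarizedExperiment} holding per-probe methylated
#' (\code{"meth"}) and unmethylated (\code{"unmeth"}) channel intensities
#' (probes x samples), probe annotation in \code{rowData}, the sample sheet
#' in \code{colData}, and control-probe intensity blocks in the
#' \code{controls} slot. The methylated signal is read in the green channel
#' and the unmethylated signal in the red channel; control probes carry an
#' intensity in both channels.
#'
#' The \code{controls} slot is a list with elements \code{info} (a
#' data.frame with columns \code{probe_id}, \code{control_type},
#' \code{channel}) and \code{grn}/\code{red} (control probes x samples
#' intensity matrices).
#'
#' @slot controls list of control-probe annotation and intensities.
#' @export
setClass("MethylCohort",
         contains = "SummarizedExperiment",
         representation(controls = "list"))

setValidity("MethylCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("meth", "unmeth") %in% an))
    msg <- c(msg, "assays must include 'meth' and 'unmeth'")
  ctl <- object@controls
  if (!all(c("info", "grn", "red") %in% names(ctl)))
    msg <- c(msg, "controls slot must have elements 'info', 'grn', 'red'")
  else {
    if (nrow(ctl$info) != nrow(ctl$grn) || nrow(ctl$info) != nrow(ctl$red))
      msg <- c(msg, "control info and intensity matrices disagree on probe count")
    if (ncol(ctl$grn) != ncol(object) || ncol(ctl$red) != ncol(object))
      msg <- c(msg, "control intensity matrices must have one column per sample")
  }
  if ("meth" %in% an && any(!is.finite(SummarizedExperiment::assay(object, "meth"))))
    msg <- c(msg, "non-finite methylated intensities")
  if ("unmeth" %in% an && any(!is.finite(SummarizedExperiment::assay(object, "unmeth"))))
    msg <- c(msg, "non-finite unmethylated intensities")
  if (length(msg)) msg else TRUE
})

#' Construct a MethylCohort
#'
#' @param meth,unmeth probes x samples intensity matrices (aligned).
#' @param annotation probe annotation data.frame for the measurement probes
#'   (one row per row of \code{meth}).
#' @param sampleSheet sample sheet data.frame (one row per column).
#' @param controls list with \code{info}, \code{grn}, \code{red} as described
#'   in \linkS4class{MethylCohort}.
#' @return a \linkS4class{MethylCohort}.
#' @export
MethylCohort <- function(meth, unmeth, annotation, sampleSheet, controls) {
  stopifnot(identical(dim(meth), dim(unmeth)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(meth = meth, unmeth = unmeth),
    rowData = S4Vectors::DataFrame(annotation),
    colData = S4Vectors::DataFrame(sampleSheet))
  rownames(se) <- annotation$probe_id
  colnames(se) <- sampleSheet$sample_id
  new("MethylCohort", se, controls = controls)
}

#' @describeIn MethylCohort-class methylated-channel intensity matrix.
#' @param object,x a \code{MethylCohort}.
#' @export
methylated <- function(x) SummarizedExperiment::assay(x, "meth")

#' @describeIn MethylCohort-class unmethylated-channel intensity matrix.
#' @export
unmethylated <- function(x) SummarizedExperiment::assay(x, "unmeth")

#' @describeIn MethylCohort-class control-probe block (list of info/grn/red).
#' @export
controlIntensities <- function(x) x@controls

#' @describeIn MethylCohort-class sample sheet as a data.frame.
#' @export
sampleSheet <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @describeIn MethylCohort-class probe annotation (measurement probes plus
#'   control probes) as a data.frame.
#' @export
probeAnnotation <- function(x) {
  meas <- as.data.frame(SummarizedExperiment::rowData(x))
  ctl <- x@controls$info
  ctl_full <- data.frame(probe_id = ctl$probe_id,
                         chromosome = NA_character_, position = NA_integer_,
                         snp_within_5bp = FALSE, maps_uniquely = TRUE,
                         on_450k = TRUE, on_epic = TRUE,
                         control_type = ctl$control_type,
                         channel = ctl$channel,
                         stringsAsFactors = FALSE)
  rbind(meas[, colnames(ctl_full)], ctl_full)
}

#' @describeIn MethylCohort-class subsetting keeps the control-probe
#'   intensity columns aligned with the retained samples.
#' @param i,j,...,drop standard subsetting arguments.
#' @export
setMethod("[", c("MethylCohort", "ANY", "ANY"), function(x, i, j, ..., drop = FALSE) {
  out <- callNextMethod()
  if (!missing(j)) {
    ctl <- out@controls
    ctl$grn <- ctl$grn[, j, drop = FALSE]
    ctl$red <- ctl$red[, j, drop = FALSE]
    out@controls <- ctl
  }
  out
})

setMethod("show", "MethylCohort", function(object) {
  cat("MethylCohort with", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  control probes:", nrow(object@controls$info), "\n")
  cl <- SummarizedExperiment::colData(object)$class_label
  if (!is.null(cl)) {
    tab <- table(cl)
    cat("  classes:", paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
  }
})

#' Class-balanced Random Forest methylation classifier
#'
#' Wraps a fitted \pkg{randomForest} ensemble trained on a selected CpG
#' subset, with each tree grown on a per-class balanced subsample of size
#' equal to the smallest class.
#'
#' @slot selectedProbes ordered character vector of CpG probe ids used.
#' @slot forest the fitted \code{randomForest} object.
#' @slot classLabels ordered class names.
#' @slot config the \code{\link{forestConfig}} used.
#' @slot fingerprint digest of training inputs and configuration.
#' @export
setClass("SarcomaClassifier",
         representation(selectedProbes = "character",
                        forest = "ANY",
                        classLabels = "character",
                        config = "list",
                        fingerprint = "character"))

setValidity("SarcomaClassifier", function(object) {
  if (length(object@classLabels) < 2) "need at least two classes" else TRUE
})

#' @describeIn SarcomaClassifier-class class labels of a fitted model.
#' @param x a fitted model object.
#' @export
classLabels <- function(x) x@classLabels

#' @describeIn SarcomaClassifier-class probe ids the forest was trained on.
#' @export
selectedProbes <- function(x) x@selectedProbes

setMethod("show", "SarcomaClassifier", function(object) {
  cat("SarcomaClassifier:", object@forest$ntree, "trees,",
      length(object@selectedProbes), "CpGs,",
      length(object@classLabels), "classes\n")
})

#' Multinomial logistic calibration model
#'
#' Maps Random-Forest vote fractions to calibrated class probabilities by
#' an L2-penalized multinomial logistic regression (softmax of a linear
#' map; intercepts unpenalized).
#'
#' @slot coefficients K x (K+1) weight matrix; first column intercepts.
#' @slot lambda the L2 penalty strength.
#' @slot classLabels ordered class names.
#' @slot convergence list with gradient norm and objective at the optimum.
#' @export
setClass("CalibrationModel",
         representation(coefficients = "matrix",
                        lambda = "numeric",
                        classLabels = "character",
                        convergence = "list"))

setValidity("CalibrationModel", function(object) {
  if (any(!is.finite(object@coefficients))) "non-finite coefficients" else TRUE
})

setMethod("show", "CalibrationModel", function(object) {
  cat("CalibrationModel:", length(object@classLabels),
      "classes, lambda =", format(object@lambda), "\n")
  cat("  gradient norm at optimum:",
      format(object@convergence$grad_norm, digits = 3), "\n")
})

#' Copy-number profile of one sample
#'
#' Genome-ordered log2 ratios of combined probe intensity (M+U) against a
#' copy-neutral baseline, mode-centred, binned and segmented by a penalized
#' least-squares change-point fit.
#'
#' @slot sampleId sample identifier.
#' @slot probeRatios named per-probe log2 ratios (genome order).
#' @slot probeInfo data.frame with \code{chromosome}, \code{position} per probe.
#' @slot bins data.frame: \code{chromosome}, \code{start}, \code{end}
#'   (half-open, 0-based), \code{mean_ratio}, \code{n_probes}.
#' @slot segments data.frame: \code{chromosome}, \code{start}, \code{end},
#'   \code{mean_ratio}, \code{n_bins}.
#' @slot baselineShift the mode subtracted during baseline correction.
#' @export
setClass("CNVProfile",
         representation(sampleId = "character",
                        probeRatios = "numeric",
                        probeInfo = "data.frame",
                        bins = "data.frame",
                        segments = "data.frame",
                        baselineShift = "numeric"))

#' @describeIn CNVProfile-class genomic bins with mean log2 ratios.
#' @param x a \code{CNVProfile}.
#' @export
cnvBins <- function(x) x@bins

#' @describeIn CNVProfile-class fitted copy-number segments.
#' @export
cnvSegments <- function(x) x@segments

setMethod("show", "CNVProfile", function(object) {
  cat("CNVProfile for", object@sampleId, "-",
      length(object@probeRatios), "probes,",
      nrow(object@bins), "bins,",
      nrow(object@segments), "segments\n")
  cat("  baseline shift:", format(object@baselineShift, digits = 3), "\n")
})
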