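#' Classify samples and assemble classifier reports
#'
#' Runs the full per-sample chain on a cohort of query samples: QC
#' metrics and gate, preprocessing (normalization, batch adjustment,
#' beta values), Random-Forest raw scores, calibration, optional
#' methylation-class-family aggregation, and the 0.9-threshold decision.
#' A report is produced for every sample whether or not it passes QC;
#' the QC verdict is part of the report.
#'
#' @param cohort a \linkS4class{MethylCohort} of query samples.
#' @param model a trained \linkS4class{SarcomaClassifier}.
#' @param calibration a fitted \linkS4class{CalibrationModel}.
#' @param mcf optional named list of methylation class families.
#' @param cutoff reporting threshold.
#' @param referenceMetrics optional QC reference distribution (defaults
#'   to the cohort's own metrics).
#' @return list with \code{predictions} (the
#'   \code{\link{predictWithThreshold}} table) and \code{reports} (one
#'   machine-readable list per sample: metadata, QC verdict, top-5
#'   calibrated scores, family scores, decision, fingerprints).
#' @export
classifySample <- function(cohort, model, calibration, mcf = NULL,
                           cutoff = 0.9, referenceMetrics = NULL) {
  metrics <- qcMetrics(cohort)
  gate <- qcGate(metrics,
                 referenceMetrics = if (is.null(referenceMetrics)) metrics
                 else referenceMetrics)
  beta <- preprocessCohort(cohort)
  raw <- rawScores(model, beta)
  cal <- calibrateScores(calibration, raw)
  fam <- if (!is.null(mcf)) aggregateMCF(cal, mcf) else NULL
  pred <- predictWithThreshold(cal, fam, cutoff = cutoff)

  ss <- sampleSheet(cohort)
  reports <- lapply(seq_len(nrow(pred)), function(i) {
    top5 <- sort(cal[i, ], decreasing = TRUE)[seq_len(min(5, ncol(cal)))]
    list(sample = as.list(ss[i, , drop = FALSE]),
         qc = list(keep = gate$keep[i],
                   reasons = gate$reasons[i],
                   metrics = as.list(metrics[i, -1, drop = FALSE])),
         top_scores = as.list(top5),
         family_scores = if (is.null(fam)) NULL else as.list(fam[i, ]),
         prediction = as.list(pred[i, , drop = FALSE]),
         cutoff = cutoff,
         fingerprints = list(model = model@fingerprint,
                             calibration_lambda = calibration@lambda,
                             package = as.character(utils::packageVersion("sarclass"))))
  })
  names(reports) <- pred$sample_id
  list(predictions = pred, reports = reports)
}

#' Write classifier reports as JSON
#'
#' @param reports the \code{reports} element of
#'   \code{\link{classifySample}}'s result.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeReports <- function(reports, file) {
  jsonlite::write_json(reports, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}

#' Tumour purity versus classifier score
#'
#' Joins ground-truth (or estimated) tumour purity onto the prediction
#' table and summarizes mean purity in the classifiable and
#' non-classifiable groups.
#'
#' @param predictions table from \code{\link{predictWithThreshold}}.
#' @param sampleSheet sample sheet with \code{sample_id} and \code{purity}.
#' @return list with \code{table} (per-sample purity, max score,
#'   classifiable flag) and \code{group_means} (mean purity per group; a
#'   single row when all samples fall in one group).
#' @export
purityVsScore <- function(predictions, sampleSheet) {
  tab <- merge(predictions, sampleSheet[, c("sample_id", "purity")],
               by = "sample_id", sort = FALSE)
  tab$max_score <- pmax(tab$best_score, tab$family_score, na.rm = TRUE)
  tab <- tab[, c("sample_id", "purity", "max_score", "classifiable")]
  gm <- stats::aggregate(purity ~ classifiable, data = tab, FUN = mean)
  list(table = tab, group_means = gm)
}
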