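#' Overall noise level of a genome-ordered log2-ratio profile
#'
#' First-difference estimator of local noise: the standard deviation of
#' successive differences of the genome-ordered log2 ratios divided by
#' \code{sqrt(2)}, so that unit-variance white noise yields 1.0 while
#' smooth copy-number steps contribute negligibly. The ">3" exclusion
#' threshold is meaningful relative to this scale.
#'
#' @param ratios genome-ordered numeric vector of log2 ratios.
#' @return the noise level (non-negative scalar).
#' @export
computeNoise <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2) stop("need at least 2 finite probe ratios")
  stats::sd(diff(ratios)) / sqrt(2)
}

#' On-chip quality metrics per sample
#'
#' Mean bisulfite-conversion control intensities per control block
#' (both channels pooled) and the overall noise level of the sample's
#' log2 total-intensity profile against the cohort median baseline.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{bc_conversion_I_a}, \code{bc_conversion_I_b},
#'   \code{bc_conversion_II}, \code{noise_level}.
#' @export
qcMetrics <- function(cohort) {
  ctl <- cohort@controls
  blockMean <- function(type) {
    rows <- ctl$info$control_type == type
    if (!any(rows)) return(rep(NA_real_, ncol(cohort)))
    (colMeans(ctl$grn[rows, , drop = FALSE]) +
       colMeans(ctl$red[rows, , drop = FALSE])) / 2
  }
  ann <- as.data.frame(SummarizedExperiment::rowData(cohort))
  auto <- ann$chromosome %in% paste0("chr", 1:22)
  tot <- methylated(cohort) + unmethylated(cohort)
  tot <- tot[auto, , drop = FALSE]
  ord <- order(ann$chromosome[auto], ann$position[auto])
  tot <- tot[ord, , drop = FALSE]
  baseline <- matrixStats::rowMedians(tot)
  ratios <- log2(pmax(tot, 1) / pmax(baseline, 1))
  noise <- apply(ratios, 2, computeNoise)
  data.frame(sample_id = colnames(cohort),
             bc_conversion_I_a = blockMean("bc_conversion_I_a"),
             bc_conversion_I_b = blockMean("bc_conversion_I_b"),
             bc_conversion_II = blockMean("bc_conversion_II"),
             noise_level = noise,
             stringsAsFactors = FALSE)
}

#' Sample-level quality gate
#'
#' A sample is excluded when at least one of its bisulfite-conversion
#' control metrics falls within the lowest 10 percent of the reference
#' distribution \emph{and} its overall noise level exceeds 3
#' (\code{logic = "and"}, the default conjunctive reading). With
#' \code{logic = "or"} either condition alone excludes.
#'
#' @param metrics data.frame as from \code{\link{qcMetrics}} (the samples
#'   to gate).
#' @param referenceMetrics data.frame of the same shape giving the
#'   reference distribution; defaults to \code{metrics} itself when no
#'   external reference cohort is available.
#' @param logic \code{"and"} or \code{"or"}.
#' @param noiseCutoff noise level above which a sample is noisy.
#' @param decile lower quantile of the reference control distribution
#'   defining "low quality".
#' @return data.frame: \code{sample_id}, \code{keep} (logical),
#'   \code{reasons} (semicolon-separated failing metrics, "" if clean).
#' @export
qcGate <- function(metrics, referenceMetrics = metrics,
                   logic = c("and", "or"), noiseCutoff = 3, decile = 0.10) {
  logic <- match.arg(logic)
  if (nrow(referenceMetrics) == 0) stop("reference distribution is empty")
  ctrl_cols <- c("bc_conversion_I_a", "bc_conversion_I_b", "bc_conversion_II")
  cuts <- vapply(ctrl_cols, function(cc)
    stats::quantile(referenceMetrics[[cc]], probs = decile, names = FALSE,
                    na.rm = TRUE), numeric(1))
  keep <- logical(nrow(metrics))
  reasons <- character(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    low <- vapply(ctrl_cols, function(cc)
      isTRUE(metrics[[cc]][i] <= cuts[[cc]]), logical(1))
    noisy <- isTRUE(metrics$noise_level[i] > noiseCutoff)
    excl <- if (logic == "and") any(low) && noisy else any(low) || noisy
    keep[i] <- !excl
    rs <- c(ctrl_cols[low],
            if (noisy) sprintf("noise_level>%g", noiseCutoff))
    reasons[i] <- if (excl) paste(rs, collapse = ";") else ""
  }
  data.frame(sample_id = metrics$sample_id, keep = keep, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Probe filtering to the analysis probe set
#'
#' Sequentially removes, from the non-control probes: (1) probes on the X
#' and Y chromosomes, (2) probes with a SNP within five base pairs of and
#' including the targeted CpG, (3) probes not mapping uniquely to the
#' reference genome allowing one mismatch, (4) probes not present on both
#' the 450k and EPIC arrays. Each probe is attributed to the first filter
#' that removes it, so the per-filter counts plus the kept count equal the
#' input count exactly.
#'
#' @param annotation probe annotation data.frame (control probes are not
#'   candidates and do not enter the bookkeeping).
#' @return a list of class \code{"ProbeFilterReport"}: \code{n_input},
#'   \code{n_removed_xy}, \code{n_removed_snp}, \code{n_removed_nonunique},
#'   \code{n_removed_array_mismatch}, \code{n_kept}, \code{kept_probe_ids}.
#' @export
filterProbes <- function(annotation) {
  req <- c("probe_id", "chromosome", "snp_within_5bp", "maps_uniquely",
           "on_450k", "on_epic", "control_type")
  missing_cols <- setdiff(req, colnames(annotation))
  if (length(missing_cols))
    stop("annotation lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  ann <- annotation[annotation$control_type == "none", ]
  n_input <- nrow(ann)

  is_xy <- ann$chromosome %in% c("chrX", "chrY")
  n_xy <- sum(is_xy); ann <- ann[!is_xy, ]
  is_snp <- ann$snp_within_5bp
  n_snp <- sum(is_snp); ann <- ann[!is_snp, ]
  is_nu <- !ann$maps_uniquely
  n_nu <- sum(is_nu); ann <- ann[!is_nu, ]
  is_mismatch <- !(ann$on_450k & ann$on_epic)
  n_mm <- sum(is_mismatch); ann <- ann[!is_mismatch, ]

  structure(list(n_input = n_input, n_removed_xy = n_xy,
                 n_removed_snp = n_snp, n_removed_nonunique = n_nu,
                 n_removed_array_mismatch = n_mm, n_kept = nrow(ann),
                 kept_probe_ids = ann$probe_id),
            class = "ProbeFilterReport")
}

#' @export
print.ProbeFilterReport <- function(x, ...) {
  cat("ProbeFilterReport:", x$n_input, "probes in\n")
  cat("  removed chrX/chrY:      ", x$n_removed_xy, "\n")
  cat("  removed SNP <= 5bp:     ", x$n_removed_snp, "\n")
  cat("  removed non-unique:     ", x$n_removed_nonunique, "\n")
  cat("  removed array mismatch: ", x$n_removed_array_mismatch, "\n")
  cat("  kept:                   ", x$n_kept, "\n")
  invisible(x)
}
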