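#' Read/write probe annotations and cohorts as plain text
#'
#' The on-disk layout mirrors the array vendor's text exports: the
#' annotation as a BED-like TSV, intensities as two probes x samples TSV
#' matrices (\code{*_meth.tsv}, \code{*_unmeth.tsv}) plus a control table
#' (\code{*_controls.tsv} with one row per control probe and channel),
#' and the sample sheet as CSV.
#'
#' @param annotation probe annotation data.frame.
#' @param file,prefix output path / path prefix.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeAnnotation <- function(annotation, file) {
  utils::write.table(annotation, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname cohort-io
#' @export
readAnnotation <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname cohort-io
#' @param cohort a \linkS4class{MethylCohort}.
#' @export
writeCohort <- function(cohort, prefix) {
  wt <- function(x, suffix) {
    utils::write.table(data.frame(probe_id = rownames(x), x,
                                  check.names = FALSE),
                       paste0(prefix, suffix), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(methylated(cohort), "_meth.tsv")
  wt(unmethylated(cohort), "_unmeth.tsv")
  ctl <- cohort@controls
  ctl_long <- rbind(
    data.frame(ctl$info, channel_read = "grn", ctl$grn, check.names = FALSE),
    data.frame(ctl$info, channel_read = "red", ctl$red, check.names = FALSE))
  utils::write.table(ctl_long, paste0(prefix, "_controls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(sampleSheet(cohort), paste0(prefix, "_samplesheet.csv"),
                   row.names = FALSE)
  writeAnnotation(as.data.frame(SummarizedExperiment::rowData(cohort)),
                  paste0(prefix, "_annotation.tsv"))
  invisible(prefix)
}

#' @rdname cohort-io
#' @export
readCohort <- function(prefix) {
  rd <- function(suffix) {
    x <- utils::read.delim(paste0(prefix, suffix), check.names = FALSE)
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- x$probe_id
    m
  }
  meth <- rd("_meth.tsv")
  unmeth <- rd("_unmeth.tsv")
  ann <- readAnnotation(paste0(prefix, "_annotation.tsv"))
  ss <- utils::read.csv(paste0(prefix, "_samplesheet.csv"),
                        stringsAsFactors = FALSE)
  ctl_long <- utils::read.delim(paste0(prefix, "_controls.tsv"),
                                check.names = FALSE)
  info_cols <- c("probe_id", "control_type", "channel")
  sample_cols <- setdiff(colnames(ctl_long), c(info_cols, "channel_read"))
  grn_rows <- ctl_long$channel_read == "grn"
  info <- ctl_long[grn_rows, info_cols]
  asm <- function(rows) {
    m <- as.matrix(ctl_long[rows, sample_cols, drop = FALSE])
    rownames(m) <- ctl_long$probe_id[rows]
    m
  }
  controls <- list(info = info, grn = asm(grn_rows), red = asm(!grn_rows))
  MethylCohort(meth, unmeth, ann, ss, controls)
}

#' Write a beta matrix as TSV
#'
#' @param beta beta matrix or SummarizedExperiment.
#' @param file output path.
#' @param digits decimal places (default 6).
#' @export
writeBeta <- function(beta, file, digits = 6) {
  b <- round(.betaMatrix(beta), digits)
  utils::write.table(data.frame(probe_id = rownames(b), b,
                                check.names = FALSE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
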