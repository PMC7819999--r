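#' Copy-neutral baseline for CNV calling
#'
#' Per-probe median of the combined (M + U) intensity across a set of
#' reference samples, the copy-neutral reference against which per-sample
#' log2 ratios are formed. Restricting the reference to samples of one
#' material and array type keeps channel-specific batch shifts out of the
#' ratios.
#'
#' @param cohort a normalized \linkS4class{MethylCohort} (background and
#'   dye-bias corrected).
#' @param samples sample ids (or indices) to build the baseline from;
#'   default all.
#' @return named numeric vector of baseline intensities per probe.
#' @export
cnvBaseline <- function(cohort, samples = colnames(cohort)) {
  tot <- (methylated(cohort) + unmethylated(cohort))[, samples, drop = FALSE]
  stats::setNames(matrixStats::rowMedians(tot), rownames(cohort))
}

# reference samples for the copy-neutral baseline: same material and array
# type as the query, excluding the query itself so its own aberrations do
# not contaminate the baseline (fall back to larger sets when too few)
.batchPeers <- function(cohort, sampleId) {
  ss <- sampleSheet(cohort)
  all_others <- setdiff(colnames(cohort), sampleId)
  if (!all(c("material", "array_type") %in% colnames(ss)))
    return(if (length(all_others) >= 3) all_others else colnames(cohort))
  me <- ss[ss$sample_id == sampleId, ]
  peers <- setdiff(ss$sample_id[ss$material == me$material &
                                  ss$array_type == me$array_type], sampleId)
  if (length(peers) >= 3) peers
  else if (length(all_others) >= 3) all_others
  else colnames(cohort)
}

# genome-ordered analysis probes (filter-surviving autosomal probes)
.cnvProbeInfo <- function(cohort) {
  ann <- as.data.frame(SummarizedExperiment::rowData(cohort))
  ann$control_type <- "none"
  kept <- filterProbes(ann)$kept_probe_ids
  info <- ann[ann$probe_id %in% kept, c("probe_id", "chromosome", "position")]
  chrom_num <- as.integer(sub("chr", "", info$chromosome))
  info[order(chrom_num, info$position), ]
}

#' Per-probe log2 copy-number ratios
#'
#' \code{log2((M + U) / baseline)} over the genome-ordered,
#' filter-surviving autosomal probes, recentred by subtracting the mode of
#' the ratio distribution (kernel-density estimate) as the baseline
#' correction, so the copy-neutral state sits at 0 even in aneuploid
#' genomes. Probes with non-positive baseline are excluded with a message.
#'
#' @param cohort a normalized \linkS4class{MethylCohort}.
#' @param sampleId the sample to profile.
#' @param baseline per-probe baseline; by default the median over the
#'   samples sharing the query's material and array type.
#' @return list with \code{ratios} (named, genome-ordered), \code{info}
#'   (probe coordinates) and \code{shift} (the subtracted mode).
#' @export
log2Ratio <- function(cohort, sampleId,
                      baseline = cnvBaseline(cohort,
                                             .batchPeers(cohort, sampleId))) {
  col <- match(sampleId, colnames(cohort))
  if (is.na(col)) stop("unknown sample: ", sampleId)
  info <- .cnvProbeInfo(cohort)
  tot <- (methylated(cohort) + unmethylated(cohort))[info$probe_id, col]
  base <- baseline[info$probe_id]
  bad <- !is.finite(base) | base <= 0 | tot <= 0
  if (any(bad)) {
    message(sum(bad), " probe(s) with non-positive baseline or intensity excluded")
    info <- info[!bad, ]; tot <- tot[!bad]; base <- base[!bad]
  }
  ratios <- log2(tot / base)
  shift <- .densityMode(ratios)
  list(ratios = stats::setNames(ratios - shift, info$probe_id),
       info = info, shift = shift)
}

.densityMode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x, n = 2048)
  m0 <- d$x[which.max(d$y)]
  # refine the kernel-density peak by the median of the surrounding bulk:
  # same location, far lower variance than the raw grid argmax
  w <- max(3 * d$bw, 0.05)
  local <- x[abs(x - m0) <= w]
  if (length(local) >= 10) stats::median(local) else m0
}

#' Bin probe ratios along the genome
#'
#' Tiles each chromosome with fixed-width bins (half-open, 0-based) and
#' merges bins rightward until each holds at least
#' \code{minProbesPerBin} probes; a short trailing bin is merged into its
#' left neighbour. The bin value is the arithmetic mean of its probes'
#' ratios.
#'
#' @param ratios named, genome-ordered log2 ratios.
#' @param info probe coordinate data.frame (\code{probe_id},
#'   \code{chromosome}, \code{position}) aligned to \code{ratios}.
#' @param minProbesPerBin minimum probes per emitted bin.
#' @param targetBinBp nominal bin width in base pairs.
#' @return data.frame: \code{chromosome}, \code{start}, \code{end},
#'   \code{mean_ratio}, \code{n_probes}.
#' @export
binGenome <- function(ratios, info, minProbesPerBin = 5,
                      targetBinBp = 100000) {
  out <- list()
  for (cc in unique(info$chromosome)) {
    on_cc <- info$chromosome == cc
    pos <- info$position[on_cc]
    val <- ratios[on_cc]
    if (length(pos) == 0) next
    # half-open 0-based bins: [k*w, (k+1)*w) holds 1-based point p iff
    # k*w < p <= (k+1)*w
    w <- targetBinBp
    bin_idx <- ceiling(pos / w)
    max_bin <- max(bin_idx)
    cand <- lapply(seq_len(max_bin), function(k) which(bin_idx == k))
    starts <- (seq_len(max_bin) - 1) * w
    ends <- seq_len(max_bin) * w
    merged <- list(); cur <- integer(); cur_start <- starts[1]
    for (k in seq_len(max_bin)) {
      cur <- c(cur, cand[[k]])
      if (length(cur) >= minProbesPerBin) {
        merged[[length(merged) + 1]] <- list(start = cur_start,
                                             end = ends[k], probes = cur)
        cur <- integer()
        if (k < max_bin) cur_start <- starts[k + 1]
      }
    }
    if (length(cur)) {
      if (length(merged)) {
        last <- merged[[length(merged)]]
        last$end <- ends[max_bin]
        last$probes <- c(last$probes, cur)
        merged[[length(merged)]] <- last
      } else {
        merged[[1]] <- list(start = cur_start, end = ends[max_bin],
                            probes = cur)
      }
    }
    for (m in merged) {
      out[[length(out) + 1]] <- data.frame(
        chromosome = cc, start = m$start, end = m$end,
        mean_ratio = mean(val[m$probes]), n_probes = length(m$probes),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# optimal partitioning: minimize sum of segment RSS + penalty per breakpoint
.dpSegment <- function(x, penalty) {
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  rss <- function(i, j) {  # segment x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  F <- c(-penalty, rep(Inf, n))
  prev <- integer(n)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      v <- F[i] + rss(i, j) + penalty
      if (v < F[j + 1]) { F[j + 1] <- v; prev[j] <- i }
    }
  }
  ends <- integer(); j <- n
  while (j > 0) { ends <- c(j, ends); j <- prev[j] - 1 }
  starts <- c(1, utils::head(ends, -1) + 1)
  cbind(start = starts, end = ends)
}

#' Segment binned ratios by penalized least squares
#'
#' Exact change-point segmentation per chromosome: the piecewise-constant
#' fit minimizing the residual sum of squares plus a penalty per
#' breakpoint, solved by dynamic programming. The default penalty is
#' BIC-like, \code{2 * sigma^2 * log(n)} with \code{sigma^2} estimated
#' from the median squared first difference of the bin values.
#'
#' @param bins data.frame from \code{\link{binGenome}}.
#' @param penalty cost per breakpoint; \code{NULL} for the BIC-like
#'   default.
#' @return data.frame: \code{chromosome}, \code{start}, \code{end},
#'   \code{mean_ratio}, \code{n_bins}; segment boundaries align to bin
#'   boundaries.
#' @export
segmentBins <- function(bins, penalty = NULL) {
  if (is.null(penalty)) {
    # noise scale from first differences (robust to true copy-number steps):
    # for white noise, sd(diff) = 1.4826 * median|diff| and var(diff) = 2 sigma^2
    dd <- diff(bins$mean_ratio)
    sigma2 <- if (length(dd)) (1.4826 * stats::median(abs(dd)))^2 / 2 else 0
    penalty <- max(2 * sigma2 * log(nrow(bins)), 1e-8)
  }
  out <- list()
  for (cc in unique(bins$chromosome)) {
    bb <- bins[bins$chromosome == cc, ]
    seg <- .dpSegment(bb$mean_ratio, penalty)
    for (r in seq_len(nrow(seg))) {
      i <- seg[r, "start"]; j <- seg[r, "end"]
      out[[length(out) + 1]] <- data.frame(
        chromosome = cc, start = bb$start[i], end = bb$end[j],
        mean_ratio = mean(bb$mean_ratio[i:j]), n_bins = j - i + 1,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Copy-number profile of one sample
#'
#' Convenience chain: \code{\link{log2Ratio}} then \code{\link{binGenome}}
#' then \code{\link{segmentBins}}.
#'
#' @param cohort a normalized \linkS4class{MethylCohort}.
#' @param sampleId sample to profile.
#' @param baseline per-probe copy-neutral baseline.
#' @param minProbesPerBin,targetBinBp binning parameters.
#' @param penalty segmentation penalty (NULL = automatic).
#' @return a \linkS4class{CNVProfile}.
#' @export
cnvProfile <- function(cohort, sampleId,
                       baseline = cnvBaseline(cohort,
                                              .batchPeers(cohort, sampleId)),
                       minProbesPerBin = 5, targetBinBp = 100000,
                       penalty = NULL) {
  lr <- log2Ratio(cohort, sampleId, baseline)
  bins <- binGenome(lr$ratios, lr$info, minProbesPerBin, targetBinBp)
  segs <- segmentBins(bins, penalty)
  new("CNVProfile", sampleId = sampleId, probeRatios = lr$ratios,
      probeInfo = lr$info, bins = bins, segments = segs,
      baselineShift = lr$shift)
}

#' Per-class summary of copy-number alterations
#'
#' For each genomic bin, the fraction of a class's samples whose covering
#' segment mean exceeds \code{gainCut} (gain frequency) or falls below
#' \code{lossCut} (loss frequency). All profiles must share the same
#' binning.
#'
#' @param profiles list of \linkS4class{CNVProfile} (one class's samples).
#' @param gainCut,lossCut segment-mean thresholds (log2 ratio).
#' @return data.frame: bin coordinates, \code{gain_freq}, \code{loss_freq},
#'   \code{n_samples}.
#' @export
summarizeClass <- function(profiles, gainCut = 0.15, lossCut = -0.15) {
  ref <- profiles[[1]]@bins[, c("chromosome", "start", "end")]
  segMeanPerBin <- function(p) {
    bb <- p@bins[, c("chromosome", "start", "end")]
    if (!identical(bb, ref)) stop("profiles have heterogeneous binning")
    vapply(seq_len(nrow(bb)), function(i) {
      s <- p@segments
      hit <- s$chromosome == bb$chromosome[i] & s$start <= bb$start[i] &
        s$end >= bb$end[i]
      s$mean_ratio[which(hit)[1]]
    }, numeric(1))
  }
  m <- vapply(profiles, segMeanPerBin, numeric(nrow(ref)))
  m <- matrix(m, nrow = nrow(ref))
  data.frame(ref, gain_freq = rowMeans(m > gainCut),
             loss_freq = rowMeans(m < lossCut),
             n_samples = length(profiles), stringsAsFactors = FALSE)
}

#' Export segments as SEG-format text
#'
#' @param profile a \linkS4class{CNVProfile}.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeSEG <- function(profile, file) {
  seg <- profile@segments
  out <- data.frame(ID = profile@sampleId, chrom = seg$chromosome,
                    loc.start = format(seg$start + 1, scientific = FALSE,
                                       trim = TRUE),
                    loc.end = format(seg$end, scientific = FALSE, trim = TRUE),
                    num.mark = seg$n_bins, seg.mean = round(seg$mean_ratio, 4))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
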