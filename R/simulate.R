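#' Simulate a methylation array probe annotation
#'
#' Builds a synthetic probe manifest with the attributes that drive probe
#' filtering: sex-chromosome placement, SNP proximity, mapping uniqueness,
#' array membership (450k/EPIC) and control-probe blocks. Exclusion
#' attributes are assigned to disjoint probe sets so the sequential filter
#' counts are exact: \code{round(frac * nProbes)} probes receive each flag.
#'
#' @param nProbes number of measurement probes (>= 10).
#' @param fracXY fraction placed on chrX/chrY.
#' @param fracSNP fraction flagged with a SNP within 5 bp of the CpG.
#' @param fracNonunique fraction flagged as not mapping uniquely.
#' @param frac450kOnly fraction present on the 450k array only.
#' @param nControlsPerType control probes per control type.
#' @param seed RNG seed; the annotation is deterministic given the seed.
#' @return data.frame with columns \code{probe_id}, \code{chromosome},
#'   \code{position}, \code{snp_within_5bp}, \code{maps_uniquely},
#'   \code{on_450k}, \code{on_epic}, \code{control_type}, \code{channel}.
#'   Control probes have \code{NA} chromosome/position.
#' @export
simulateAnnotation <- function(nProbes, fracXY = 0.02, fracSNP = 0.02,
                               fracNonunique = 0.01, frac450kOnly = 0.02,
                               nControlsPerType = 20, seed = 1) {
  if (nProbes < 10) stop("nProbes must be at least 10")
  if (nControlsPerType < 0) stop("nControlsPerType must be non-negative")
  fr <- c(fracXY, fracSNP, fracNonunique, frac450kOnly)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sum(fr) >= 1) stop("exclusion fractions must sum to less than 1")
  set.seed(seed)

  nXY <- round(fracXY * nProbes)
  nSNP <- round(fracSNP * nProbes)
  nNU <- round(fracNonunique * nProbes)
  n450 <- round(frac450kOnly * nProbes)

  idx <- sample.int(nProbes)
  take <- function(n) {
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  xy_idx <- if (nXY > 0) take(nXY) else integer()
  snp_idx <- if (nSNP > 0) take(nSNP) else integer()
  nu_idx <- if (nNU > 0) take(nNU) else integer()
  k450_idx <- if (n450 > 0) take(n450) else integer()

  chrom <- character(nProbes)
  auto_idx <- setdiff(seq_len(nProbes), xy_idx)
  n_chrom <- min(22L, max(1L, length(auto_idx) %/% 10L))
  chrom[auto_idx] <- paste0("chr", rep(seq_len(n_chrom),
                                       each = ceiling(length(auto_idx) / n_chrom),
                                       length.out = length(auto_idx)))
  chrom[xy_idx] <- rep(c("chrX", "chrY"), length.out = length(xy_idx))

  position <- integer(nProbes)
  for (cc in unique(chrom)) {
    on_cc <- which(chrom == cc)
    position[on_cc] <- seq_along(on_cc) * 10000L
  }

  meas <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(nProbes)),
    chromosome = chrom,
    position = position,
    snp_within_5bp = seq_len(nProbes) %in% snp_idx,
    maps_uniquely = !(seq_len(nProbes) %in% nu_idx),
    on_450k = TRUE,
    on_epic = !(seq_len(nProbes) %in% k450_idx),
    control_type = "none",
    channel = "both",
    stringsAsFactors = FALSE)

  ctl_types <- c("negative", "normalization", "bc_conversion_I_a",
                 "bc_conversion_I_b", "bc_conversion_II")
  ctl <- data.frame(
    probe_id = sprintf("ctl_%s_%03d",
                       rep(ctl_types, each = nControlsPerType),
                       rep(seq_len(nControlsPerType), times = length(ctl_types))),
    chromosome = NA_character_,
    position = NA_integer_,
    snp_within_5bp = FALSE,
    maps_uniquely = TRUE,
    on_450k = TRUE,
    on_epic = TRUE,
    control_type = rep(ctl_types, each = nControlsPerType),
    channel = "both",
    stringsAsFactors = FALSE)
  if (nControlsPerType == 0) ctl <- ctl[0, ]
  rbind(meas, ctl)
}

#' Synthetic cohort configuration
#'
#' Parameters of the generative model for synthetic reference cohorts:
#' class-specific beta archetypes at informative CpGs, convex purity mixing
#' towards a leukocyte archetype, Beta-distributed within-class dispersion,
#' log-normal total intensities, additive log2 batch shifts per
#' material/array level, control-probe blocks and optional copy-number
#' events.
#'
#' At each informative CpG the class archetypes sit at
#' \code{0.5 +/- archetypeSeparation/2}; each class is "high" on its own
#' block of informative probes and "low" elsewhere, so for two classes the
#' archetype distance equals \code{archetypeSeparation} at every
#' informative probe. The observed mean beta is
#' \code{purity * archetype + (1 - purity) * leukocyte}.
#'
#' @param nClasses number of reference methylation classes.
#' @param samplesPerClass scalar or per-class vector of cohort sizes; at
#'   least 7 per class when \code{reference = TRUE} (the minimum for
#'   defining a methylation class).
#' @param nProbes total measurement probes (must match the annotation).
#' @param nInformative number of class-informative CpGs.
#' @param archetypeSeparation distance in beta between class archetype
#'   levels at informative CpGs; must keep archetypes inside (0, 1).
#' @param betaConcentration Beta-distribution concentration (higher =
#'   tighter around the archetype); \code{Inf} gives noiseless betas.
#' @param purityRange range of the uniform ground-truth tumour purity.
#' @param batchEffectLog2 additive log2 intensity shift applied to both
#'   channels of FFPE samples and (independently) EPIC samples.
#' @param cnvEvents optional data.frame with columns \code{class},
#'   \code{chromosome}, \code{start}, \code{end}, \code{copy_state};
#'   injected into every sample of the class at its own purity.
#' @param backgroundLevel median additive optical background per channel
#'   (read back by the negative controls); 0 disables background entirely,
#'   giving the pure mixing model.
#' @param novelSamples number of out-of-reference "novel entity" samples
#'   whose archetypes are drawn independently of all reference archetypes.
#' @param confusable optional list \code{list(pair = c(i, j), separation =
#'   s)} making classes i and j a deliberately confusable pair separated
#'   by \code{s} instead of \code{archetypeSeparation}.
#' @param reference enforce the >= 7 samples/class rule.
#' @param seed RNG seed.
#' @return a list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nClasses = 6, samplesPerClass = 15, nProbes = 2000,
                         nInformative = 50, archetypeSeparation = 0.4,
                         betaConcentration = 50, purityRange = c(0.6, 1),
                         batchEffectLog2 = 0.5, cnvEvents = NULL,
                         backgroundLevel = 200, novelSamples = 0,
                         confusable = NULL, reference = TRUE, seed = 1) {
  if (nInformative > nProbes) stop("nInformative must not exceed nProbes")
  spc <- rep(samplesPerClass, length.out = nClasses)
  if (reference && any(spc < 7))
    stop("a reference cohort requires at least 7 samples per methylation class")
  lo <- 0.5 - archetypeSeparation / 2
  hi <- 0.5 + archetypeSeparation / 2
  if (lo <= 0 || hi >= 1)
    stop("archetypeSeparation places archetypes outside (0, 1)")
  structure(list(nClasses = nClasses, samplesPerClass = spc,
                 nProbes = nProbes, nInformative = nInformative,
                 archetypeSeparation = archetypeSeparation,
                 betaConcentration = betaConcentration,
                 purityRange = purityRange,
                 batchEffectLog2 = batchEffectLog2,
                 backgroundLevel = backgroundLevel,
                 cnvEvents = cnvEvents, novelSamples = novelSamples,
                 confusable = confusable, reference = reference,
                 seed = seed),
            class = "CohortConfig")
}

.drawBimodalBeta <- function(n) {
  comp <- stats::rbinom(n, 1, 0.5)
  ifelse(comp == 1, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
}

.drawIntensityBlock <- function(nr, nc, log2_median, log2_sd) {
  matrix(2 ^ stats::rnorm(nr * nc, mean = log2(log2_median), sd = log2_sd),
         nrow = nr, ncol = nc)
}

#' Simulate a synthetic methylation cohort
#'
#' Draws a cohort of two-channel intensity profiles under the generative
#' model of \code{\link{cohortConfig}}: per-sample betas around purity-mixed
#' class archetypes, per-probe log-normal total intensities split as
#' \code{M = T * beta}, \code{U = T * (1 - beta)}, multiplicative
#' (\code{2^batchEffectLog2}) batch shifts on the measurement probes of
#' FFPE and EPIC samples, control-probe intensity blocks, and any
#' configured copy-number events.
#'
#' @param annotation probe annotation from \code{\link{simulateAnnotation}}.
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{MethylCohort}; ground-truth archetypes and
#'   informative probe ids are stored in \code{metadata()}.
#' @export
simulateCohort <- function(annotation, config) {
  stopifnot(inherits(config, "CohortConfig"))
  meas <- annotation[annotation$control_type == "none", ]
  ctl_info <- annotation[annotation$control_type != "none", ]
  if (!any(ctl_info$control_type == "negative") ||
      !any(ctl_info$control_type == "normalization"))
    stop("annotation needs at least one negative and one normalization control probe")
  p <- nrow(meas)
  if (p != config$nProbes)
    stop("annotation has ", p, " measurement probes but config expects ",
         config$nProbes)
  K <- config$nClasses
  set.seed(config$seed)

  # leukocyte and shared tumour-baseline archetypes over all probes
  leuk <- .drawBimodalBeta(p)
  baseline <- .drawBimodalBeta(p)

  kept <- meas$chromosome %in% paste0("chr", 1:22) &
    !meas$snp_within_5bp & meas$maps_uniquely & meas$on_450k & meas$on_epic
  if (sum(kept) < config$nInformative)
    stop("not enough filter-surviving probes to place informative CpGs")
  informative <- sort(sample(which(kept), config$nInformative))

  lo <- 0.5 - config$archetypeSeparation / 2
  hi <- 0.5 + config$archetypeSeparation / 2
  baseline[informative] <- lo

  # block design: class k is "high" on its own block of informative probes
  blocks <- split(informative,
                  rep(seq_len(K), length.out = length(informative)))
  arch <- matrix(rep(baseline, K), nrow = p)
  for (k in seq_len(K)) arch[blocks[[k]], k] <- hi
  colnames(arch) <- sprintf("class%02d", seq_len(K))

  if (!is.null(config$confusable)) {
    i <- config$confusable$pair[1]; j <- config$confusable$pair[2]
    s <- config$confusable$separation
    arch[, j] <- arch[, i]
    arch[blocks[[j]], j] <- lo + s
    arch[blocks[[j]], i] <- lo
  }

  spc <- config$samplesPerClass
  n_ref <- sum(spc)
  n <- n_ref + config$novelSamples
  class_label <- c(rep(colnames(arch), times = spc),
                   rep("novel", config$novelSamples))

  # per-sample archetype matrix; novel archetypes drawn independently
  sample_arch <- arch[, rep(seq_len(K), times = spc), drop = FALSE]
  if (config$novelSamples > 0) {
    pool <- setdiff(which(kept), informative)
    nov <- matrix(rep(baseline, config$novelSamples), nrow = p)
    for (s in seq_len(config$novelSamples)) {
      own <- sample(pool, min(config$nInformative, length(pool)))
      nov[own, s] <- hi
    }
    sample_arch <- cbind(sample_arch, nov)
  }

  purity <- stats::runif(n, config$purityRange[1], config$purityRange[2])
  # balanced batch design: material and array alternate (with different
  # periods) within each class, keeping both factors orthogonal to class
  # and to each other so the batch correction cannot absorb class signal
  material <- character(n); array_type <- character(n)
  for (cl in unique(class_label)) {
    idx <- which(class_label == cl)
    material[idx] <- rep(c("FFPE", "frozen"), length.out = length(idx))
    array_type[idx] <- rep(c("450k", "EPIC", "EPIC", "450k"),
                           length.out = length(idx))
  }
  sex <- sample(c("F", "M"), n, replace = TRUE)
  ss <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                   class_label = class_label, material = material,
                   array_type = array_type, purity = purity, sex = sex,
                   stringsAsFactors = FALSE)

  m_mean <- sample_arch * rep(purity, each = p) +
    leuk * rep(1 - purity, each = p)
  m_mean <- pmin(pmax(m_mean, 1e-6), 1 - 1e-6)
  if (is.finite(config$betaConcentration)) {
    cc <- config$betaConcentration
    beta <- matrix(stats::rbeta(p * n, m_mean * cc, (1 - m_mean) * cc),
                   nrow = p)
    beta <- pmin(pmax(beta, 1e-9), 1 - 1e-9)
  } else {
    beta <- m_mean
  }

  # total intensity: log-normal, median 5000, 0.3 log2 sd overall; most of
  # the spread is probe affinity shared across samples (as on real arrays,
  # where it cancels against a cohort baseline), the rest per-sample noise
  affinity <- 2 ^ stats::rnorm(p, mean = log2(5000), sd = 0.29)
  tot <- affinity * 2 ^ matrix(stats::rnorm(p * n, 0, 0.08), p, n)
  meth <- tot * beta
  unmeth <- tot * (1 - beta)

  # batch shifts on measurement probes (additive on the log2 scale); the
  # material effect hits the methylated channel and the array effect the
  # unmethylated channel, so the distortion is visible in beta space and
  # removable by the channel-wise linear-model correction -- a shift common
  # to both channels would cancel in M/(M+U) and be unobservable downstream
  b <- config$batchEffectLog2
  meth <- sweep(meth, 2, 2 ^ (b * (material == "FFPE")), "*")
  unmeth <- sweep(unmeth, 2, 2 ^ (b * (array_type == "EPIC")), "*")

  # additive optical background, one level per sample and channel (median
  # 200), read back by the negative controls; every measured intensity
  # carries it, which is what the background-correction step removes
  bgl <- config$backgroundLevel
  bg_grn <- if (bgl > 0) 2 ^ stats::rnorm(n, log2(bgl), 0.2) else rep(0, n)
  bg_red <- if (bgl > 0) 2 ^ stats::rnorm(n, log2(bgl), 0.2) else rep(0, n)
  bgNoise <- function() matrix(2 ^ stats::rnorm(p * n, 0, 0.15), p, n)
  bgM <- sweep(bgNoise(), 2, bg_grn, "*")
  bgU <- sweep(bgNoise(), 2, bg_red, "*")
  meth <- meth + bgM
  unmeth <- unmeth + bgU
  dimnames(meth) <- dimnames(unmeth) <- list(meas$probe_id, ss$sample_id)
  dimnames(bgM) <- dimnames(bgU) <- dimnames(meth)

  # control signal above background; negatives are background only; the
  # normalization controls are tight (their mean sets the dye scale, and a
  # noisy scale would itself distort betas between channels)
  ctl_signal <- c(negative = 0, normalization = 5000,
                  bc_conversion_I_a = 4000, bc_conversion_I_b = 4000,
                  bc_conversion_II = 4000)
  ctl_sd <- c(negative = 0, normalization = 0.05,
              bc_conversion_I_a = 0.2, bc_conversion_I_b = 0.2,
              bc_conversion_II = 0.2)
  nc <- nrow(ctl_info)
  grn <- matrix(0, nc, n); red <- matrix(0, nc, n)
  for (tt in unique(ctl_info$control_type)) {
    rows <- which(ctl_info$control_type == tt)
    nr <- length(rows)
    sig <- ctl_signal[[tt]]
    sigBlock <- function() {
      if (sig == 0) matrix(0, nr, n)
      else matrix(2 ^ stats::rnorm(nr * n, log2(sig), ctl_sd[[tt]]), nr, n)
    }
    ctlBg <- function(lvl) sweep(matrix(2 ^ stats::rnorm(nr * n, 0, 0.15),
                                        nr, n), 2, lvl, "*")
    grn[rows, ] <- sigBlock() + ctlBg(bg_grn)
    red[rows, ] <- sigBlock() + ctlBg(bg_red)
  }
  dimnames(grn) <- dimnames(red) <- list(ctl_info$probe_id, ss$sample_id)
  controls <- list(info = ctl_info[, c("probe_id", "control_type", "channel")],
                   grn = grn, red = red)

  cohort <- MethylCohort(meth, unmeth, meas, ss, controls)
  # kept so that copy-number injection can scale the genomic signal only
  S4Vectors::metadata(cohort)$background <- list(grn = bgM, red = bgU)
  S4Vectors::metadata(cohort)$archetypes <- arch
  S4Vectors::metadata(cohort)$leukocyte <- leuk
  S4Vectors::metadata(cohort)$informative <- meas$probe_id[informative]
  S4Vectors::metadata(cohort)$config <- config

  ev <- config$cnvEvents
  if (!is.null(ev)) {
    for (r in seq_len(nrow(ev))) {
      in_class <- which(ss$class_label == ev$class[r])
      for (s in in_class) {
        cohort <- injectCNV(cohort, ss$sample_id[s], ev$chromosome[r],
                            ev$start[r], ev$end[r], ev$copy_state[r],
                            purity = ss$purity[s])
      }
    }
  }
  cohort
}

#' Inject a copy-number event into one sample
#'
#' Scales the total intensity (M + U) of all probes in a genomic region by
#' \code{purity * copyState/2 + (1 - purity)}, the expected intensity
#' ratio of a clonal copy-number state diluted by normal cells. Both
#' channels are scaled equally, so per-probe beta values are unchanged.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @param sampleId the sample to modify.
#' @param chromosome,start,end the affected region (positions inclusive).
#' @param copyState total copy number of the event (2 = neutral); must be
#'   positive.
#' @param purity fraction of cells carrying the event.
#' @return the modified cohort; if the region overlaps no probe a warning
#'   is raised and the cohort is returned unchanged.
#' @export
injectCNV <- function(cohort, sampleId, chromosome, start, end, copyState,
                      purity = 1) {
  if (copyState <= 0) stop("copyState must be positive")
  ann <- as.data.frame(SummarizedExperiment::rowData(cohort))
  rows <- which(ann$chromosome == chromosome &
                ann$position >= start & ann$position <= end)
  if (length(rows) == 0) {
    warning("region ", chromosome, ":", start, "-", end,
            " overlaps no probe; sample unchanged")
    return(cohort)
  }
  col <- match(sampleId, colnames(cohort))
  if (is.na(col)) stop("unknown sample: ", sampleId)
  scale <- purity * (copyState / 2) + (1 - purity)
  a <- SummarizedExperiment::assays(cohort)
  # a copy-number event amplifies genomic signal, not optical background:
  # when the generator recorded its background, scale only the excess
  bg <- S4Vectors::metadata(cohort)$background
  if (!is.null(bg)) {
    a$meth[rows, col] <- (a$meth[rows, col] - bg$grn[rows, col]) * scale +
      bg$grn[rows, col]
    a$unmeth[rows, col] <- (a$unmeth[rows, col] - bg$red[rows, col]) * scale +
      bg$red[rows, col]
  } else {
    a$meth[rows, col] <- a$meth[rows, col] * scale
    a$unmeth[rows, col] <- a$unmeth[rows, col] * scale
  }
  SummarizedExperiment::assays(cohort) <- a
  cohort
}
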