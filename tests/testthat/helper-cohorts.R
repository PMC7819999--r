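# Shared fixture builders and small oracles used across the suite.

# A hand-assembled two-sample cohort with fully controlled intensities,
# for exact normalization arithmetic. Negative/normalization controls can
# be set per channel.
makeToyCohort <- function(meth, unmeth,
                          negGrn, negRed = negGrn,
                          normGrn, normRed = normGrn) {
  p <- nrow(meth)
  n <- ncol(meth)
  ann <- data.frame(probe_id = sprintf("cg%03d", seq_len(p)),
                    chromosome = "chr1", position = seq_len(p) * 1000L,
                    snp_within_5bp = FALSE, maps_uniquely = TRUE,
                    on_450k = TRUE, on_epic = TRUE,
                    control_type = "none", channel = "both",
                    stringsAsFactors = FALSE)
  ss <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   class_label = "classA", material = "FFPE",
                   array_type = "450k", purity = 1, sex = "F",
                   stringsAsFactors = FALSE)
  nneg <- nrow(negGrn); nnorm <- nrow(normGrn)
  info <- data.frame(
    probe_id = c(sprintf("neg%02d", seq_len(nneg)),
                 sprintf("norm%02d", seq_len(nnorm))),
    control_type = rep(c("negative", "normalization"), c(nneg, nnorm)),
    channel = "both", stringsAsFactors = FALSE)
  controls <- list(info = info,
                   grn = rbind(negGrn, normGrn),
                   red = rbind(negRed, normRed))
  rownames(meth) <- rownames(unmeth) <- ann$probe_id
  colnames(meth) <- colnames(unmeth) <- ss$sample_id
  MethylCohort(meth, unmeth, ann, ss, controls)
}

# simulateAnnotation + simulateCohort in one call with clean defaults
makeCohort <- function(nClasses = 3, samplesPerClass = 8, nProbes = 400,
                       nInformative = 30, separation = 0.4,
                       concentration = 100, purityRange = c(1, 1),
                       batch = 0, background = 200, seed = 1,
                       annSeed = seed, ...) {
  ann <- simulateAnnotation(nProbes, fracXY = 0.02, fracSNP = 0.02,
                            fracNonunique = 0.01, frac450kOnly = 0.02,
                            nControlsPerType = 10, seed = annSeed)
  cfg <- cohortConfig(nClasses = nClasses, samplesPerClass = samplesPerClass,
                      nProbes = nProbes, nInformative = nInformative,
                      archetypeSeparation = separation,
                      betaConcentration = concentration,
                      purityRange = purityRange, batchEffectLog2 = batch,
                      backgroundLevel = background,
                      reference = FALSE, seed = seed, ...)
  simulateCohort(ann, cfg)
}

classLabelsOf <- function(cohort) sampleSheet(cohort)$class_label

# adjusted Rand index between two labelings (closed-form contingency sum)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# brute-force two-class AUC by enumerating all pairs (ties count half)
bruteAUC <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# mean silhouette width of a labeling over 2-D coordinates
meanSilhouette <- function(coords, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(coords))
  mean(sil[, "sil_width"])
}
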