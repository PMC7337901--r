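#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median across genes of the ratio of the
#' sample's count to the gene's geometric mean across samples, using only
#' genes with a positive geometric mean (i.e. expressed in all samples).
#' Factors are then rescaled to geometric mean 1 so that normalized counts
#' keep the scale of the raw library; only ratios between factors are
#' identified by the method.
#'
#' @param counts integer matrix, genes x samples.
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; filter low-count genes first")
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - log_gm[use]))
  })
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Method-of-moments NB dispersion with trend shrinkage
#'
#' Per gene, a pooled within-group moments estimate on normalized counts:
#' alpha = (s^2 - mean)/mean^2 pooled across the design groups
#' (dataset x genotype cells), floored at zero. Gene-wise estimates are then
#' shrunk 50/50 on the log-ish scale toward a mean-dispersion trend
#' alpha_trend(mu) = a/mu + b fit by least squares, which stabilises genes
#' with few replicates. A simplification of the full Cox-Reid/empirical-Bayes
#' machinery of the established DE packages, adequate at the replicate
#' numbers exercised here.
#'
#' @param counts integer matrix, genes x samples.
#' @param sf size factors from [size_factors()].
#' @param sheet sample sheet defining the groups.
#' @return list with \code{alpha} (named per-gene dispersion, floored at
#'   1e-8) and \code{flagged} (gene ids with no usable moments estimate).
#' @export
estimate_dispersion <- function(counts, sf, sheet) {
  norm <- sweep(counts, 2, sf, "/")
  groups <- interaction(sheet$dataset, sheet$genotype, sheet$arm, drop = TRUE)
  if (any(table(groups) < 2)) stop("every design group needs >= 2 samples")
  ng <- nrow(counts)
  num <- rep(0, ng); den <- rep(0, ng); mu_all <- rowMeans(norm)
  for (g in levels(groups)) {
    sub <- norm[, groups == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    w <- ncol(sub) - 1
    ok <- m > 0
    num[ok] <- num[ok] + w * (v[ok] - m[ok]) / m[ok]^2
    den[ok] <- den[ok] + w
  }
  raw <- ifelse(den > 0, pmax(0, num / den), NA_real_)
  flagged <- rownames(counts)[!is.finite(raw)]
  # trend alpha(mu) = a/mu + b by least squares over genes with an estimate
  ok <- is.finite(raw) & mu_all > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm.fit(cbind(1 / mu_all[ok], 1), raw[ok])
    a <- fit$coefficients[1]; b <- fit$coefficients[2]
  } else {
    a <- 0; b <- stats::median(raw[ok], na.rm = TRUE)
  }
  trend <- pmax(0, a / pmax(mu_all, 1e-8) + b)
  alpha <- ifelse(is.finite(raw), 0.5 * raw + 0.5 * trend, trend)
  alpha <- pmax(alpha, 1e-8)
  names(alpha) <- rownames(counts)
  list(alpha = alpha, flagged = flagged)
}

#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up BH across the non-missing p-values; NAs (non-converged fits) are
#' excluded from the adjustment and propagated.
#'
#' @param pvalues numeric vector in [0, 1], NA allowed.
#' @return adjusted values in [0, 1], NA where input was NA.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Per-gene negative binomial differential expression
#'
#' Fits, for each gene, an NB log-link GLM of counts with offset
#' log(size factor), testing WT vs non-WT. The per-dataset model uses design
#' ~ genotype within one dataset; the joint model pools all datasets of one
#' comparison arm with design ~ genotype + dataset, so the dataset covariate
#' absorbs dataset-level baseline differences while the genotype coefficient
#' estimates the shared effect. Inference is a Wald test on the genotype
#' coefficient with BH correction across genes.
#'
#' @param counts integer matrix covering the samples to model (one arm).
#' @param sheet sample sheet for those samples.
#' @param joint pool datasets with a dataset covariate when TRUE.
#' @param genotype which non-WT genotype to compare against WT ("HOM" or
#'   "HET"); the other genotype's samples are dropped.
#' @param min_group_count genes with zero counts in every sample of any
#'   genotype group are filtered before fitting.
#' @param sf optional named size factors; computed from \code{counts} when
#'   NULL.
#' @param dispersion optional precomputed [estimate_dispersion()] result.
#' @return data.frame with gene_id, log2fc, se, wald_stat, p, fdr, mean_expr,
#'   model; genes failing convergence carry NA and are excluded from BH.
#' @export
fit_de <- function(counts, sheet, joint = FALSE, genotype = "HOM",
                   min_group_count = 1, sf = NULL, dispersion = NULL) {
  keep <- sheet$genotype %in% c("WT", genotype)
  sheet <- sheet[keep, , drop = FALSE]
  counts <- counts[, sheet$sample_id, drop = FALSE]
  n_ds <- length(unique(sheet$dataset))
  if (joint && n_ds < 2) {
    # a single dataset leaves nothing for the covariate to absorb
    joint_design <- FALSE
  } else {
    joint_design <- joint
  }
  if (is.null(sf)) sf <- size_factors(counts)
  sf <- sf[colnames(counts)]
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, sf, sheet)
  alpha <- dispersion$alpha
  mutant <- as.integer(sheet$genotype != "WT")
  if (length(unique(mutant)) < 2) stop("need both WT and non-WT samples")
  X <- if (joint_design) {
    stats::model.matrix(~ mutant + factor(sheet$dataset))
  } else {
    stats::model.matrix(~ mutant)
  }
  # filter genes with an all-zero genotype group (GLM stability)
  grp_zero <- vapply(rownames(counts), function(g) {
    any(tapply(counts[g, ], mutant, max) < min_group_count)
  }, TRUE)
  norm_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  off <- log(sf)
  res <- data.frame(gene_id = rownames(counts), log2fc = NA_real_,
                    se = NA_real_, wald_stat = NA_real_, p = NA_real_,
                    fdr = NA_real_, mean_expr = norm_mean,
                    model = if (joint_design) "joint" else "per-dataset",
                    stringsAsFactors = FALSE)
  for (i in which(!grp_zero)) {
    y <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, offset = off, family = fam,
                                      control = stats::glm.control(
                                        epsilon = 1e-8, maxit = 100))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) next
    cf <- fit$coefficients["mutant"]
    # Wald se with the NB variance fully specified by alpha (dispersion 1):
    # covariance = (X' W X)^{-1} from the final IRLS weights
    w <- fit$weights
    cov <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
    if (is.null(cov) || !is.finite(cf)) next
    se_log <- sqrt(cov["mutant", "mutant"])
    if (!is.finite(se_log) || se_log <= 0) next
    res$log2fc[i] <- cf / log(2)
    res$se[i] <- se_log / log(2)
    res$wald_stat[i] <- cf / se_log
    # t reference with residual df: the plug-in dispersion makes the normal
    # reference anticonservative at small replicate numbers
    res$p[i] <- 2 * stats::pt(-abs(res$wald_stat[i]),
                              df = nrow(X) - ncol(X))
  }
  res$fdr <- bh_adjust(res$p)
  res
}

#' Expression relative to wild type
#'
#' Normalized counts divided, per dataset, by the gene's mean normalized
#' count over that dataset's WT samples, so WT maps to 1 and a doubled mutant
#' to 2. Genes with WT mean zero in a dataset are NA there.
#'
#' @param counts integer matrix.
#' @param sf named size factors.
#' @param sheet sample sheet.
#' @return numeric matrix, genes x samples.
#' @export
relative_expression <- function(counts, sf, sheet) {
  norm <- sweep(counts[, sheet$sample_id, drop = FALSE], 2,
                sf[sheet$sample_id], "/")
  out <- norm
  for (d in unique(sheet$dataset)) {
    in_ds <- sheet$dataset == d
    wt <- in_ds & sheet$genotype == "WT"
    if (!any(wt)) stop("dataset ", d, " has no WT sample")
    wt_mean <- rowMeans(norm[, wt, drop = FALSE])
    denom <- ifelse(wt_mean > 0, wt_mean, NA_real_)
    out[, in_ds] <- norm[, in_ds, drop = FALSE] / denom
  }
  out
}
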