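#' Strict/relaxed overlap classification between two joint models
#'
#' Labels every feature of the common universe by where its evidence lies:
#' \describe{
#'   \item{shared_strict}{FDR < alpha in both models.}
#'   \item{shared_relaxed_only}{FDR < alpha in exactly one model and raw
#'     p < alpha in the other.}
#'   \item{ko_specific / nls_specific}{FDR < alpha on that side and raw
#'     p >= alpha on the other.}
#'   \item{neither}{everything else.}
#' }
#' Ties at exactly FDR = alpha are non-significant (strict inequality).
#' Features present in only one model are excluded with a warning.
#'
#' @param ko,nls result data.frames with a feature id column (first column
#'   named \code{gene_id} or \code{event_id}), \code{p} and \code{fdr}.
#' @param alpha significance level (default 0.05).
#' @return data.frame with feature_id, label, ko_p, ko_fdr, nls_p, nls_fdr
#'   and the two log2 effect columns \code{ko_lfc}, \code{nls_lfc}.
#' @export
classify_overlap <- function(ko, nls, alpha = 0.05) {
  id_col <- intersect(c("event_id", "gene_id"), names(ko))[1]
  lfc_col <- intersect(c("log2fc", "log2_usage_fc"), names(ko))[1]
  common <- intersect(ko[[id_col]], nls[[id_col]])
  dropped <- length(union(ko[[id_col]], nls[[id_col]])) - length(common)
  if (dropped > 0) {
    warning(dropped, " feature(s) present in only one model were excluded")
  }
  k <- ko[match(common, ko[[id_col]]), ]
  n <- nls[match(common, nls[[id_col]]), ]
  sig_k <- !is.na(k$fdr) & k$fdr < alpha
  sig_n <- !is.na(n$fdr) & n$fdr < alpha
  raw_k <- !is.na(k$p) & k$p < alpha
  raw_n <- !is.na(n$p) & n$p < alpha
  label <- rep("neither", length(common))
  label[sig_k & sig_n] <- "shared_strict"
  label[sig_k & !sig_n & raw_n] <- "shared_relaxed_only"
  label[!sig_k & sig_n & raw_k] <- "shared_relaxed_only"
  label[sig_k & !sig_n & !raw_n] <- "ko_specific"
  label[!sig_k & sig_n & !raw_k] <- "nls_specific"
  data.frame(feature_id = common, label = label,
             ko_p = k$p, ko_fdr = k$fdr, nls_p = n$p, nls_fdr = n$fdr,
             ko_lfc = k[[lfc_col]], nls_lfc = n[[lfc_col]],
             stringsAsFactors = FALSE)
}

#' Direction concordance among shared features
#'
#' A shared feature (strict or relaxed) is discordant when its two effect
#' estimates have opposite signs; zero effects count as concordant.
#'
#' @param overlap data.frame from [classify_overlap()].
#' @return list with n_concordant, n_discordant and the discordant ids.
#' @export
direction_concordance <- function(overlap) {
  shared <- overlap[overlap$label %in% c("shared_strict",
                                         "shared_relaxed_only"), ]
  disc <- sign(shared$ko_lfc) * sign(shared$nls_lfc) < 0
  disc[is.na(disc)] <- FALSE
  list(n_concordant = sum(!disc), n_discordant = sum(disc),
       discordant_ids = shared$feature_id[disc])
}

#' Attenuation regression of one arm's effects on the other's
#'
#' Ordinary least squares of the NLS-arm log2 effects on the KO-arm effects,
#' with intercept: a slope below 1 quantifies a partial loss of function
#' (the NLS effect is that fraction of the KO effect), and a near-zero
#' intercept is itself a sanity check. The slope through the origin is also
#' reported for transparency.
#'
#' @param ko_lfc,nls_lfc paired finite effect estimates (shared features).
#' @return list with slope, intercept, slope_origin, r_squared, f_p, n.
#' @export
fit_attenuation <- function(ko_lfc, nls_lfc) {
  ok <- is.finite(ko_lfc) & is.finite(nls_lfc)
  x <- ko_lfc[ok]; y <- nls_lfc[ok]
  if (length(x) < 3) stop("need at least 3 paired finite effects")
  if (stats::var(x) == 0) stop("zero variance in the reference effects")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_origin = sum(x * y) / sum(x * x),
       r_squared = sm$r.squared,
       f_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                       lower.tail = FALSE)[[1]],
       n = length(x))
}

#' Dosage regression of heterozygote on homozygote effects
#'
#' Same estimator as [fit_attenuation()]; a slope below 1 demonstrates a
#' gene-dosage effect (heterozygotes show a reduced effect size).
#'
#' @param het_lfc,hom_lfc paired effect estimates.
#' @return as [fit_attenuation()].
#' @export
fit_dosage <- function(het_lfc, hom_lfc) {
  fit_attenuation(ko_lfc = hom_lfc, nls_lfc = het_lfc)
}

#' Fisher intersection of two feature sets
#'
#' Two-sided Fisher's exact test on the 2x2 table induced by membership of
#' the two sets within a common universe (e.g. genes with a complex splicing
#' event against differentially expressed genes).
#'
#' @param set_a,set_b character vectors of feature ids.
#' @param universe character vector containing both sets.
#' @return list with overlap, n_a, n_b, n_universe, odds_ratio, p.
#' @export
intersect_sets <- function(set_a, set_b, universe) {
  offenders <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(offenders)) {
    stop("sets must be contained in the universe; offenders: ",
         paste(utils::head(offenders, 5), collapse = ", "))
  }
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(overlap = sum(in_a & in_b), n_a = sum(in_a), n_b = sum(in_b),
       n_universe = length(universe), odds_ratio = unname(ft$estimate),
       p = ft$p.value)
}
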