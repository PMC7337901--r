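#' Splice event table
#'
#' A collection of splicing events with per-sample inclusion and exclusion
#' read counts, a JSON descriptor of the variant junctions (see
#' [make_descriptor()]) and the coordinates of the encompassing intron, the
#' interval later used for binding and conservation summaries.
#'
#' @param events data.frame with event_id, gene_id, descriptor, chrom, start,
#'   end, strand.
#' @param inclusion,exclusion integer matrices, events x samples, with
#'   matching dimnames.
#' @return object of class \code{splice_event_table}.
#' @export
splice_event_table <- function(events, inclusion, exclusion) {
  stopifnot(is.data.frame(events),
            all(c("event_id", "gene_id", "descriptor", "chrom", "start",
                  "end", "strand") %in% names(events)))
  if (anyDuplicated(events$event_id)) stop("event ids must be unique")
  if (!identical(dim(inclusion), dim(exclusion))) {
    stop("inclusion and exclusion dimensions differ")
  }
  if (any(inclusion < 0) || any(exclusion < 0)) {
    stop("negative inclusion/exclusion counts")
  }
  stopifnot(identical(rownames(inclusion), events$event_id),
            identical(colnames(inclusion), colnames(exclusion)))
  validate_intervals(events[, c("chrom", "start", "end", "strand")])
  structure(list(events = events, inclusion = inclusion,
                 exclusion = exclusion), class = "splice_event_table")
}

#' Write / read a splice event table as TSV
#'
#' One row per event: the descriptor column is JSON-encoded; per-sample
#' counts appear as \code{incl_<sample>} and \code{excl_<sample>} columns.
#'
#' @param tab a [splice_event_table()].
#' @param path file path.
#' @export
write_events <- function(tab, path) {
  stopifnot(inherits(tab, "splice_event_table"))
  inc <- as.data.frame(tab$inclusion)
  names(inc) <- paste0("incl_", colnames(tab$inclusion))
  exc <- as.data.frame(tab$exclusion)
  names(exc) <- paste0("excl_", colnames(tab$exclusion))
  out <- cbind(tab$events, inc, exc)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  inc_cols <- grep("^incl_", names(df), value = TRUE)
  exc_cols <- grep("^excl_", names(df), value = TRUE)
  inclusion <- as.matrix(df[, inc_cols, drop = FALSE])
  exclusion <- as.matrix(df[, exc_cols, drop = FALSE])
  colnames(inclusion) <- sub("^incl_", "", inc_cols)
  colnames(exclusion) <- sub("^excl_", "", exc_cols)
  rownames(inclusion) <- rownames(exclusion) <- df$event_id
  storage.mode(inclusion) <- storage.mode(exclusion) <- "integer"
  splice_event_table(df[, setdiff(names(df), c(inc_cols, exc_cols))],
                     inclusion, exclusion)
}

#' Percent spliced in
#'
#' psi = inclusion / (inclusion + exclusion) per event and sample, NA when no
#' reads cover the event; totals below \code{min_total} are flagged
#' low-coverage.
#'
#' @param tab a [splice_event_table()].
#' @param min_total coverage below which a value is flagged.
#' @return data.frame with event_id, sample_id, psi, total, low_coverage.
#' @export
compute_psi <- function(tab, min_total = 10) {
  stopifnot(inherits(tab, "splice_event_table"))
  total <- tab$inclusion + tab$exclusion
  psi <- ifelse(total > 0, tab$inclusion / total, NA_real_)
  data.frame(
    event_id = rep(rownames(total), ncol(total)),
    sample_id = rep(colnames(total), each = nrow(total)),
    psi = as.vector(psi), total = as.vector(total),
    low_coverage = as.vector(total) < min_total,
    stringsAsFactors = FALSE)
}

parse_descriptor <- function(descriptor) {
  d <- jsonlite::fromJSON(descriptor, simplifyVector = FALSE)
  norm <- function(x) lapply(x, function(p) c(as.numeric(p[[1]]),
                                              as.numeric(p[[2]])))
  list(strand = d$strand, inclusion = norm(d$inclusion),
       exclusion = norm(d$exclusion))
}

#' Classify a splicing event from its junction descriptor
#'
#' Assigns exactly one label. With I and E the junction sets of the inclusion
#' and exclusion forms: an unspliced form against a single donor-acceptor
#' junction is a retained intron; one internal exon whose two flanking
#' junctions share their outer coordinates with a single skipping junction is
#' a cassette exon; two single junctions sharing the acceptor (donor) are an
#' alternative 5' donor (3' acceptor), resolved strand-aware; two identical
#' single junctions are degenerate ("other"); anything combining more than
#' one elementary alternative is complex.
#'
#' @param descriptor JSON descriptor string (see [make_descriptor()]).
#' @return one of retained_intron, cassette_exon, alt5, alt3, complex, other.
#' @export
classify_event <- function(descriptor) {
  d <- parse_descriptor(descriptor)
  I <- d$inclusion; E <- d$exclusion
  nI <- length(I); nE <- length(E)
  if (nI + nE == 0) stop("empty splicing descriptor")
  if (xor(nI == 0, nE == 0)) {
    spliced <- if (nI == 0) E else I
    return(if (length(spliced) == 1) "retained_intron" else "complex")
  }
  if (nI == 1 && nE == 1) {
    a <- I[[1]]; b <- E[[1]]
    if (all(a == b)) return("other")
    plus <- !identical(d$strand, "-")
    shared_start <- a[1] == b[1]
    shared_end <- a[2] == b[2]
    if (shared_start && !shared_end) return(if (plus) "alt3" else "alt5")
    if (shared_end && !shared_start) return(if (plus) "alt5" else "alt3")
    return("complex")  # both ends differ: two distinct alternatives
  }
  if ((nI == 2 && nE == 1) || (nI == 1 && nE == 2)) {
    two <- if (nI == 2) I else E
    one <- (if (nI == 2) E else I)[[1]]
    outer_start <- min(vapply(two, `[`, 0, 1))
    outer_end <- max(vapply(two, `[`, 0, 2))
    if (outer_start == one[1] && outer_end == one[2]) return("cassette_exon")
    return("complex")
  }
  "complex"
}

# method-of-moments intraclass correlation for a binomial GLM fit
mom_rho <- function(y, m, fitted_p, n_coef) {
  ok <- m > 0 & fitted_p > 1e-12 & fitted_p < 1 - 1e-12
  if (sum(ok) <= n_coef) return(0)
  X2 <- sum((y[ok] - m[ok] * fitted_p[ok])^2 /
              (m[ok] * fitted_p[ok] * (1 - fitted_p[ok])))
  phi <- X2 / (sum(ok) - n_coef)
  mbar <- mean(m[ok])
  if (mbar <= 1) return(0)
  min(max((phi - 1) / (mbar - 1), 0), 0.95)
}

betabin_negll <- function(beta, X, y, m, rho) {
  p <- stats::plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  nu <- 1 / rho - 1
  a <- p * nu; b <- (1 - p) * nu
  -sum(lbeta(y + a, m - y + b) - lbeta(a, b))
}

fit_betabin <- function(X, y, m, rho, start) {
  opt <- try(stats::optim(start, betabin_negll, X = X, y = y, m = m, rho = rho,
                          method = "BFGS", hessian = TRUE,
                          control = list(maxit = 200, reltol = 1e-10)),
             silent = TRUE)
  if (inherits(opt, "try-error")) return(NULL)
  opt
}

#' Differential splicing usage across genotypes
#'
#' For each event, models inclusion counts given totals on the logit scale
#' with design ~ genotype (plus a dataset covariate when \code{joint}).
#' Overdispersion relative to the binomial is estimated per event by method
#' of moments (intraclass correlation from the Pearson statistic of a
#' binomial fit); when positive, a beta-binomial likelihood with that fixed
#' correlation is maximized for the full and reduced designs, otherwise the
#' binomial fit stands. The genotype effect is tested by likelihood ratio
#' (1 df) with BH across events; log2_usage_fc is the genotype log-odds
#' coefficient divided by ln 2.
#'
#' @param tab a [splice_event_table()] covering the samples of one arm.
#' @param sheet sample sheet for those samples.
#' @param joint include a dataset covariate.
#' @param genotype non-WT genotype compared to WT.
#' @param min_total events whose totals are all below this are NA and
#'   excluded from BH.
#' @return data.frame with event_id, gene_id, type, log2_usage_fc, se, stat,
#'   p, fdr, delta_psi, model.
#' @export
fit_usage <- function(tab, sheet, joint = FALSE, genotype = "HOM",
                      min_total = 10) {
  stopifnot(inherits(tab, "splice_event_table"))
  keep <- sheet$genotype %in% c("WT", genotype)
  sheet <- sheet[keep, , drop = FALSE]
  inc <- tab$inclusion[, sheet$sample_id, drop = FALSE]
  exc <- tab$exclusion[, sheet$sample_id, drop = FALSE]
  mutant <- as.integer(sheet$genotype != "WT")
  if (length(unique(mutant)) < 2) stop("need both WT and non-WT samples")
  n_ds <- length(unique(sheet$dataset))
  joint_design <- joint && n_ds >= 2
  Xf <- if (joint_design) {
    stats::model.matrix(~ mutant + factor(sheet$dataset))
  } else {
    stats::model.matrix(~ mutant)
  }
  Xr <- Xf[, -2, drop = FALSE]
  ne <- nrow(inc)
  res <- data.frame(event_id = tab$events$event_id,
                    gene_id = tab$events$gene_id,
                    type = vapply(tab$events$descriptor, classify_event, "",
                                  USE.NAMES = FALSE),
                    log2_usage_fc = NA_real_, se = NA_real_, stat = NA_real_,
                    p = NA_real_, fdr = NA_real_, delta_psi = NA_real_,
                    model = if (joint_design) "joint" else "per-dataset",
                    stringsAsFactors = FALSE)
  for (i in seq_len(ne)) {
    y <- inc[i, ]; m <- y + exc[i, ]
    if (all(m < min_total)) next
    use <- m > 0
    if (sum(use & mutant == 1) == 0 || sum(use & mutant == 0) == 0) next
    yy <- y[use]; mm <- m[use]
    Xfu <- Xf[use, , drop = FALSE]; Xru <- Xr[use, , drop = FALSE]
    ff <- tryCatch(suppressWarnings(
      stats::glm.fit(Xfu, cbind(yy, mm - yy), family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100))),
      error = function(e) NULL)
    fr <- tryCatch(suppressWarnings(
      stats::glm.fit(Xru, cbind(yy, mm - yy), family = stats::binomial(),
                     control = stats::glm.control(epsilon = 1e-10,
                                                  maxit = 100))),
      error = function(e) NULL)
    if (is.null(ff) || is.null(fr) || !ff$converged) next
    rho <- mom_rho(yy, mm, ff$fitted.values, ncol(Xfu))
    if (rho <= 0) {
      stat <- fr$deviance - ff$deviance
      coef_mut <- ff$coefficients["mutant"]
      w <- ff$weights
      cov <- tryCatch(solve(crossprod(Xfu * sqrt(w))), error = function(e) NULL)
      se <- if (is.null(cov)) NA_real_ else sqrt(cov["mutant", "mutant"])
    } else {
      of <- fit_betabin(Xfu, yy, mm, rho,
                        start = ifelse(is.finite(ff$coefficients),
                                       ff$coefficients, 0))
      or <- fit_betabin(Xru, yy, mm, rho,
                        start = ifelse(is.finite(fr$coefficients),
                                       fr$coefficients, 0))
      if (is.null(of) || is.null(or)) next
      stat <- 2 * (or$value - of$value)
      coef_mut <- of$par[2]
      hin <- tryCatch(solve(of$hessian), error = function(e) NULL)
      se <- if (is.null(hin) || hin[2, 2] <= 0) NA_real_ else sqrt(hin[2, 2])
    }
    if (!is.finite(stat)) next
    stat <- max(stat, 0)
    res$log2_usage_fc[i] <- coef_mut / log(2)
    res$se[i] <- se / log(2)
    res$stat[i] <- stat
    res$p[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    psi <- ifelse(m > 0, y / m, NA_real_)
    res$delta_psi[i] <- mean(psi[mutant == 1], na.rm = TRUE) -
      mean(psi[mutant == 0], na.rm = TRUE)
  }
  res$fdr <- bh_adjust(res$p)
  res
}

#' Mean mutant minus mean WT PSI per event
#'
#' @param psi data.frame from [compute_psi()].
#' @param sheet sample sheet; samples with genotype != WT count as mutant.
#' @return named numeric vector of delta PSI per event (NA when a group has
#'   no defined PSI).
#' @export
delta_psi <- function(psi, sheet) {
  mut <- sheet$sample_id[sheet$genotype != "WT"]
  wt <- sheet$sample_id[sheet$genotype == "WT"]
  if (length(mut) == 0 || length(wt) == 0) {
    stop("need both WT and mutant samples")
  }
  grp_mean <- function(ids) {
    sub <- psi[psi$sample_id %in% ids, , drop = FALSE]
    tapply(sub$psi, sub$event_id, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  }
  m <- grp_mean(mut); w <- grp_mean(wt)
  m[names(w)] - w
}

#' Cryptic / skiptic classification of cassette exons
#'
#' A cassette exon essentially absent in wild type (mean WT PSI <= low_thr)
#' that gains inclusion under perturbation (mean mutant PSI >= low_thr +
#' min_gain) is cryptic; one constitutively included in wild type (>=
#' high_thr) that loses inclusion (<= high_thr - min_gain) is skiptic;
#' everything else is neither. Thresholds are configurable; the defaults
#' (0.05 / 0.95 / 0.10) restate commonly used criteria rather than a value
#' fixed by the modelled study.
#'
#' @param results data.frame from [fit_usage()], cassette_exon rows only.
#' @param psi data.frame from [compute_psi()].
#' @param sheet sample sheet.
#' @param low_thr,high_thr,min_gain classification thresholds.
#' @return data.frame with event_id and label in {cryptic, skiptic, neither}.
#' @export
classify_cryptic_skiptic <- function(results, psi, sheet, low_thr = 0.05,
                                     high_thr = 0.95, min_gain = 0.10) {
  if (any(results$type != "cassette_exon")) {
    stop("classify_cryptic_skiptic accepts cassette_exon events only")
  }
  mut <- sheet$sample_id[sheet$genotype != "WT"]
  wt <- sheet$sample_id[sheet$genotype == "WT"]
  lab <- vapply(results$event_id, function(e) {
    pw <- psi$psi[psi$event_id == e & psi$sample_id %in% wt]
    pm <- psi$psi[psi$event_id == e & psi$sample_id %in% mut]
    mw <- mean(pw, na.rm = TRUE); mm <- mean(pm, na.rm = TRUE)
    if (is.nan(mw) || is.nan(mm)) return("neither")
    if (mw <= low_thr && mm >= low_thr + min_gain) return("cryptic")
    if (mw >= high_thr && mm <= high_thr - min_gain) return("skiptic")
    "neither"
  }, "", USE.NAMES = FALSE)
  data.frame(event_id = results$event_id, label = lab,
             stringsAsFactors = FALSE)
}
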