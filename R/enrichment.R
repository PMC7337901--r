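#' Partition gene models into genomic feature classes
#'
#' For every gene with an annotated CDS, produces labeled intervals:
#' \code{five_prime_utr}, \code{cds}, \code{intron} (any gap in the
#' transcript model between CDS and UTR coordinates),
#' \code{three_prime_utr_ext} (exactly 5 kb beyond the annotated 3' end,
#' clamped at contig bounds, to capture unannotated downstream sequence) and
#' \code{promoter_antisense} (5 kb upstream of the 5' UTR with the strand
#' inverted). Where transcripts of a gene disagree, precedence is
#' CDS > UTR > intron. UTR intervals are assigned to the 5' or 3' side by
#' overlap with annotated polyadenylation sites when \code{polya} is given,
#' otherwise by position relative to the CDS.
#'
#' @param models transcript models from [read_gtf()] or
#'   [simulate_annotation()].
#' @param polya optional interval data.frame of polyadenylation
#'   sites/signals.
#' @param contig_lengths named numeric of contig lengths for clamping.
#' @param flank extension length in bases (default 5000).
#' @return interval data.frame with columns gene_id and feature.
#' @export
build_partition <- function(models, polya = NULL, contig_lengths = NULL,
                            flank = 5000) {
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  rows <- list()
  for (gid in names(by_gene)) {
    txs <- by_gene[[gid]]
    txs <- Filter(function(m) !is.null(m$cds) && nrow(m$cds) > 0, txs)
    if (length(txs) == 0) {
      warning("gene ", gid, " has no CDS-bearing transcript; skipped")
      next
    }
    chrom <- txs[[1]]$chrom; strand <- txs[[1]]$strand
    ir <- function(df) IRanges::IRanges(start = df$start + 1, end = df$end)
    exon_u <- IRanges::reduce(do.call(c, lapply(txs, function(m) ir(m$exons))))
    cds_u <- IRanges::reduce(do.call(c, lapply(txs, function(m) ir(m$cds))))
    utr_u <- IRanges::setdiff(exon_u, cds_u)
    span <- IRanges::IRanges(min(IRanges::start(exon_u)),
                             max(IRanges::end(exon_u)))
    intron_u <- IRanges::setdiff(span, IRanges::union(exon_u, cds_u))
    cds_lo <- min(IRanges::start(cds_u)); cds_hi <- max(IRanges::end(cds_u))
    to_df <- function(r, feature, strand_out = strand) {
      if (length(r) == 0) return(NULL)
      data.frame(chrom = chrom, start = IRanges::start(r) - 1,
                 end = IRanges::end(r), strand = strand_out, gene_id = gid,
                 feature = feature, stringsAsFactors = FALSE)
    }
    # UTR side
    if (length(utr_u) > 0) {
      if (!is.null(polya) && nrow(polya) > 0) {
        pa <- polya[polya$chrom == chrom, , drop = FALSE]
        hit <- IRanges::overlapsAny(utr_u, ir(pa))
        side3 <- hit
      } else {
        mid <- (IRanges::start(utr_u) + IRanges::end(utr_u)) / 2
        side3 <- if (strand == "-") mid < cds_lo else mid > cds_hi
      }
      rows[[length(rows) + 1]] <- to_df(utr_u[!side3], "five_prime_utr")
      rows[[length(rows) + 1]] <- to_df(utr_u[side3], "three_prime_utr")
    }
    rows[[length(rows) + 1]] <- to_df(cds_u, "cds")
    rows[[length(rows) + 1]] <- to_df(intron_u, "intron")
    clen <- if (!is.null(contig_lengths) && chrom %in% names(contig_lengths)) {
      contig_lengths[[chrom]]
    } else Inf
    g_lo <- min(IRanges::start(exon_u)) - 1; g_hi <- max(IRanges::end(exon_u))
    if (strand == "-") {
      ext <- c(max(0, g_lo - flank), g_lo)
      prom <- c(g_hi, min(clen, g_hi + flank))
      prom_strand <- "+"
    } else {
      ext <- c(g_hi, min(clen, g_hi + flank))
      prom <- c(max(0, g_lo - flank), g_lo)
      prom_strand <- "-"
    }
    if (ext[2] > ext[1]) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = ext[1], end = ext[2], strand = strand,
        gene_id = gid, feature = "three_prime_utr_ext",
        stringsAsFactors = FALSE)
    }
    if (prom[2] > prom[1]) {
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = prom[1], end = prom[2], strand = prom_strand,
        gene_id = gid, feature = "promoter_antisense",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_intervals(out)
  out
}

#' Expression- and length-matched null feature set
#'
#' Candidate null features are those with no evidence of an effect
#' (raw p > p_threshold in both joint models) and not in the test set; they
#' are then restricted to features whose length and expression both lie
#' within the first and third quartile (closed bounds) of the test set's
#' values, removing the two main confounders of cluster overlap: longer
#' regions and more abundant RNA accumulate crosslink clusters by chance.
#'
#' @param test_ids feature ids of the test set.
#' @param model_a,model_b result data.frames (both joint models) with a
#'   feature id column and \code{p}.
#' @param lengths,expression named numeric maps over all features
#'   (expression = mean normalized read count in control samples).
#' @param p_threshold evidence threshold (default 0.05).
#' @return character vector of matched null feature ids.
#' @export
match_null <- function(test_ids, model_a, model_b, lengths, expression,
                       p_threshold = 0.05) {
  id_col <- intersect(c("event_id", "gene_id", "feature_id"),
                      names(model_a))[1]
  pa <- stats::setNames(model_a$p, model_a[[id_col]])
  pb <- stats::setNames(model_b$p, model_b[[id_col]])
  cand <- intersect(names(pa), names(pb))
  cand <- cand[!is.na(pa[cand]) & !is.na(pb[cand]) &
                 pa[cand] > p_threshold & pb[cand] > p_threshold]
  cand <- setdiff(cand, test_ids)
  lb <- stats::quantile(lengths[test_ids], c(0.25, 0.75), na.rm = TRUE)
  eb <- stats::quantile(expression[test_ids], c(0.25, 0.75), na.rm = TRUE)
  ok <- lengths[cand] >= lb[1] & lengths[cand] <= lb[2] &
    expression[cand] >= eb[1] & expression[cand] <= eb[2]
  null_ids <- cand[!is.na(ok) & ok]
  if (length(null_ids) == 0) {
    stop("no matched null features; relax the matching bounds")
  }
  if (length(null_ids) < length(test_ids)) {
    warning("matched null set (", length(null_ids),
            ") is smaller than the test set (", length(test_ids), ")")
  }
  null_ids
}

two_prop_chisq <- function(x1, n1, x2, n2) {
  # small-count approximation warnings are expected on tiny region sets and
  # carry no information the caller can act on
  pt <- suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
  list(chi2 = unname(pt$statistic), p = pt$p.value)
}

#' Cluster-overlap enrichment against a matched null
#'
#' A region counts as overlapping when at least one same-strand cluster
#' intersects it by at least one base. The test-set overlap proportion is
#' compared to the null set's with a two-proportion chi-squared test (no
#' continuity correction).
#'
#' @param test_regions,null_regions interval data.frames.
#' @param clusters interval data.frame of (pre-filtered) clusters.
#' @param test_name label carried into the result.
#' @return one-row data.frame: test_name, n_test, n_null, prop_test,
#'   prop_null, chi2, p.
#' @export
overlap_test <- function(test_regions, null_regions, clusters,
                         test_name = "overlap") {
  if (nrow(test_regions) == 0) stop("empty test region set")
  ht <- overlaps_any(test_regions, clusters)
  hn <- overlaps_any(null_regions, clusters)
  ct <- two_prop_chisq(sum(ht), length(ht), sum(hn), length(hn))
  data.frame(test_name = test_name, n_test = length(ht), n_null = length(hn),
             prop_test = mean(ht), prop_null = mean(hn), chi2 = ct$chi2,
             p = ct$p, stringsAsFactors = FALSE)
}

#' Per-feature-class binding profile for up/down gene sets
#'
#' Runs one [overlap_test()] per genomic feature class and direction
#' (upregulated: log2 fold change > 0; downregulated: < 0; zero effects are
#' assigned to neither) against the same feature class of the matched null
#' genes, with Bonferroni correction over the family of tests run.
#'
#' @param up_ids,down_ids,null_ids gene id vectors.
#' @param partition interval data.frame from [build_partition()].
#' @param clusters cluster intervals.
#' @return data.frame with one row per (feature, direction) plus
#'   p_bonferroni.
#' @export
feature_profile <- function(up_ids, down_ids, null_ids, partition, clusters) {
  sets <- list(up = up_ids, down = down_ids)
  out <- list()
  for (dir in names(sets)) {
    for (feat in unique(partition$feature)) {
      test_r <- partition[partition$gene_id %in% sets[[dir]] &
                            partition$feature == feat, , drop = FALSE]
      null_r <- partition[partition$gene_id %in% null_ids &
                            partition$feature == feat, , drop = FALSE]
      if (nrow(test_r) == 0 || nrow(null_r) == 0) next
      r <- overlap_test(test_r, null_r, clusters,
                        test_name = paste(feat, dir, sep = "_"))
      r$feature <- feat; r$direction <- dir
      out[[length(out) + 1]] <- r
    }
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res
}

weighted_median <- function(values, weights) {
  ok <- weights > 0
  values <- values[ok]; weights <- weights[ok]
  if (length(values) == 0) return(NA_real_)
  ord <- order(values)
  values <- values[ord]; weights <- weights[ord]
  cw <- cumsum(weights); half <- sum(weights) / 2
  i <- which(cw >= half)[1]
  if (abs(cw[i] - half) < 1e-9 && i < length(values)) {
    (values[i] + values[i + 1]) / 2
  } else {
    values[i]
  }
}

#' Median per-base conservation over regions
#'
#' Median of the per-base scores falling inside each region; bases without a
#' score are excluded (treated as missing, not zero, to avoid biasing sparse
#' tracks), and a region with no scored base is NA.
#'
#' @param regions interval data.frame.
#' @param scores non-overlapping scored intervals from [read_bedgraph()].
#' @return numeric vector, one median per region row.
#' @export
median_conservation <- function(regions, scores) {
  if (nrow(regions) == 0) return(numeric(0))
  rg <- intervals_to_granges(regions)
  sg <- intervals_to_granges(scores)
  hits <- GenomicRanges::findOverlaps(rg, sg, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  w <- pmin(regions$end[q], scores$end[s]) -
    pmax(regions$start[q], scores$start[s])
  out <- rep(NA_real_, nrow(regions))
  idx <- split(seq_along(q), q)
  for (nm in names(idx)) {
    sel <- idx[[nm]]
    out[as.integer(nm)] <- weighted_median(scores$score[s[sel]], w[sel])
  }
  out
}

#' Conservation enrichment against a matched null
#'
#' Compares the proportion of regions with median conservation strictly
#' above \code{threshold} (default 0.5: 0 is neutral, above 1 highly
#' conserved) between the test and null sets with a two-proportion
#' chi-squared test. Regions with no scored base are excluded from both
#' numerator and denominator.
#'
#' @param test_regions,null_regions interval data.frames.
#' @param scores scored intervals.
#' @param threshold median-score cutoff (strict >).
#' @param test_name label.
#' @return one-row data.frame as [overlap_test()].
#' @export
conservation_test <- function(test_regions, null_regions, scores,
                              threshold = 0.5, test_name = "conservation") {
  mt <- median_conservation(test_regions, scores)
  mn <- median_conservation(null_regions, scores)
  mt <- mt[!is.na(mt)]; mn <- mn[!is.na(mn)]
  if (length(mt) == 0 || length(mn) == 0) {
    stop("all region medians are NA; no scored bases")
  }
  ct <- two_prop_chisq(sum(mt > threshold), length(mt),
                       sum(mn > threshold), length(mn))
  data.frame(test_name = test_name, n_test = length(mt), n_null = length(mn),
             prop_test = mean(mt > threshold), prop_null = mean(mn > threshold),
             chi2 = ct$chi2, p = ct$p, stringsAsFactors = FALSE)
}

#' Cluster proximity flag per region
#'
#' \code{overlapping} when a same-strand cluster intersects the region;
#' otherwise \code{within_distance} when one lies within \code{distance}
#' bases of either region end; otherwise \code{none}.
#'
#' @param regions interval data.frame.
#' @param clusters cluster intervals.
#' @param distance window in bases (default 1000).
#' @return character vector per region row.
#' @export
proximity_flag <- function(regions, clusters, distance = 1000) {
  stopifnot(distance >= 0)
  direct <- overlaps_any(regions, clusters)
  widened <- regions
  widened$start <- pmax(0, regions$start - distance)
  widened$end <- regions$end + distance
  near <- overlaps_any(widened, clusters)
  ifelse(direct, "overlapping", ifelse(near, "within_distance", "none"))
}
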