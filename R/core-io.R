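#' Read a gene-level count matrix and its sample sheet
#'
#' The count file is a TSV whose first column holds gene identifiers and whose
#' header row holds sample identifiers; the sheet is a TSV with columns
#' \code{sample_id}, \code{dataset}, \code{genotype} (WT/HET/HOM) and
#' \code{arm} (KO/NLS). Every sample in the matrix must appear exactly once in
#' the sheet and counts must be non-negative integers.
#'
#' @param path path to the count TSV.
#' @param sheet_path path to the sample sheet TSV.
#' @return list with \code{counts} (integer matrix, genes x samples) and
#'   \code{sheet} (data.frame).
#' @export
read_counts <- function(path, sheet_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids in ", path)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("count at (%s, %s) is not a non-negative integer",
                 gene_ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  storage.mode(mat) <- "integer"
  rownames(mat) <- gene_ids
  sheet <- utils::read.delim(sheet_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  validate_sheet(sheet, sample_ids = colnames(mat))
  list(counts = mat, sheet = sheet[match(colnames(mat), sheet$sample_id), ,
                                   drop = FALSE])
}

#' Validate a sample sheet against a set of sample ids
#' @param sheet data.frame with sample_id, dataset, genotype, arm.
#' @param sample_ids sample ids that must each appear exactly once.
#' @export
validate_sheet <- function(sheet, sample_ids = sheet$sample_id) {
  need <- c("sample_id", "dataset", "genotype", "arm")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(sample_ids, sheet$sample_id)
  if (length(absent)) {
    stop(sprintf("sample '%s' present in count matrix but absent from sheet",
                 absent[1]))
  }
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample_id in sheet")
  if (!all(sheet$genotype %in% c("WT", "HET", "HOM"))) {
    stop("genotype must be one of WT, HET, HOM")
  }
  if (!all(sheet$arm %in% c("KO", "NLS"))) stop("arm must be KO or NLS")
  invisible(sheet)
}

#' Write a count matrix (genes x samples) as TSV
#' @param counts integer matrix with dimnames.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of clusters
#'
#' The score column is interpreted as the number of reads supporting a CLIP
#' cluster; rows with score below \code{min_score} are dropped (the cluster
#' filter applied before enrichment testing keeps clusters with at least two
#' supporting reads).
#'
#' @param path path to a BED6 file.
#' @param min_score optional minimum score; rows below it are dropped.
#' @return interval data.frame with \code{name} and \code{score} columns.
#' @export
read_bed <- function(path, min_score = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(genomic_intervals(character(), numeric(), numeric(), character(),
                             name = character(), score = numeric())[0, ])
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  if (any(n < 6)) stop("BED6 requires 6 fields (line ", which(n < 6)[1], ")")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.numeric(vapply(fields, `[[`, "", 2))
  end <- as.numeric(vapply(fields, `[[`, "", 3))
  name <- vapply(fields, `[[`, "", 4)
  score <- as.numeric(vapply(fields, `[[`, "", 5))
  strand <- vapply(fields, `[[`, "", 6)
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) stop(sprintf("invalid BED interval at line %d: end <= start",
                                bad[1]))
  keep <- if (is.null(min_score)) rep(TRUE, length(score)) else score >= min_score
  genomic_intervals(chrom[keep], start[keep], end[keep], strand[keep],
                    name = name[keep], score = score[keep])
}

#' Write intervals as BED6
#' @param x interval data.frame with optional name/score columns.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else sprintf("iv%d", seq_len(nrow(x)))
  score <- if ("score" %in% names(x)) x$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), name, format(score, trim = TRUE),
                   x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph track of per-base scores
#'
#' Used for per-nucleotide conservation (phyloP) scores, which may be
#' negative. Intervals must not overlap: a base with two scores would be
#' ambiguous.
#'
#' @param path path to a bedGraph file.
#' @return interval data.frame with a \code{score} column; strand is ".".
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 4)) {
    stop("bedGraph requires 4 fields (line ", which(lengths(fields) < 4)[1], ")")
  }
  chrom <- normalize_chrom(vapply(fields, `[[`, "", 1))
  start <- as.numeric(vapply(fields, `[[`, "", 2))
  end <- as.numeric(vapply(fields, `[[`, "", 3))
  score <- as.numeric(vapply(fields, `[[`, "", 4))
  bad <- which(is.na(start) | is.na(end) | end <= start | !is.finite(score))
  if (length(bad)) stop(sprintf("invalid bedGraph record at line %d", bad[1]))
  ord <- order(chrom, start)
  if (length(ord) > 1) {
    same <- chrom[ord][-1] == chrom[ord][-length(ord)]
    clash <- same & start[ord][-1] < end[ord][-length(ord)]
    if (any(clash)) {
      stop(sprintf("overlapping bedGraph intervals on chrom %s near base %d",
                   chrom[ord][which(clash)[1]], start[ord][which(clash)[1] + 1]))
    }
  }
  genomic_intervals(chrom, start, end, ".", score = score)
}

#' Write scored intervals as bedGraph
#' @param x interval data.frame with a \code{score} column.
#' @param path output path.
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x)
  writeLines(sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), format(x$score, trim = TRUE,
                                               digits = 12)), path)
  invisible(path)
}

# ---- GTF -------------------------------------------------------------------

parse_gtf_attributes <- function(attr, line_no) {
  m <- gregexpr('(\\w+) "([^"]*)"', attr)
  hits <- regmatches(attr, m)[[1]]
  if (length(hits) == 0) {
    stop(sprintf("unparseable GTF attribute block at line %d", line_no))
  }
  keys <- sub('^(\\w+) ".*', "\\1", hits)
  vals <- sub('^\\w+ "([^"]*)"$', "\\1", hits)
  stats::setNames(as.list(vals), keys)
}

#' Read transcript models from a GTF file
#'
#' GTF coordinates (1-based, closed) are converted to the package's 0-based
#' half-open convention on read. Transcripts carrying any tag in
#' \code{excluded_tags} are dropped; the annotation filter used ahead of the
#' genomic feature partition removes intron-retention, nonsense-mediated-decay
#' and cds-end-not-found transcript classes, whose UTR/CDS structure is
#' unreliable. Which attribute values encode those classes varies between
#' annotation releases, so the excluded set is an argument rather than a
#' constant. Exons extending outside the declared transcript span are clamped
#' with a warning.
#'
#' @param path path to a GTF file with transcript/exon/CDS features.
#' @param excluded_tags character vector of tag or transcript-type values; a
#'   transcript carrying any of them is dropped.
#' @return list of transcript models; each has \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{exons} and \code{cds}
#'   (data.frames of 0-based half-open start/end, 5'-to-3' on the genome) and
#'   \code{tags} (character vector).
#' @export
read_gtf <- function(path, excluded_tags = character()) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !grepl("^#", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) != 9)) {
    stop("GTF requires 9 tab-separated fields (line ",
         line_no[which(lengths(fields) != 9)[1]], ")")
  }
  rec <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    at <- parse_gtf_attributes(f[9], line_no[i])
    list(chrom = normalize_chrom(f[1]), feature = f[3],
         start = as.numeric(f[4]) - 1, end = as.numeric(f[5]),
         strand = f[7], attrs = at)
  })
  feats <- vapply(rec, `[[`, "", "feature")
  tx_ids <- vapply(rec, function(r) {
    id <- r$attrs[["transcript_id"]]
    if (is.null(id)) NA_character_ else id
  }, "")
  rec <- rec[!is.na(tx_ids) & feats %in% c("transcript", "exon", "CDS")]
  tx_ids <- tx_ids[!is.na(tx_ids) & feats %in% c("transcript", "exon", "CDS")]
  models <- lapply(split(rec, tx_ids), build_transcript_model)
  models <- unname(models[order(vapply(models, `[[`, "", "transcript_id"))])
  if (length(excluded_tags)) {
    drop <- vapply(models, function(m) any(m$tags %in% excluded_tags), TRUE)
    models <- models[!drop]
  }
  models
}

build_transcript_model <- function(recs) {
  feats <- vapply(recs, `[[`, "", "feature")
  first <- recs[[1]]
  tags <- unique(unlist(lapply(recs, function(r) {
    tg <- r$attrs[["tag"]]
    if (is.null(tg)) character() else strsplit(tg, ",")[[1]]
  })))
  span <- recs[feats == "transcript"]
  exons <- recs[feats == "exon"]
  if (length(exons) == 0) stop("transcript without exons: ",
                               first$attrs[["transcript_id"]])
  ex <- data.frame(start = vapply(exons, `[[`, 0, "start"),
                   end = vapply(exons, `[[`, 0, "end"))
  ex <- ex[order(ex$start), , drop = FALSE]
  if (length(span) == 1) {
    lo <- span[[1]]$start; hi <- span[[1]]$end
    if (any(ex$start < lo | ex$end > hi)) {
      warning(sprintf("exon outside declared span of %s; clamped",
                      first$attrs[["transcript_id"]]))
      ex$start <- pmax(ex$start, lo)
      ex$end <- pmin(ex$end, hi)
    }
  }
  if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
    stop("overlapping exons in transcript ", first$attrs[["transcript_id"]])
  }
  cds <- recs[feats == "CDS"]
  cds_df <- if (length(cds)) {
    d <- data.frame(start = vapply(cds, `[[`, 0, "start"),
                    end = vapply(cds, `[[`, 0, "end"))
    d[order(d$start), , drop = FALSE]
  } else NULL
  gid <- first$attrs[["gene_id"]]
  list(transcript_id = first$attrs[["transcript_id"]],
       gene_id = if (is.null(gid)) NA_character_ else gid,
       chrom = first$chrom, strand = first$strand,
       exons = ex, cds = cds_df, tags = tags)
}

#' Write transcript models as GTF
#' @param models list of transcript models (see [read_gtf()]).
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  fmt <- function(m, feature, start, end) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                     m$transcript_id)
    if (length(m$tags)) {
      attrs <- paste0(attrs, sprintf(' tag "%s";', paste(m$tags, collapse = ",")))
    }
    sprintf("%s\tjointlof\t%s\t%d\t%d\t.\t%s\t.\t%s", m$chrom, feature,
            as.integer(start) + 1L, as.integer(end), m$strand, attrs)
  }
  lines <- unlist(lapply(models, function(m) {
    span <- c(min(m$exons$start), max(m$exons$end))
    out <- fmt(m, "transcript", span[1], span[2])
    out <- c(out, mapply(function(s, e) fmt(m, "exon", s, e),
                         m$exons$start, m$exons$end))
    if (!is.null(m$cds)) {
      out <- c(out, mapply(function(s, e) fmt(m, "CDS", s, e),
                           m$cds$start, m$cds$end))
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- result tables ---------------------------------------------------------

#' Write a result table as TSV
#'
#' Numeric columns are serialized at 12 significant digits so a written table
#' re-reads to the same values; NA (including NA p-values for non-converged
#' fits) is written as "NA". An empty table produces a header-only file with a
#' warning.
#'
#' @param table a data.frame of results.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) warning("writing empty result table: ", path)
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v), "NA",
                  ifelse(v == round(v) & abs(v) < 1e15,
                         sprintf("%.0f", v), sprintf("%.12g", v)))
      out[[j]] <- s
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path path to the TSV.
#' @return data.frame with numeric columns restored.
#' @export
read_results <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}
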