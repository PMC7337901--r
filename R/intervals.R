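#' Genomic interval data model
#'
#' All intervals inside the package use the BED convention: 0-based start,
#' exclusive end, strand one of \code{"+"}, \code{"-"}, \code{"."}. Formats
#' that use other conventions (GTF) are converted at read time. Chromosome
#' names are normalized by stripping an optional \code{"chr"} prefix so that
#' UCSC- and ENSEMBL-style inputs can be mixed.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy \code{end > start}.
#' @param strand character vector in \code{c("+", "-", ".")}.
#' @param ... further equal-length columns carried along (e.g. \code{name},
#'   \code{score}, \code{gene_id}).
#' @return a data.frame with at least columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  df <- data.frame(
    chrom = rep_len(normalize_chrom(as.character(chrom)), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    ...,
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

#' @rdname genomic_intervals
#' @param x a data.frame of intervals.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end", "strand") %in% names(x)))
  if (any(x$start < 0)) stop("interval start must be >= 0")
  if (any(x$end <= x$start)) {
    bad <- which(x$end <= x$start)[1]
    stop(sprintf("interval end must exceed start (row %d: %s:%s-%s)",
                 bad, x$chrom[bad], x$start[bad], x$end[bad]))
  }
  if (!all(x$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(x)
}

#' Strip an optional "chr" prefix from chromosome names
#' @param x character vector.
#' @return character vector without the prefix.
#' @export
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Convert 0-based half-open intervals to a GRanges
#'
#' Used wherever overlap machinery is needed; the +1 shift to 1-based closed
#' coordinates happens only here.
#'
#' @param x interval data.frame (see [genomic_intervals()]).
#' @return a \code{GenomicRanges::GRanges}.
#' @export
intervals_to_granges <- function(x) {
  validate_intervals(x)
  strand <- ifelse(x$strand == ".", "*", x$strand)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

#' Strand-aware overlap indicator
#'
#' @param query,subject interval data.frames.
#' @param ignore_strand overlap regardless of strand when TRUE.
#' @return logical vector, one element per query row: does any same-strand
#'   subject interval intersect it by at least one base?
#' @export
overlaps_any <- function(query, subject, ignore_strand = FALSE) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  qg <- intervals_to_granges(query)
  sg <- intervals_to_granges(subject)
  IRanges::overlapsAny(qg, sg, ignore.strand = ignore_strand)
}
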