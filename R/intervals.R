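# Interval algebra shared by every annotation layer. All coordinates in this
# package are 0-based half-open [start, end); conversion to/from the 1-based
# closed conventions of GFF3 and IRanges happens only here and in the parsers.

#' Overlap width between two intervals
#'
#' Vectorised number of shared base pairs between interval `a` and interval
#' `b`, zero when the chromosomes differ or the intervals are disjoint.
#' Intervals are 0-based half-open.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end` (recycled
#'   row-wise against each other).
#' @return Integer vector of overlap widths in bp.
#' @examples
#' overlap_bp(
#'   data.frame(chrom = "chr1", start = 0, end = 100),
#'   data.frame(chrom = "chr1", start = 50, end = 150)
#' )
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ac <- rep_len(a$chrom, n); bc <- rep_len(b$chrom, n)
  as <- rep_len(a$start, n); bs <- rep_len(b$start, n)
  ae <- rep_len(a$end, n);   be <- rep_len(b$end, n)
  w <- pmin(ae, be) - pmax(as, bs)
  as.integer(ifelse(ac == bc, pmax(w, 0), 0L))
}

#' Overlap fraction relative to one interval
#'
#' @inheritParams overlap_bp
#' @param of Which interval's length is the denominator, `"a"` or `"b"`.
#' @return Numeric vector in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, of = c("a", "b")) {
  of <- match.arg(of)
  len <- if (of == "a") rep_len(a$end - a$start, max(nrow(a), nrow(b)))
         else rep_len(b$end - b$start, max(nrow(a), nrow(b)))
  overlap_bp(a, b) / len
}

# GRanges view of an interval tibble (1-based closed internally to IRanges).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Index pairs (a_idx, b_idx) of intervals overlapping by >= min_bp.
overlap_pairs <- function(a, b, min_bp = 1L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble(a_idx = integer(), b_idx = integer()))
  }
  hits <- GenomicRanges::findOverlaps(
    as_granges(a), as_granges(b),
    minoverlap = as.integer(min_bp), ignore.strand = TRUE
  )
  tibble(a_idx = S4Vectors::queryHits(hits), b_idx = S4Vectors::subjectHits(hits))
}

# For each row of `a`, the edge-to-edge distance to the nearest row of `b`
# on the same chromosome (0 when overlapping; NA when no candidate).
nearest_distance <- function(a, b) {
  out <- rep(NA_real_, nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  hits <- GenomicRanges::distanceToNearest(as_granges(a), as_granges(b))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

stopifnot_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

validate_intervals <- function(df, what = "interval table",
                               chrom_sizes = NULL) {
  stopifnot_cols(df, c("chrom", "start", "end"), what)
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0)) stop(what, ": negative coordinate", call. = FALSE)
  if (any(df$start >= df$end)) stop(what, ": start >= end", call. = FALSE)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(df$chrom), chrom_sizes$chrom)
    if (length(unknown)) {
      stop(what, ": unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  invisible(df)
}
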