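#' Genomic interval (1-based, inclusive)
#'
#' The unit of all mapping output.  `start` and `end` are base-pair positions
#' on `chrom`, both included in the span, so a single base has
#' `start == end` and length 1 bp.
#'
#' @param chrom Chromosome name.
#' @param start First base of the span (>= 1).
#' @param end Last base of the span (>= start).
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("3", 70468129, 70487067)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid interval: need 1 <= start <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' The empty interval
#'
#' Marker value returned by [interval_intersect()] when two intervals do not
#' overlap.
#' @return An object of class `genomic_interval` that is empty.
#' @export
empty_interval <- function() {
  structure(list(chrom = NA_character_, start = NA_real_, end = NA_real_),
            class = c("empty_interval", "genomic_interval"))
}

#' Test whether an interval is empty
#' @param x A `genomic_interval`.
#' @export
is_empty_interval <- function(x) inherits(x, "empty_interval")

#' @export
print.genomic_interval <- function(x, ...) {
  if (is_empty_interval(x)) {
    cat("<empty interval>\n")
  } else {
    cat(sprintf("%s:%s-%s (%.1f kb)\n", x$chrom,
                format(x$start, big.mark = ",", scientific = FALSE),
                format(x$end, big.mark = ",", scientific = FALSE),
                interval_length_kb(x)))
  }
  invisible(x)
}

#' Interval length in base pairs
#' @param interval A `genomic_interval`.
#' @return `end - start + 1`, or 0 for the empty interval.
#' @export
interval_length_bp <- function(interval) {
  if (is_empty_interval(interval)) return(0)
  interval$end - interval$start + 1
}

#' Interval length in kilobases, rounded half-up to one decimal
#'
#' This is the convention used to report region sizes (e.g. a span of
#' 70,468,129-70,487,067 bp is 18.9 kb).
#'
#' @param interval A `genomic_interval`.
#' @return Length in kb, one decimal place.
#' @export
interval_length_kb <- function(interval) {
  kb <- interval_length_bp(interval) / 1000
  floor(kb * 10 + 0.5) / 10    # round half-up, not banker's rounding
}

#' Intersect two genomic intervals
#'
#' @param a,b `genomic_interval` objects.
#' @return Their overlap as a `genomic_interval`, or [empty_interval()] if they
#'   are on different chromosomes or disjoint.
#' @examples
#' interval_intersect(genomic_interval("3", 70201106, 70581126),
#'                    genomic_interval("3", 70399176, 70988264))
#' @export
interval_intersect <- function(a, b) {
  if (is_empty_interval(a) || is_empty_interval(b)) return(empty_interval())
  if (a$chrom != b$chrom) return(empty_interval())
  s <- max(a$start, b$start)
  e <- min(a$end, b$end)
  if (s > e) return(empty_interval())
  genomic_interval(a$chrom, s, e)
}

#' Write intervals to a BED file
#'
#' Internal coordinates are 1-based inclusive; BED records are 0-based
#' half-open, so each interval is written as `chrom, start - 1, end`.
#' Reading the file back with [read_bed()] restores the intervals exactly.
#'
#' @param intervals A list of `genomic_interval` objects (empty intervals are
#'   skipped).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  keep <- Filter(Negate(is_empty_interval), intervals)
  df <- data.frame(
    chrom = vapply(keep, function(x) x$chrom, character(1)),
    start = vapply(keep, function(x) x$start - 1, numeric(1)),
    end = vapply(keep, function(x) x$end, numeric(1))
  )
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED file as 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return A list of `genomic_interval` objects.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0) return(list())
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric"))
  lapply(seq_len(nrow(df)), function(i)
    genomic_interval(df[i, 1], df[i, 2] + 1, df[i, 3]))
}
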