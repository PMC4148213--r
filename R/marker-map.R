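#' Construct a marker map
#'
#' An ordered physical map of genotyped markers.  Positions must be unique
#' within a chromosome and marker ids unique overall; markers are stored
#' sorted by (chrom, position).
#'
#' @param marker Character vector of marker ids.
#' @param chrom Chromosome of each marker.
#' @param pos 1-based bp position of each marker.
#' @return A `data.frame` of class `marker_map` with columns
#'   `marker`, `chrom`, `pos`.
#' @export
marker_map <- function(marker, chrom, pos) {
  df <- data.frame(marker = as.character(marker),
                   chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("no markers")
  if (anyDuplicated(df$marker)) stop("duplicate marker ids")
  if (anyDuplicated(df[c("chrom", "pos")])) stop("duplicate marker positions")
  ord <- order(df$chrom, df$pos)
  if (is.unsorted(ord)) message("marker map was unsorted; sorting by position")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read a marker map from disk
#'
#' @param path File path.
#' @param format `"tsv"` for a headered table with columns `marker`, `chrom`,
#'   `pos` (aliases `id`/`snp` and `position`/`position_bp` accepted), or
#'   `"plink_map"` for a PLINK `.map` file (chrom, id, cM, bp).
#' @return A [marker_map()].
#' @export
read_marker_map <- function(path, format = c("tsv", "plink_map")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                 comment.char = "#"),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e)))
    if (nrow(df) == 0) stop("no markers")
    names(df) <- tolower(names(df))
    id_col <- intersect(c("marker", "id", "snp"), names(df))[1]
    pos_col <- intersect(c("pos", "position", "position_bp"), names(df))[1]
    if (is.na(id_col) || is.na(pos_col) || !"chrom" %in% names(df))
      stop("marker map needs columns marker/id, chrom, pos/position")
    pos <- suppressWarnings(as.numeric(gsub(",", "", df[[pos_col]])))
    if (anyNA(pos))
      stop("malformed position at line ", which(is.na(pos))[1] + 1L)
    marker_map(df[[id_col]], df$chrom, pos)
  } else {
    df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) == 0) stop("no markers")
    if (ncol(df) < 4) stop("PLINK .map needs 4 columns: chrom id cM bp")
    marker_map(df[[2]], df[[1]], df[[4]])
  }
}

#' Subset a marker map to an interval
#'
#' @param map A [marker_map()].
#' @param interval A [genomic_interval()]; both endpoints inclusive.
#' @return The markers lying within the interval, as a `marker_map` (or an
#'   empty data.frame when none do).
#' @export
markers_in_interval <- function(map, interval) {
  keep <- map$chrom == interval$chrom &
    map$pos >= interval$start & map$pos <= interval$end
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
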