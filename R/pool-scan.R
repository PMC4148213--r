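# Pooled-sequencing fixation scan: in a DNA pool of affected birds the
# causal haplotype region shows variant allele frequency ~1 at every
# segregating site, so extended runs of fixed sites mark the IBD haplotype.

#' Per-site variant allele frequency from pooled counts
#'
#' `vaf = alt / (alt + ref)` at sites with total coverage at or above
#' `min_coverage`; lower-coverage sites are flagged undefined (not treated
#' as frequency 0).
#'
#' @param counts A [pool_site_counts()].
#' @param min_coverage Coverage floor (reads) below which the VAF is
#'   undefined.
#' @return `counts` with columns `coverage`, `vaf` (`NA` where undefined)
#'   and `defined` added.
#' @export
site_vaf <- function(counts, min_coverage = 4) {
  total <- counts$ref + counts$alt
  vaf <- ifelse(total >= min_coverage, counts$alt / total, NA_real_)
  out <- counts
  out$coverage <- total
  out$vaf <- vaf
  out$defined <- !is.na(vaf)
  out
}

#' Detect runs of sites fixed for the variant allele
#'
#' Maximal runs of consecutive defined-VAF sites with
#' `vaf >= fixation_threshold`.  Undefined (low-coverage) sites are skipped
#' and never break a run.  `max_gap_sites` defined failing sites are
#' tolerated between consecutive passing sites; runs with fewer than
#' `min_sites` passing sites are dropped.  Run intervals span the first to
#' the last passing site.
#'
#' @param vaf_table Output of [site_vaf()].
#' @param fixation_threshold Minimum VAF for a site to count as fixed.  The
#'   default 0.95 tolerates pooled-sequencing error; set 1.0 for the strict
#'   reading of fixation.
#' @param min_sites Minimum passing sites per reported run.
#' @param max_gap_sites Defined failing sites tolerated between consecutive
#'   passing sites within a run.
#' @return A `data.frame` with one row per run: `start`, `end` (bp of first
#'   and last passing site), `n_sites` (passing sites), `mean_vaf`,
#'   `min_coverage`, ordered and disjoint.
#' @export
fixed_runs <- function(vaf_table, fixation_threshold = 0.95, min_sites = 5,
                       max_gap_sites = 0) {
  dft <- vaf_table[vaf_table$defined, , drop = FALSE]
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_sites = integer(0), mean_vaf = numeric(0),
                      min_coverage = integer(0))
  if (nrow(dft) == 0) return(empty)
  pass <- dft$vaf >= fixation_threshold
  pidx <- which(pass)
  if (length(pidx) == 0) return(empty)

  # chain consecutive passing sites whose interior gap (failing defined
  # sites) does not exceed max_gap_sites
  gap <- diff(pidx) - 1L
  brk <- c(0L, cumsum(gap > max_gap_sites))
  runs <- split(pidx, brk)
  runs <- Filter(function(r) length(r) >= min_sites, runs)
  if (length(runs) == 0) return(empty)
  do.call(rbind, lapply(runs, function(r) {
    span <- seq(r[1], r[length(r)])
    data.frame(start = dft$pos[r[1]],
               end = dft$pos[r[length(r)]],
               n_sites = length(r),
               mean_vaf = mean(dft$vaf[span]),
               min_coverage = min(dft$coverage[span]),
               row.names = NULL)
  }))
}
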