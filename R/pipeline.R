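#' Run the full IBD fine-mapping pipeline
#'
#' Composes the fine-mapping chain: shared-homozygosity block finding in the
#' cases, control-exclusion of blocks, boundary narrowing with an extended
#' case panel, then variant exclusion filtering and complete-association
#' tabulation of any retained variant.  The report records each narrowing
#' step with its interval and kb length.
#'
#' @param cases,controls [genotype_matrix()] objects (or one matrix holding
#'   both, with phenotype labels) typed on `map`.
#' @param extended_panel Optional [genotype_matrix()] of additional case
#'   individuals for [narrow_boundaries()].
#' @param variants Optional [genotype_matrix()] of candidate variants (its
#'   own map) with phenotype labels, for [variant_exclusion_filter()].
#' @param map A [marker_map()] for `cases`/`controls` (taken from `cases`
#'   when it carries one).
#' @param missing_policy,max_case_exceptions Passed to
#'   [shared_homozygous_blocks()].
#' @return A list of class `ibd_report`: `steps` (data.frame of step name,
#'   interval, kb), `blocks`, `surviving`, `interval` (the final candidate
#'   interval, empty when no block survives), `narrowing`, `variant_filter`,
#'   `association`.
#' @export
run_ibd_pipeline <- function(cases, controls = NULL, extended_panel = NULL,
                             variants = NULL, map = NULL,
                             missing_policy = "compatible",
                             max_case_exceptions = 0) {
  if (is.null(map) && inherits(cases, "genotype_matrix")) map <- cases$map
  blocks <- shared_homozygous_blocks(cases, map,
                                     missing_policy = missing_policy,
                                     max_case_exceptions = max_case_exceptions)
  if (!is.null(controls)) blocks <- exclude_control_matches(blocks, controls)
  surviving <- Filter(function(b) length(b$excluded_by) == 0, blocks)

  step_row <- function(step, interval) {
    data.frame(step = step,
               interval = if (is_empty_interval(interval)) "-" else
                 sprintf("%s:%.0f-%.0f", interval$chrom, interval$start,
                         interval$end),
               kb = interval_length_kb(interval), stringsAsFactors = FALSE)
  }
  steps <- step_row("map extent",
                    genomic_interval(map$chrom[1], min(map$pos), max(map$pos)))
  for (b in blocks) steps <- rbind(steps, step_row(
    if (length(b$excluded_by)) "shared block (excluded by controls)"
    else "shared block", b$interval))

  narrowing <- NULL
  if (length(surviving) == 0) {
    final <- empty_interval()
  } else {
    best <- surviving[[which.max(vapply(surviving, function(b)
      interval_length_bp(b$interval), numeric(1)))]]
    final <- best$interval
    if (!is.null(extended_panel)) {
      narrowing <- narrow_boundaries(best, extended_panel, map)
      final <- narrowing$interval
      steps <- rbind(steps, step_row("het-narrowed candidate region", final))
    } else {
      steps <- rbind(steps, step_row("surviving shared block", final))
    }
  }

  filt <- NULL
  assoc <- NULL
  if (!is.null(variants) && !is_empty_interval(final)) {
    filt <- variant_exclusion_filter(variants)
    if (!is.null(variants$map) && "pos" %in% names(filt)) {
      inside <- filt$pos >= final$start & filt$pos <= final$end
      filt$in_candidate_region <- inside
    }
    kept <- which(filt$retained)
    if (length(kept) >= 1) {
      j <- kept[1]
      assoc <- association_table(variants$geno[, j],
                                 variants$individuals$phenotype,
                                 variants$individuals$population)
    }
  }
  structure(list(steps = steps, blocks = blocks, surviving = surviving,
                 interval = final, narrowing = narrowing,
                 variant_filter = filt, association = assoc),
            class = "ibd_report")
}

#' @export
print.ibd_report <- function(x, ...) {
  cat("IBD fine-mapping report\n")
  print(x$steps, row.names = FALSE)
  if (is_empty_interval(x$interval)) {
    cat("no surviving shared block: cases share no exclusive haplotype\n")
  } else {
    cat("candidate region: ")
    print(x$interval)
  }
  if (!is.null(x$variant_filter))
    cat(sprintf("variants: %d tested, %d retained\n",
                nrow(x$variant_filter), sum(x$variant_filter$retained)))
  if (!is.null(x$association))
    cat(sprintf("complete association at retained variant: %s\n",
                x$association$complete_association))
  invisible(x)
}
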