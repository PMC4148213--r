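# Identical-by-descent fine mapping: a recessive causal allele makes every
# affected bird autozygous around the locus, so the haplotype shared
# homozygously by all cases -- and carried by no control -- brackets the
# mutation.  Haplotypes are read directly from homozygous calls (genotypes
# are unphased; autozygosity makes the shared haplotype visible without
# phasing).

.case_rows <- function(gm) {
  if (inherits(gm, "genotype_matrix")) {
    ph <- gm$individuals$phenotype
    if (any(ph == "case")) return(gm$geno[ph == "case", , drop = FALSE])
    return(gm$geno)
  }
  as.matrix(gm)
}

# Shared-homozygosity state of one marker column across cases.
# Returns list(shared, allele, support, witness).
.marker_shared <- function(calls, missing_policy, max_exceptions) {
  obs <- calls[!is.na(calls)]
  if (missing_policy == "breaking" && anyNA(calls))
    return(list(shared = FALSE, allele = NA_integer_, support = 0L))
  if (length(obs) == 0)  # no data: compatible with any haplotype
    return(list(shared = missing_policy == "compatible",
                allele = NA_integer_, support = 0L))
  n0 <- sum(obs == 0L)
  n2 <- sum(obs == 2L)
  if (n0 == 0 && n2 == 0)
    return(list(shared = FALSE, allele = NA_integer_, support = 0L))
  allele <- if (n2 >= n0) 2L else 0L
  violations <- sum(obs != allele)
  list(shared = violations <= max_exceptions, allele = allele,
       support = sum(obs == allele))
}

#' Find haplotype blocks shared homozygously by all cases
#'
#' Maximal runs of consecutive markers at which every case is homozygous for
#' one common allele.  Under `missing_policy = "compatible"` (default) a
#' missing cell does not break a run but contributes no support; under
#' `"breaking"` any missing cell breaks sharing at that marker.
#' `max_case_exceptions` allows that many discordant cases per marker before
#' sharing breaks (default 0: a single heterozygous case breaks the run).
#'
#' @param cases A [genotype_matrix()] (rows labelled `case` are used; if no
#'   row is labelled, all rows are treated as cases) or a plain 0/1/2/`NA`
#'   matrix of case genotypes.
#' @param map A [marker_map()] matching the genotype columns (taken from
#'   `cases` when it carries one).
#' @param missing_policy `"compatible"` or `"breaking"`.
#' @param max_case_exceptions Discordant cases tolerated per marker.
#' @return A list of `shared_block` objects, in map order.  Each has
#'   `interval` (span of first to last marker), `marker_indices`,
#'   `shared_alleles` (per-marker code, `NA` where no case was typed),
#'   `n_supporting_cases` (minimum per-marker concordant case count over the
#'   allele-defined markers) and `excluded_by` (`NULL` until
#'   [exclude_control_matches()]).
#' @export
shared_homozygous_blocks <- function(cases, map = NULL,
                                     missing_policy = c("compatible",
                                                        "breaking"),
                                     max_case_exceptions = 0) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(map) && inherits(cases, "genotype_matrix")) map <- cases$map
  geno <- .case_rows(cases)
  if (nrow(geno) < 1) stop("need at least one case")
  if (is.null(map)) stop("a marker map is required")
  if (ncol(geno) != nrow(map)) stop("genotypes do not match the marker map")

  st <- lapply(seq_len(ncol(geno)), function(j)
    .marker_shared(geno[, j], missing_policy, max_case_exceptions))
  shared <- vapply(st, `[[`, logical(1), "shared")

  r <- rle(shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    alleles <- vapply(st[idx], `[[`, integer(1), "allele")
    supp <- vapply(st[idx], `[[`, integer(1), "support")
    defined <- !is.na(alleles)
    structure(list(
      interval = genomic_interval(map$chrom[idx[1]], map$pos[idx[1]],
                                  map$pos[idx[length(idx)]]),
      marker_indices = idx,
      shared_alleles = setNames(alleles, map$marker[idx]),
      n_supporting_cases = if (any(defined)) min(supp[defined]) else 0L,
      excluded_by = NULL),
      class = "shared_block")
  })
}

#' @export
print.shared_block <- function(x, ...) {
  cat(sprintf("shared block over %d markers, ", length(x$marker_indices)))
  print(x$interval)
  if (length(x$excluded_by))
    cat("  excluded by control(s): ", paste(x$excluded_by, collapse = ", "),
        "\n")
  invisible(x)
}

#' Exclude shared blocks carried homozygously by a control
#'
#' A block is marked excluded iff at least one control is homozygous for the
#' shared allele at every marker of the block where it has a call (and has a
#' call at at least one allele-defined marker).  A control that is
#' heterozygous anywhere in the block does not match.
#'
#' @param blocks Output of [shared_homozygous_blocks()].
#' @param controls A [genotype_matrix()] (rows labelled `control` are used;
#'   all rows if none is labelled) or a plain matrix, typed on the same map.
#' @return `blocks` with `excluded_by` populated with matching control ids.
#' @export
exclude_control_matches <- function(blocks, controls) {
  geno <- if (inherits(controls, "genotype_matrix")) {
    ph <- controls$individuals$phenotype
    if (any(ph == "control")) controls$geno[ph == "control", , drop = FALSE]
    else controls$geno
  } else as.matrix(controls)
  if (nrow(geno) == 0) return(blocks)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- sprintf("control_%d", seq_len(nrow(geno)))
  lapply(blocks, function(b) {
    idx <- b$marker_indices[!is.na(b$shared_alleles)]
    al <- b$shared_alleles[!is.na(b$shared_alleles)]
    matches <- vapply(seq_len(nrow(geno)), function(i) {
      calls <- geno[i, idx]
      ok <- !is.na(calls)
      any(ok) && all(calls[ok] == al[ok])
    }, logical(1))
    b$excluded_by <- ids[matches]
    b
  })
}

#' Narrow a shared block's boundaries with an extended case panel
#'
#' Additional affected individuals typed at the block's markers refine the
#' boundaries: any panel case that is heterozygous (or homozygous for the
#' non-shared allele) at a marker excludes that marker from the shared
#' haplotype.  The returned interval is boundary-exclusive: it starts 1 bp
#' inside the proximal boundary marker and ends 1 bp inside the distal one
#' (a het boundary at 70,460,738 bp puts the candidate region start at
#' 70,460,739 bp).  A side with no discordant marker keeps the block
#' endpoint and is flagged open.
#'
#' @param block A `shared_block` from [shared_homozygous_blocks()].
#' @param extended_panel [genotype_matrix()] or matrix of additional case
#'   individuals typed on the same map.
#' @param map The [marker_map()] the block indices refer to.
#' @param which_run When discordant interior markers split the block,
#'   `"longest"` keeps the longest concordant run (first on ties);
#'   `"all"` is available through the `runs` element of the result.
#' @return A list: `interval`, `proximal_closed`, `distal_closed`,
#'   `boundary_markers` (ids or `NA`), `runs` (all concordant marker-index
#'   runs, for cross-checking).
#' @export
narrow_boundaries <- function(block, extended_panel, map,
                              which_run = "longest") {
  geno <- .case_rows(extended_panel)
  idx <- block$marker_indices
  al <- block$shared_alleles
  discordant <- vapply(seq_along(idx), function(k) {
    if (is.na(al[k])) return(FALSE)
    calls <- geno[, idx[k]]
    any(!is.na(calls) & calls != al[k])
  }, logical(1))

  r <- rle(!discordant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- lapply(which(r$values), function(k) idx[starts[k]:ends[k]])
  if (length(runs) == 0)
    return(list(interval = empty_interval(), proximal_closed = TRUE,
                distal_closed = TRUE,
                boundary_markers = list(proximal = NA, distal = NA),
                runs = runs))
  run <- runs[[which.max(lengths(runs))]]

  left_bound <- run[1] - 1L
  right_bound <- run[length(run)] + 1L
  prox_closed <- left_bound %in% idx[discordant]
  dist_closed <- right_bound %in% idx[discordant]
  start <- if (prox_closed) map$pos[left_bound] + 1 else block$interval$start
  end <- if (dist_closed) map$pos[right_bound] - 1 else block$interval$end
  list(interval = genomic_interval(map$chrom[run[1]], start, end),
       proximal_closed = prox_closed,
       distal_closed = dist_closed,
       boundary_markers = list(
         proximal = if (prox_closed) map$marker[left_bound] else NA,
         distal = if (dist_closed) map$marker[right_bound] else NA),
       runs = runs)
}
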