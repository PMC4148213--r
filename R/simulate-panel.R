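#' Configuration for a case/control breed-panel simulation
#'
#' Emulates a fine-mapping panel in which every affected bird carries two
#' copies of one ancestral haplotype over `shared_interval`, eroded at each
#' edge by historical recombination, while controls and the genome outside
#' the interval follow Hardy-Weinberg draws from per-marker background
#' frequencies.  Defaults follow the study design the pipeline targets:
#' 76 affected and 95 wild-type birds typed on 34 SNPs around a ~57 kb
#' candidate region.
#'
#' @param n_cases,n_controls Panel sizes.
#' @param n_markers Number of SNPs, evenly spaced across `region`.
#' @param region [genomic_interval()] covered by the marker map.
#' @param shared_interval [genomic_interval()] planted identical-by-descent
#'   in every case; must lie within `region`.
#' @param causal_pos Position of the hidden causal variant (inside
#'   `shared_interval`).
#' @param erosion_cM Mean exponential erosion of the shared haplotype at each
#'   edge, per case per side, in cM.  0 disables erosion.
#' @param cm_per_mb Genetic-to-physical scaling for the erosion draws.
#' @param background_freq Per-marker alternate-allele frequencies in `[0,1]`
#'   (`NULL`: drawn uniformly from `[0.2, 0.8]`).
#' @param seed Integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_cases = 76, n_controls = 95, n_markers = 34,
                         region = genomic_interval("3", 70400000, 70560000),
                         shared_interval = genomic_interval("3", 70447648,
                                                            70504365),
                         causal_pos = 70486623, erosion_cM = 0.005,
                         cm_per_mb = 3, background_freq = NULL, seed = NULL) {
  stopifnot(n_cases >= 1, n_controls >= 0, n_markers >= 2, erosion_cM >= 0)
  if (shared_interval$chrom != region$chrom ||
      shared_interval$start < region$start ||
      shared_interval$end > region$end)
    stop("shared interval outside map extent")
  if (causal_pos < shared_interval$start || causal_pos > shared_interval$end)
    stop("causal position outside the shared interval")
  if (!is.null(background_freq) &&
      (length(background_freq) != n_markers ||
       any(background_freq < 0 | background_freq > 1)))
    stop("background_freq must be n_markers frequencies in [0,1]")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_markers = n_markers, region = region,
                 shared_interval = shared_interval, causal_pos = causal_pos,
                 erosion_cM = erosion_cM, cm_per_mb = cm_per_mb,
                 background_freq = background_freq, seed = seed),
            class = "panel_config")
}

#' Simulate a case/control breed panel with a planted IBD haplotype
#'
#' Every case is homozygous for the ancestral (alternate, code 2) allele at
#' all markers inside `shared_interval` minus an edge erosion drawn per case
#' per side (exponential in genetic distance); everywhere else, and in
#' controls throughout, genotypes are Hardy-Weinberg draws from the
#' background frequencies.  The innermost eroded boundaries across cases
#' define the recoverable truth, returned alongside the genotypes.
#'
#' @param config A [panel_config()].
#' @return A list with elements:
#'   \item{genotypes}{[genotype_matrix()] of cases (phenotype `case`) and
#'     controls (`control`).}
#'   \item{truth}{List: `interval` (recoverable shared interval after
#'     erosion; empty if erosion consumed it), `causal_pos`, `shared_code`
#'     (always 2).}
#' @export
simulate_breed_panel <- function(config = panel_config())
  with_seed(config$seed, {
  reg <- config$region
  shi <- config$shared_interval
  m <- config$n_markers
  pos <- round(seq(reg$start, reg$end, length.out = m))
  p <- config$background_freq
  if (is.null(p)) p <- runif(m, 0.2, 0.8)

  hwe_draw <- function(n) {
    matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  }

  bp_per_cM <- 1e6 / config$cm_per_mb
  erode <- function(n) {
    if (config$erosion_cM == 0) numeric(n)
    else rexp(n, rate = 1 / config$erosion_cM) * bp_per_cM
  }
  dl <- erode(config$n_cases)
  dr <- erode(config$n_cases)

  cases <- hwe_draw(config$n_cases)
  for (i in seq_len(config$n_cases)) {
    inside <- pos >= shi$start + dl[i] & pos <= shi$end - dr[i]
    cases[i, inside] <- 2L
  }
  controls <- if (config$n_controls > 0) hwe_draw(config$n_controls)
              else matrix(integer(0), 0, m)

  truth_start <- shi$start + max(dl)
  truth_end <- shi$end - max(dr)
  truth_int <- if (truth_start <= truth_end)
    genomic_interval(reg$chrom, truth_start, truth_end) else empty_interval()

  mm <- marker_map(sprintf("P%02d", seq_len(m)), reg$chrom, pos)
  ind <- data.frame(
    id = c(sprintf("case_%03d", seq_len(config$n_cases)),
           if (config$n_controls > 0)
             sprintf("ctrl_%03d", seq_len(config$n_controls))),
    phenotype = c(rep("case", config$n_cases),
                  rep("control", config$n_controls)),
    population = c(rep("silky", config$n_cases),
                   rep("wildtype", config$n_controls)),
    stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(rbind(cases, controls), ind, mm),
       truth = list(interval = truth_int, causal_pos = config$causal_pos,
                    shared_code = 2L),
       config = config)
})
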