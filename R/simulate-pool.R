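#' Per-site read counts from a DNA pool
#'
#' @param pos Strictly increasing bp positions.
#' @param ref,alt Non-negative read counts per site.
#' @param pool_size Number of individuals in the pool.
#' @param chrom Chromosome name.
#' @return A `data.frame` of class `pool_site_counts` with columns
#'   `pos`, `ref`, `alt`.
#' @export
pool_site_counts <- function(pos, ref, alt, pool_size = NA_integer_,
                             chrom = "3") {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  if (any(ref < 0 | alt < 0)) stop("read counts must be non-negative")
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
  df <- data.frame(pos = as.numeric(pos), ref = as.integer(ref),
                   alt = as.integer(alt))
  attr(df, "pool_size") <- pool_size
  attr(df, "chrom") <- chrom
  class(df) <- c("pool_site_counts", "data.frame")
  df
}

#' Configuration for a pooled-sequencing simulation
#'
#' Emulates whole-genome sequencing of a pool of affected birds over a
#' mapped region: segregating sites with background allele frequencies drawn
#' from a low-to-moderate (Beta) site-frequency distribution, plus one
#' planted interval where the variant allele is fixed in the pool.
#' Defaults follow the study scale: 15 pooled birds, mean coverage 20, a
#' ~22 kb fixed haplotype inside a 182 kb region.
#'
#' @param n_sites Number of segregating sites, placed uniformly at random.
#' @param region [genomic_interval()] scanned.
#' @param fixed_interval [genomic_interval()] where the variant allele
#'   frequency is 1 in the pool.
#' @param mean_coverage Mean reads per site (Poisson).
#' @param bg_shape1,bg_shape2 Beta parameters of the background variant
#'   allele frequency distribution.
#' @param pool_size Individuals in the pool.
#' @param seed Integer seed.
#' @return A list of class `pool_config`.
#' @export
pool_config <- function(n_sites = 500,
                        region = genomic_interval("3", 70399176, 70581126),
                        fixed_interval = genomic_interval("3", 70467293,
                                                          70489020),
                        mean_coverage = 20, bg_shape1 = 2, bg_shape2 = 5,
                        pool_size = 15, seed = NULL) {
  stopifnot(n_sites >= 1, mean_coverage > 0, bg_shape1 > 0, bg_shape2 > 0)
  structure(list(n_sites = n_sites, region = region,
                 fixed_interval = fixed_interval,
                 mean_coverage = mean_coverage, bg_shape1 = bg_shape1,
                 bg_shape2 = bg_shape2, pool_size = pool_size, seed = seed),
            class = "pool_config")
}

#' Simulate pooled read counts over segregating sites
#'
#' Per site, coverage is Poisson(`mean_coverage`) and alternate reads are
#' Binomial(coverage, site frequency); sites inside `fixed_interval` have
#' frequency 1, all others draw a background frequency from
#' Beta(`bg_shape1`, `bg_shape2`).  Zero-coverage sites are retained (their
#' frequency is simply unobserved — see [site_vaf()]).
#'
#' @param config A [pool_config()].
#' @return A [pool_site_counts()] with attributes `truth` (the planted fixed
#'   interval) and `freq` (the true per-site frequencies).
#' @export
simulate_pool_counts <- function(config = pool_config())
  with_seed(config$seed, {
  reg <- config$region
  pos <- sort(sample(seq(reg$start, reg$end), config$n_sites))
  freq <- rbeta(config$n_sites, config$bg_shape1, config$bg_shape2)
  fx <- config$fixed_interval
  inside <- pos >= fx$start & pos <= fx$end
  freq[inside] <- 1
  cov <- rpois(config$n_sites, config$mean_coverage)
  alt <- rbinom(config$n_sites, cov, freq)
  out <- pool_site_counts(pos, cov - alt, alt, pool_size = config$pool_size,
                          chrom = reg$chrom)
  attr(out, "truth") <- fx
  attr(out, "freq") <- freq
  out
})
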