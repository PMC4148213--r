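#' Haldane map function
#'
#' Converts genetic distance to a recombination fraction assuming no
#' crossover interference: `theta = (1 - exp(-2 d)) / 2` with `d` in Morgans.
#'
#' @param d_cM Genetic distance in centiMorgans (may be `Inf`).
#' @return Recombination fraction in `[0, 0.5]`.
#' @export
haldane_theta <- function(d_cM) {
  th <- 0.5 * (1 - exp(-2 * d_cM / 100))
  th[is.nan(th)] <- 0.5   # Inf - Inf distances: free recombination
  th
}

#' Configuration for an F2 intercross simulation
#'
#' Defaults mirror the mapping population the pipeline was designed around:
#' 229 F2 offspring from two inbred founder lines fixed for alternative
#' alleles at every marker and at a fully penetrant recessive trait locus.
#'
#' @param n_f2 Number of F2 offspring.
#' @param n_markers Number of codominant markers on one chromosome.
#' @param marker_spacing_cM Genetic distance between adjacent markers
#'   (`Inf` makes every locus segregate independently).
#' @param causal_index Marker index of the hidden trait locus; fractional
#'   values place it between markers.  Default: the middle of the map.
#' @param penetrance Probability a recessive homozygote shows the trait.
#' @param genotyping_error_rate Per-call probability that a marker call is
#'   replaced by one of the other two states, uniformly.
#' @param missing_rate Per-call probability of a missing marker call.
#' @param chrom Chromosome name used in the generated map.
#' @param cm_per_mb Genetic-to-physical scaling used to invent bp positions.
#' @param seed Integer seed (`NULL`: use the current RNG state).
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_f2 = 229, n_markers = 22, marker_spacing_cM = 1,
                         causal_index = NULL, penetrance = 1,
                         genotyping_error_rate = 0, missing_rate = 0,
                         chrom = "3", cm_per_mb = 3, seed = NULL) {
  stopifnot(n_f2 >= 1, n_markers >= 1, marker_spacing_cM > 0,
            penetrance >= 0, penetrance <= 1,
            genotyping_error_rate >= 0, genotyping_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n_f2 = n_f2, n_markers = n_markers,
                 marker_spacing_cM = marker_spacing_cM,
                 causal_index = causal_index, penetrance = penetrance,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, chrom = chrom,
                 cm_per_mb = cm_per_mb, seed = seed),
            class = "cross_config")
}

# Simulate N gametes along loci with the given adjacent recombination
# fractions; returns an N x length(theta_adj)+1 0/1 matrix of line origins.
.sim_gametes <- function(n, theta_adj) {
  m <- length(theta_adj) + 1L
  g <- matrix(0L, n, m)
  g[, 1] <- rbinom(n, 1, 0.5)
  for (j in seq_len(m - 1L))
    g[, j + 1L] <- (g[, j] + rbinom(n, 1, theta_adj[j])) %% 2L
  g
}

#' Simulate an F2 intercross segregating a recessive trait
#'
#' The two founder lines are fixed for alternative alleles at all markers and
#' at the trait locus (trait allele h coupled with marker allele coded 2).
#' F1 birds are double heterozygotes of known phase; each F2 offspring is
#' formed from two independent F1 gametes generated under Haldane
#' recombination.  An offspring is a `case` iff its trait genotype is h/h and
#' a penetrance draw succeeds; all others are `control`.
#'
#' @param config A [cross_config()].
#' @return A list with elements:
#'   \item{genotypes}{[genotype_matrix()] of the F2 (codes count the
#'     trait-line allele: 2 = homozygous for the allele coupled with h).}
#'   \item{theta_true}{True recombination fraction between the trait locus
#'     and each marker.}
#'   \item{trait_genotype}{Number of h alleles (0/1/2) carried by each F2.}
#' @export
simulate_f2_cross <- function(config = cross_config()) with_seed(config$seed, {
  n <- config$n_markers
  sp <- config$marker_spacing_cM
  ci <- if (is.null(config$causal_index)) (n + 1) / 2 else config$causal_index
  inf_sp <- is.infinite(sp)
  marker_cM <- if (inf_sp) as.numeric(seq_len(n)) else (seq_len(n) - 1) * sp
  causal_cM <- if (inf_sp) ci else (ci - 1) * sp

  loci_cM <- c(marker_cM, causal_cM)
  ord <- order(loci_cM, c(rep(1L, n), 0L))   # trait first on exact ties
  theta_adj <- if (inf_sp) rep(0.5, n) else haldane_theta(diff(loci_cM[ord]))
  trait_col <- which(ord == n + 1L)

  g1 <- .sim_gametes(config$n_f2, theta_adj)
  g2 <- .sim_gametes(config$n_f2, theta_adj)
  all_geno <- g1 + g2
  trait_geno <- all_geno[, trait_col]
  geno <- all_geno[, -trait_col, drop = FALSE]
  geno <- geno[, order(ord[-trait_col]), drop = FALSE]  # back to marker order

  affected <- trait_geno == 2L & runif(config$n_f2) < config$penetrance
  phen <- ifelse(affected, "case", "control")

  if (config$genotyping_error_rate > 0) {
    idx <- which(runif(length(geno)) < config$genotyping_error_rate)
    geno[idx] <- (geno[idx] +
                    sample(c(1L, 2L), length(idx), replace = TRUE)) %% 3L
  }
  if (config$missing_rate > 0)
    geno[runif(length(geno)) < config$missing_rate] <- NA_integer_

  bp <- if (inf_sp) seq_len(n) * 1e6
        else 1 + round(marker_cM * 1e6 / config$cm_per_mb)
  for (j in seq_len(n)[-1]) if (bp[j] <= bp[j - 1]) bp[j] <- bp[j - 1] + 1
  mm <- marker_map(sprintf("M%02d", seq_len(n)), config$chrom, bp)
  ind <- data.frame(id = sprintf("F2_%03d", seq_len(config$n_f2)),
                    phenotype = phen, population = "F2",
                    stringsAsFactors = FALSE)
  theta_true <- if (inf_sp) rep(0.5, n)
                else haldane_theta(abs(marker_cM - causal_cM))
  list(genotypes = genotype_matrix(geno, ind, mm),
       theta_true = setNames(theta_true, mm$marker),
       trait_genotype = trait_geno,
       config = config)
})
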