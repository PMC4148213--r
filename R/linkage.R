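#' Segregation-ratio chi-square test
#'
#' Pearson goodness-of-fit of observed dominant:recessive counts against an
#' expected Mendelian ratio (default 3:1 for a recessive trait in an F2).
#'
#' @param n_dominant,n_recessive Observed counts.
#' @param expected_ratio Length-2 numeric, dominant:recessive.
#' @return A list with `chi2`, `df` (1) and `p_value`.
#' @examples
#' segregation_chi_square(162, 67)   # chi2 = 2.21, not significant
#' @export
segregation_chi_square <- function(n_dominant, n_recessive,
                                   expected_ratio = c(3, 1)) {
  stopifnot(n_dominant >= 0, n_recessive >= 0, length(expected_ratio) == 2)
  if (n_dominant + n_recessive == 0) stop("zero total count")
  ht <- chisq.test(c(n_dominant, n_recessive),
                   p = expected_ratio / sum(expected_ratio), correct = FALSE)
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' F2 joint class probabilities for a recessive trait and a codominant marker
#'
#' One F2 offspring is formed from two independent F1 gametes; with the
#' trait allele h coupled to marker allele B in the founders, gamete
#' frequencies are hB = HA = (1 - theta)/2 and hA = HB = theta/2.  A `case`
#' requires trait genotype h/h; `wt` pools H/H and H/h.  The six class
#' probabilities sum to 1.
#'
#' @param marker_genotype `"AA"`, `"AB"` or `"BB"` (B = allele coupled with h).
#' @param phenotype `"wt"` or `"case"`.
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @return The class probability.
#' @export
f2_class_prob <- function(marker_genotype = c("AA", "AB", "BB"),
                          phenotype = c("wt", "case"), theta) {
  marker_genotype <- match.arg(marker_genotype)
  phenotype <- match.arg(phenotype)
  p <- .f2_class_probs(theta)
  p[marker_genotype, phenotype]
}

# 3x2 matrix of class probabilities at one theta (rows AA/AB/BB, cols wt/case)
.f2_class_probs <- function(theta) {
  if (theta < 0 || theta > 0.5) stop("theta must be in [0, 0.5]")
  hB <- (1 - theta) / 2   # non-recombinant gamete carrying h
  hA <- theta / 2         # recombinant gamete carrying h
  p_case <- c(AA = hA^2, AB = 2 * hA * hB, BB = hB^2)
  p_marker <- c(AA = 0.25, AB = 0.5, BB = 0.25)
  cbind(wt = p_marker - p_case, case = p_case)
}

# log-likelihood of a 3x2 count table at theta (0*log(0) treated as 0)
.f2_loglik <- function(counts, theta) {
  p <- .f2_class_probs(theta)
  lp <- log(p)
  lp[counts == 0] <- 0
  if (any(counts > 0 & p == 0)) return(-Inf)
  sum(counts * lp)
}

.as_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 2)))
    stop("counts must be a 3x2 table: rows AA/AB/BB, columns wt/case")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("zero total count")
  dimnames(counts) <- list(c("AA", "AB", "BB"), c("wt", "case"))
  counts
}

#' Two-point linkage: recombination-fraction MLE and LOD score
#'
#' Maximises the F2 intercross likelihood (see [f2_class_prob()]) over
#' `theta` in `[0, 0.5]` by golden-section/parabolic search with explicit
#' endpoint evaluation, ties broken toward smaller `theta`.
#' `LOD = log10 L(theta_hat) - log10 L(0.5)`, hence `LOD >= 0` always,
#' with equality iff `theta_hat = 0.5`.
#'
#' @param counts 3x2 numeric table of (marker genotype AA/AB/BB) x
#'   (phenotype wt/case) counts.
#' @param tol Search tolerance on `theta`.
#' @return A list of class `two_point_result`: `theta_hat`, `lod`,
#'   `loglik_at_hat`, `loglik_at_half` (natural logs), `counts`.
#' @examples
#' # 67 case offspring all homozygous for the coupled allele, no recombinants
#' counts <- matrix(c(54, 108, 0, 0, 0, 67), nrow = 3,
#'                  dimnames = list(c("AA", "AB", "BB"), c("wt", "case")))
#' two_point_lod(counts)$lod   # about 60.6
#' @export
two_point_lod <- function(counts, tol = 1e-6) {
  counts <- .as_count_table(counts)
  f <- function(th) .f2_loglik(counts, th)
  # coarse bracket, then golden-section/parabolic refinement inside it;
  # endpoints are evaluated explicitly so boundary MLEs are exact
  coarse <- seq(0, 0.5, by = 0.005)
  ll_coarse <- vapply(coarse, f, numeric(1))
  i <- which.max(ll_coarse)
  lo <- coarse[max(i - 1L, 1L)]
  hi <- coarse[min(i + 1L, length(coarse))]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  cand_th <- c(0, coarse[i], opt$maximum, 0.5)
  cand_ll <- c(ll_coarse[1], ll_coarse[i], opt$objective,
               ll_coarse[length(coarse)])
  ord <- order(cand_th)
  cand_th <- cand_th[ord]
  cand_ll <- cand_ll[ord]
  best <- which(cand_ll >= max(cand_ll) - 1e-12)[1]   # ties -> smaller theta
  th_hat <- cand_th[best]
  ll_hat <- cand_ll[best]
  ll_half <- f(0.5)
  structure(list(theta_hat = th_hat,
                 lod = (ll_hat - ll_half) / log(10),
                 loglik_at_hat = ll_hat,
                 loglik_at_half = ll_half,
                 counts = counts),
            class = "two_point_result")
}

#' @export
print.two_point_result <- function(x, ...) {
  cat(sprintf("two-point linkage: theta_hat = %.4f, LOD = %.2f\n",
              x$theta_hat, x$lod))
  invisible(x)
}

# Build the 3x2 count table for one marker from genotype codes and phenotype
# labels; code 2 is provisionally taken as the trait-coupled allele B.
.marker_counts <- function(calls, phen) {
  ok <- !is.na(calls)
  calls <- calls[ok]
  phen <- phen[ok]
  tab <- matrix(0, 3, 2, dimnames = list(c("AA", "AB", "BB"), c("wt", "case")))
  for (g in 0:2) {
    tab[g + 1, "wt"] <- sum(calls == g & phen != "case")
    tab[g + 1, "case"] <- sum(calls == g & phen == "case")
  }
  tab
}

#' Two-point linkage scan over a marker map
#'
#' One [two_point_lod()] fit per marker, complete-case per marker (missing
#' calls dropped marker by marker).  Because the coupling phase of each
#' marker is not assumed known, the likelihood is maximised over both phase
#' assignments (allele label swap), which leaves the LOD invariant to how
#' the input happens to label alleles.  Monomorphic (or all-missing) markers
#' are flagged non-informative rather than raising an error.
#'
#' @param gm A [genotype_matrix()] of F2 offspring whose phenotypes are
#'   `case`/`control`.
#' @param phase `"infer"` (default: maximise over both phases) or `"coupled"`
#'   (assume code 2 is the trait-coupled homozygote, as in
#'   [simulate_f2_cross()] output).
#' @param tol Passed to [two_point_lod()].
#' @return A `data.frame` with one row per marker: `marker`, `pos`, `n`,
#'   `theta_hat`, `lod`, `informative`.
#' @export
scan_markers <- function(gm, phase = c("infer", "coupled"), tol = 1e-6) {
  phase <- match.arg(phase)
  phen <- gm$individuals$phenotype
  if (any(!phen %in% c("case", "control")))
    stop("scan needs every individual phenotyped case or control")
  mm <- gm$map
  if (is.null(mm)) stop("genotype matrix has no marker map")
  res <- lapply(seq_len(ncol(gm$geno)), function(j) {
    calls <- gm$geno[, j]
    obs <- calls[!is.na(calls)]
    if (length(obs) == 0 || length(unique(obs)) == 1)
      return(data.frame(theta_hat = NA_real_, lod = NA_real_,
                        n = length(obs), informative = FALSE))
    tab <- .marker_counts(calls, phen)
    fit <- two_point_lod(tab, tol = tol)
    if (phase == "infer") {
      fit2 <- two_point_lod(tab[3:1, , drop = FALSE], tol = tol)
      if (fit2$lod > fit$lod) fit <- fit2
    }
    data.frame(theta_hat = fit$theta_hat, lod = fit$lod,
               n = length(obs), informative = TRUE)
  })
  out <- cbind(data.frame(marker = mm$marker, pos = mm$pos,
                          stringsAsFactors = FALSE),
               do.call(rbind, res))
  out[order(out$pos), c("marker", "pos", "n", "theta_hat", "lod",
                        "informative")]
}
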