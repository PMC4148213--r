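# Independent oracles used to validate the implementation.  They share no
# code with the package internals: class probabilities come from direct
# gamete-pair enumeration, and block finding enumerates every marker window.

# F2 class probabilities by enumeration of the 16 ordered F1 gamete pairs.
# Gametes are (trait allele, marker allele) with frequencies
# hB = HA = (1 - theta)/2 and hA = HB = theta/2 (h coupled with B).
# Returns a length(theta) x 6 matrix, columns
# AA.wt, AB.wt, BB.wt, AA.case, AB.case, BB.case.
oracle_class_probs <- function(theta) {
  trait <- c("h", "h", "H", "H")
  marker <- c("B", "A", "B", "A")
  fr <- cbind((1 - theta) / 2, theta / 2, theta / 2, (1 - theta) / 2)
  out <- matrix(0, length(theta), 6,
                dimnames = list(NULL, c("AA.wt", "AB.wt", "BB.wt",
                                        "AA.case", "AB.case", "BB.case")))
  for (i in 1:4) for (j in 1:4) {
    nB <- (marker[i] == "B") + (marker[j] == "B")
    mk <- c("AA", "AB", "BB")[nB + 1]
    ph <- if (trait[i] == "h" && trait[j] == "h") "case" else "wt"
    col <- paste(mk, ph, sep = ".")
    out[, col] <- out[, col] + fr[, i] * fr[, j]
  }
  out
}

# Exhaustive grid MLE for the two-point likelihood; counts is the 3x2 table
# (rows AA/AB/BB, cols wt/case).  Step 1e-4 as in the validation contract.
oracle_grid_lod <- function(counts, step = 1e-4) {
  th <- seq(0, 0.5, by = step)
  p <- oracle_class_probs(th)
  cnt <- c(counts[, "wt"], counts[, "case"])  # AA.wt AB.wt BB.wt AA.c AB.c BB.c
  ll <- rep(0, length(th))
  for (k in 1:6) {
    if (cnt[k] == 0) next
    ll <- ll + cnt[k] * log(p[, k])
  }
  i <- which.max(ll)   # first index on ties -> smaller theta
  list(theta_hat = th[i],
       lod = (ll[i] - ll[length(th)]) / log(10))
}

# Brute-force window oracle for case-shared homozygosity blocks: tests every
# (start, end) marker window for the sharing predicate and keeps the maximal
# qualifying windows.  Returns a list of c(start, end) index pairs.
oracle_shared_blocks <- function(geno) {
  m <- ncol(geno)
  marker_ok <- vapply(seq_len(m), function(j) {
    obs <- geno[, j][!is.na(geno[, j])]
    length(obs) == 0 ||
      (length(unique(obs)) == 1 && obs[1] %in% c(0L, 2L))
  }, logical(1))
  qualifies <- function(s, e) all(marker_ok[s:e])
  blocks <- list()
  for (s in seq_len(m)) for (e in s:m) {
    if (qualifies(s, e) &&
        (s == 1 || !qualifies(s - 1, e)) &&
        (e == m || !qualifies(s, e + 1)))
      blocks[[length(blocks) + 1]] <- c(s, e)
  }
  blocks
}

# Random 3x2 count tables for estimator validation: a mix of multinomial
# draws from the F2 model at random theta and fully arbitrary tables.
random_count_table <- function() {
  if (runif(1) < 0.7) {
    th <- runif(1, 0, 0.5)
    n <- sample(30:300, 1)
    p <- oracle_class_probs(th)[1, ]
    cnt <- as.vector(rmultinom(1, n, p))
  } else {
    cnt <- rpois(6, lambda = sample(c(2, 10, 40), 1))
    if (sum(cnt) == 0) cnt[1] <- 1
  }
  matrix(cnt, 3, 2, dimnames = list(c("AA", "AB", "BB"), c("wt", "case")))
}
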