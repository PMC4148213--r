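# Seed plumbing: every simulator takes one integer seed and derives a child
# stream per stochastic sub-task, so one global seed makes a whole pipeline
# run reproducible while sub-tasks stay independent.

#' Derive a child seed from a global seed and a stream tag
#'
#' Deterministic hash of `(seed, tag)` into a valid 32-bit seed.
#'
#' @param seed Integer global seed.
#' @param tag Character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483646)
}

# Run `expr` under `seed` (if non-NULL) without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
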