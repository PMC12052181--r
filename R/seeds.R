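# Seed plumbing.  Every stochastic entry point takes a single integer seed;
# internal stages draw sub-seeds from it through a fixed LCG so that adding a
# stage never perturbs the streams of earlier stages.

#' Derive a reproducible sub-seed from a base seed
#'
#' A small splittable-seed helper: sub-seed `k` of `seed` is obtained from a
#' Lehmer-style congruential step, keeping all values in the positive 32-bit
#' integer range.  Used internally so that independent simulation stages
#' (e.g., per-subject behavioral tables and their neural epochs) get
#' decoupled random streams from one user-facing seed.
#'
#' @param seed integer base seed.
#' @param k integer stream index (>= 0).
#' @return An integer sub-seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), length(k) == 1L, k >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (i in seq_len(k + 1L)) {
    # 16807 * s mod m in double precision via Schrage's decomposition
    hi <- s %/% 127773
    lo <- s %% 127773
    s <- 16807 * lo - 2836 * hi
    if (s <= 0) s <- s + m
  }
  as.integer(s)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
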