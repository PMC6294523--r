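#' Derive a child seed from a master seed and a stream key
#'
#' All randomness in the package flows from a single scenario seed. Independent
#' random streams (panel simulation, genotype sampling, per-replicate truth
#' selection, per-bootstrap resampling, ...) are keyed by short strings and/or
#' integer indices; the child seed is a deterministic 31-bit mix of the master
#' seed and the key, so streams never collide by accident and every stage is
#' reproducible in isolation.
#'
#' @param seed master integer seed.
#' @param key character or integer key naming the stream (vectors are folded
#'   in order).
#' @return a positive integer seed below 2^31.
#' @examples
#' split_seed(1, "panel")
#' split_seed(1, c("replicate", 7))
#' @export
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (k in unlist(key)) {
    ints <- if (is.character(k)) utf8ToInt(k) else as.integer(k)
    for (i in ints) {
      # 31-bit multiplicative mix (Park-Miller constant)
      h <- (h * 48271 + as.double(i) + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483646) + 1L
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
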