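# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible sequence of sub-seeds from a master seed
#'
#' Replicated experiments need one independent seed per replicate.  Seeds are
#' drawn without replacement from a RNG stream seeded with `master`, so the
#' whole sequence is a pure function of the master seed and every derived
#' seed fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
seedSequence <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master),
            is.numeric(n), length(n) == 1L, n >= 1L)
  withSeed(as.integer(master), sample.int(.Machine$integer.max - 1L, as.integer(n)))
}

# Cheap content fingerprint used to tag score files with their source matrix;
# a provenance aid, not a cryptographic hash.
matrixFingerprint <- function(m) {
  v <- as.numeric(m)
  a <- sum(v) %% 2147483647
  b <- sum(v * (seq_along(v) %% 9973)) %% 2147483647
  sprintf("%dx%d-%08x%08x", nrow(m), ncol(m), as.integer(a), as.integer(b))
}

# round-half-up, used for subset sizes: round(2.5) in R is banker's rounding
roundHalfUp <- function(x) floor(x + 0.5)
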