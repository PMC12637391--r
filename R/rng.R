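# Deterministic counter-based random streams.
#
# Connected and decoupled-replay simulations must reproduce identical
# stochastic outcomes (synaptic release, background-noise paths) from the same
# trial seed, independently of how many other random draws happen in between.
# Global-state RNGs cannot guarantee that, so per-entity outcomes are derived
# from a keyed counter hash, and per-entity generator streams from keyed
# sub-seeds.  The hash is a Lehmer-style multiplicative congruential mix over
# the 2^31 - 1 field; all arithmetic stays below 2^53 so it is exact in
# doubles.

.MIX_MOD <- 2147483647  # 2^31 - 1 (Mersenne prime)
.MIX_MUL <- 48271       # full-period Lehmer multiplier for this modulus

#' Mix a sequence of integer key components into a single counter hash
#'
#' @param ... numeric scalars or character scalars (characters are folded
#'   bytewise); order matters.
#' @return integer in `[1, 2^31 - 2]`
#' @keywords internal
mix_key <- function(...) {
  parts <- list(...)
  h <- 1
  for (p in parts) {
    if (is.character(p)) {
      p <- as.numeric(utf8ToInt(p))
    }
    for (x in p) {
      h <- (h + (x %% .MIX_MOD)) %% .MIX_MOD
      if (h == 0) h <- 1
      h <- (h * .MIX_MUL) %% .MIX_MOD
      h <- (h * .MIX_MUL) %% .MIX_MOD
    }
  }
  # two final scrambling rounds decorrelate adjacent counters
  h <- (h * .MIX_MUL) %% .MIX_MOD
  h <- (h * .MIX_MUL) %% .MIX_MOD
  if (h == 0) h <- 1
  as.integer(h)
}

#' Keyed uniform variate on (0, 1)
#'
#' Pure function of its key: the same key always yields the same number,
#' regardless of `.Random.seed`.  Used for per-event synaptic release draws.
#'
#' @inheritParams mix_key
#' @keywords internal
counter_uniform <- function(...) {
  mix_key(...) / .MIX_MOD
}

#' Keyed sub-seed suitable for `set.seed()`
#'
#' @inheritParams mix_key
#' @keywords internal
stream_seed <- function(...) {
  mix_key(...)
}

#' Evaluate an expression under a temporary, keyed RNG state
#'
#' Saves and restores `.Random.seed` so that keyed draws never perturb (and
#' are never perturbed by) the caller's RNG state.
#'
#' @param seed integer seed for the scoped stream
#' @param expr expression to evaluate
#' @keywords internal
with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
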