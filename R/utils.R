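# Internal RNG helpers.
#
# All simulation entry points take an integer seed and must be reproducible
# without clobbering the caller's RNG state. `local_rng(seed)` seeds the
# global generator and restores the previous state when the calling frame
# exits. Sub-stream seeds derived for participants are kept below 2^31 - 1.

local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  }
  withr::defer(restore(), envir = envir)
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(seed)
}

# Deterministic sub-stream seed for unit `i` of a parent seed (31-bit).
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
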