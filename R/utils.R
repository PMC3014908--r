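# Run code under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Named substreams derived from one master seed; keeps results < 2^31.
substream_seed <- function(seed, stream) {
  offsets <- c(generator = 11L, matching = 23L, tiebreak = 37L,
               pipeline = 53L, evaluation = 71L)
  off <- offsets[[stream]]
  (as.integer(seed) * 101L + off * 7919L) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
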