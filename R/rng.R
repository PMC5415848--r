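# Private seeded RNG stream that does not disturb the caller's global
# random state. Each draw swaps the stream's state in, draws, and restores
# whatever .Random.seed was there before.
local_rng <- function(seed) {
  state <- NULL
  draw <- function(fn, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed)) else
      assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    sample = function(x, size, replace = FALSE) draw(base::sample, x, size, replace)
  )
}
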