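# Reproducible, encapsulated RNG streams. Every stochastic component draws
# from its own named stream derived from a master seed, so schedules, gaze
# traces and responses are reproducible trial-by-trial and independent of
# the caller's global RNG state.

#' Derive a child seed from a master seed and a label
#'
#' Deterministic mixing of a master seed with a character label (e.g.
#' `"gaze"`, `"participant3"`), kept within the 32-bit integer range.
#'
#' @param master_seed integer master seed.
#' @param label character label of the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, label) {
  h <- as.integer(master_seed) %% 2147483647L
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647L
  }
  as.integer(h)
}

# A private RNG stream: draws advance the stream's own state only and the
# caller's .Random.seed is restored afterwards.
local_rng <- function(seed) {
  state_env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% 2147483647L)
  state_env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())

  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", state_env$state, globalenv())
    on.exit({
      state_env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    normal = function(n, mean = 0, sd = 1) with_state(stats::rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) with_state(stats::runif(n, min, max)),
    gamma = function(n, shape, scale) with_state(stats::rgamma(n, shape = shape, scale = scale)),
    bernoulli = function(n, p) with_state(stats::runif(n) < p),
    sample = function(x, size = length(x), replace = FALSE) with_state(sample(x, size, replace)),
    integer = function(n, max) with_state(sample.int(max, n, replace = TRUE))
  )
}
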