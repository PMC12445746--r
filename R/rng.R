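# Seed derivation and independent noise streams.
#
# All randomness in a simulation run fans out from one master seed through
# labelled child seeds, so that (a) the same environments are seen by every
# strategy, and (b) adding a strategy or noise source never perturbs the
# draws of existing streams. Child seeds are derived with a small polynomial
# rolling hash over the label, kept below 2^31 so they are valid R seeds.

#' Derive a child seed from a master seed and a stream label
#'
#' @param master integer master seed.
#' @param ... label components (coerced to character) identifying the stream,
#'   e.g. `child_seed(1, "env", 3)`.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, ...) {
  label <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  h <- 0
  p <- 2147483629 # largest prime < 2^31 - 18
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% p
  }
  as.integer((h + as.numeric(master)) %% p)
}

# A resumable RNG stream: draws from its own .Random.seed so concurrent
# streams never interleave. Used for motor noise vs global-vector noise etc.
rng_stream <- function(seed) {
  state <- withr::with_seed(as.integer(seed),
                            get(".Random.seed", envir = globalenv()))
  draw <- function(fn) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    assign(".Random.seed", state, envir = globalenv())
    out <- fn()
    state <<- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    out
  }
  list(
    rnorm = function(n = 1, mean = 0, sd = 1) draw(function() rnorm(n, mean, sd))
  )
}
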