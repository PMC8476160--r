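#' Named random-number substreams
#'
#' A model run draws randomness for several independent subsystems (movement,
#' mating, mutation, mortality, burn-in, ...). To keep runs reproducible and to
#' make subsystems independent -- so that switching one off does not shift the
#' draws another sees -- a master seed is expanded into named substreams, each
#' holding its own saved generator state. Evaluating code "in" a stream swaps
#' that state into R's global generator and saves it back afterwards.
#'
#' @param master integer master seed (< 2^31).
#' @param names character vector of stream names.
#' @return an environment mapping stream name -> saved `.Random.seed`.
#' @keywords internal
rng_streams <- function(master,
                        names = c("landscape", "genome", "movement", "mating",
                                  "mutation", "mortality", "burnin", "misc")) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  master <- as.integer(master %% 2147483647L)
  e <- new.env(parent = emptyenv())
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  for (i in seq_along(names)) {
    # distinct, deterministic child seeds kept below 2^31
    set.seed((master + 999983L * i) %% 2147483647L)
    assign(names[i], .GlobalEnv$.Random.seed, envir = e)
  }
  e
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
}

#' Evaluate an expression under a named substream
#' @keywords internal
with_stream <- function(streams, name, expr) {
  if (is.null(streams)) return(expr)
  if (!exists(name, envir = streams, inherits = FALSE)) {
    stop("unknown RNG stream: ", name)
  }
  outer <- get_rng_state()
  set_rng_state(get(name, envir = streams))
  on.exit({
    assign(name, get_rng_state(), envir = streams)
    set_rng_state(outer)
  })
  expr
}
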