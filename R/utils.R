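# Seed hygiene: every stochastic routine in the package draws from one named,
# versioned generator (Mersenne-Twister / Inversion / Rejection) under an
# explicit caller-supplied seed, and the caller's RNG state is restored
# afterwards, so results are pure functions of (seed, parameters).

#' Evaluate an expression under a fixed, named RNG seed
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`; the global RNG state is left untouched.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}
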