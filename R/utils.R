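# internal helpers shared across modules

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{code} with the global random-number state set from \code{seed},
#' restoring the previous state afterwards so that seeded draws inside package
#' functions never disturb the caller's RNG stream. A \code{NULL} seed
#' evaluates \code{code} against the ambient stream unchanged.
#'
#' @param seed single integer seed, or \code{NULL}.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
.withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!.is_number(seed)) {
    .stopf("seed must be a single finite number or NULL")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# multiplicative log-normal factors with mean 1 and the given coefficient of
# variation; cv = 0 returns exact ones
.lognormFactor <- function(n, cv) {
  if (cv <= 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}
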