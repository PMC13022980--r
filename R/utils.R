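#' @importFrom methods new validObject is slot slotNames setValidity show
#' @importFrom stats runif rnorm rpois rcauchy sd qt rmultinom
#' @importFrom utils write.csv read.csv head tail
NULL

## Evaluate `expr` under a temporary seed, restoring the caller's RNG state.
## Used everywhere a function accepts an explicit `seed` so that seeded calls
## never disturb an enclosing random stream (e.g. an optimizer loop).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' Fans a single global seed out to per-stage/per-item child seeds via a
#' counter-based linear scheme, so that stages can be rerun independently
#' while remaining reproducible. Results stay below 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param index nonnegative integer counter (stage or item index).
#' @return an integer seed.
#' @export
childSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), is.numeric(index))
  as.integer((as.double(seed %% 1000003L) * 2039 + as.double(index) * 9973 + 17) %%
               2147483647)
}

clipRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

isoNow <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

## Line-oriented logger with ISO timestamps; logs to console and optionally
## to a file connection path.
stageLog <- function(msg, logFile = NULL, verbose = TRUE) {
  line <- paste0("[", isoNow(), "] ", msg)
  if (verbose) message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
  invisible(line)
}
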