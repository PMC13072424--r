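# Internal helpers: argument checking and reproducible sub-seeding.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop2(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  x
}

#' Derive a reproducible sub-seed from a master seed and a stage name
#'
#' Every stochastic stage of the simulator and pipeline draws its own
#' random stream from a seed derived deterministically from the master
#' seed and the stage name, so individual stages can be re-run in
#' isolation with identical results. The derivation is a small string
#' hash folded into the 31-bit signed integer range R requires.
#'
#' @param seed Master seed (integer).
#' @param name Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 1986484309
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# Run `expr` under a stage-derived seed, restoring the caller's RNG state.
with_stage_seed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, name))
  expr
}
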