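## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream-specific random seed from a master seed
#'
#' All simulators draw their randomness from a single integer master seed.
#' Each named random stream gets its own derived seed so that adding a new
#' stream never perturbs existing ones. The derivation is a small multiply-add
#' hash of the stream tag, kept below 2^31 so the result is a valid R integer.
#'
#' @param seed Master integer seed.
#' @param tag Character tag naming the stream (e.g. `"shrna"`, `"reads"`).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

## stop() with a class so callers/tests can discriminate config vs data errors
sdl_stop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

config_error <- function(msg) sdl_stop(msg, "sdl_config_error")
data_error   <- function(msg) sdl_stop(msg, "sdl_data_error")

assert_prob <- function(x, nm) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    config_error(sprintf("'%s' must be in [0, 1]", nm))
  invisible(x)
}

assert_count <- function(x, nm, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    config_error(sprintf("'%s' must be an integer >= %d", nm, min))
  invisible(as.integer(x))
}

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
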