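#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed deterministically
#' from the master seed, so that a single integer reproduces a full run while
#' keeping the random streams of different stages decoupled.
#'
#' @param master master seed (integer).
#' @param label character tag naming the stage.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
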