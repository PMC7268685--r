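`%||%` <- function(a, b) if (is.null(a)) b else a

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a named random substream seed from a master seed
#'
#' All stochastic operations in the package draw their seed from a master
#' seed plus a stream name, so that independent stages are reproducible and
#' uncorrelated without sharing one global RNG state.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  # small stable string hash (polynomial rolling, modular)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(master) %% 2147483629 * 2654435 + h) %% 2147483629)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded fixtures never perturb surrounding randomness.
#'
#' @param seed integer seed; @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_phylocong <- function(msg, class) {
  stop(structure(class = c(class, "phylocong_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
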