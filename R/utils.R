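#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' All stochastic components of the package (data generation, parameter
#' initialisation, per-epoch shuffling, embedding initialisation) draw their
#' seeds through named substreams of a single master seed, so a run is
#' reproducible component-wise: changing, say, the shuffling stream cannot
#' perturb the data stream.
#'
#' @param seed integer master seed.
#' @param label character stream label, e.g. `"data"`, `"init"`,
#'   `"shuffle.12"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "data")
#' derive_seed(1, "init")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(label)) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# stop() with a class so callers/tests can catch validation errors precisely
kd_stop <- function(msg, class = "kd_error", call. = FALSE) {
  stop(structure(
    class = c(class, "kd_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

check_scalar <- function(x, name, integer = FALSE, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    kd_stop(sprintf("field '%s' must be a single finite number", name),
            class = "kd_validation_error")
  }
  if (integer && x != round(x)) {
    kd_stop(sprintf("field '%s' must be an integer", name),
            class = "kd_validation_error")
  }
  if (x < lower || x > upper) {
    kd_stop(sprintf("field '%s' must be in [%s, %s] (got %s)",
                    name, lower, upper, x),
            class = "kd_validation_error")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sigmoid, numerically safe on both tails
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}
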