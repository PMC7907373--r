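`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Every stochastic component draws from its own stream, keyed by a label, so
#' that adding or reordering pipeline stages never perturbs the randomness of
#' earlier stages. The derivation is a fixed multiplicative hash kept inside
#' 32-bit integer range.
#'
#' @param seed master seed (integer).
#' @param ... one or more character/numeric labels identifying the stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.double(seed) %% m
  for (lab in unlist(list(...))) {
    for (code in utf8ToInt(as.character(lab))) {
      h <- (h * 48271 + code) %% m
    }
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
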