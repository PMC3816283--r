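# Internal helpers: seeded substreams, argument checks, SEM.

#' Derive a reproducible substream seed from a top-level seed and a name
#'
#' All randomness in the synthetic-data generators flows from one top-level
#' seed through named substreams, one per artifact. Adding a new artifact to
#' a simulated study therefore never perturbs the draws of existing ones.
#' The derivation is a small multiplicative string hash folded into the seed
#' modulo 2^31 - 1, so it stays inside R's 32-bit integer range.
#'
#' @param seed integer top-level seed.
#' @param name character label of the substream (e.g. "standards").
#' @return an integer seed.
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% m
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("`%s` must be numeric and non-missing", name), call. = FALSE)
  }
  if (strict && any(x <= 0)) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (!strict && any(x < 0)) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}
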