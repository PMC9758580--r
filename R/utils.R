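# Internal helpers: seed streams and RNG scoping.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Deterministically mixes a master seed with any number of integer or
#' character keys, returning a seed in `[0, 2^31 - 2]`. Used to spawn
#' independent, reproducible random streams (data generation, weight
#' initialisation, augmentation, sampling, scheduling) from a single
#' master seed.
#'
#' @param seed Integer master seed.
#' @param ... Integer or character keys naming the substream.
#' @return A single integer seed.
#' @export
#' @examples
#' mix_seed(1, "weights", 3)
mix_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1, is.finite(seed))
  s <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (k in list(...)) {
    kk <- if (is.character(k)) {
      v <- utf8ToInt(k)
      sum(v * seq_along(v))
    } else {
      as.double(abs(as.integer(k)))
    }
    s <- (s * 69069 + kk * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Round a numeric vector/matrix/array through single precision, keeping
# attributes. Network weights are kept exactly float-representable so that
# the C++ core's double<->float conversions are lossless.
float_round <- function(x) {
  y <- float_round_cpp(as.double(x))
  attributes(y) <- attributes(x)
  y
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

assert_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}
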