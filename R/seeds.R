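#' Derive a deterministic child seed from a root seed
#'
#' Each stochastic component of the pipeline (trial generation, missingness,
#' imputation, bootstrap, per-replicate streams) draws its randomness from a
#' seed derived deterministically from a root seed and a string key, so that
#' any single component of any replicate can be reproduced in isolation.
#'
#' The derivation is a 31-ary polynomial hash of the key characters folded
#' into the root seed, reduced modulo 2^31 - 1; arithmetic stays exact in
#' double precision.
#'
#' @param seed Integer root seed (non-negative, below 2^31).
#' @param ... One or more strings or integers naming the sub-stream,
#'   e.g. `derive_seed(seed, "mask", r)` for the masking stream of
#'   replicate `r`.
#' @return An integer seed in `[1, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(42, "trial", 1)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  h <- seed %% m
  key <- paste(vapply(list(...), function(x) paste0(x, collapse = ","),
                      character(1)), collapse = "/")
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# RNG stream afterwards so package functions never disturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
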