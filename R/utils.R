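# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, code) {
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
  force(code)
}

#' Deterministic 31-bit seed derived from a base seed and a string id
#'
#' Polynomial string hash mixed with the base seed; keeps every derived seed
#' in [0, 2^31 - 1) so set.seed() accepts it. Used so per-sample RNG streams
#' do not depend on sample order.
#' @noRd
derive_seed <- function(seed, id) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(id))) h <- (h * 31 + ch) %% m
  as.integer((h + (abs(as.numeric(seed)) %% m) * 48271) %% m)
}

# stop() without the call, with sprintf-style formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
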