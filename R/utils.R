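## Internal helpers shared across modules.

MERSENNE31 <- 2147483647

#' Derive a reproducible 32-bit seed from a base seed and arbitrary tokens
#'
#' Polynomial rolling hash over the UTF-8 bytes of each token, folded into
#' the base seed modulo 2^31 - 1. Used to give each sample (and each
#' effective set size within a sample) its own deterministic RNG stream, so
#' that results do not depend on the order in which samples or pathways are
#' visited.
#'
#' @param seed integer base seed.
#' @param ... character or integer tokens identifying the stream.
#' @return an integer in [1, 2^31 - 2].
#' @keywords internal
derive_seed <- function(seed, ...) {
  tokens <- vapply(list(...), function(x) paste0(as.character(x), collapse = "\r"),
                   character(1))
  h <- as.numeric(seed) %% MERSENNE31
  for (tok in tokens) {
    for (b in utf8ToInt(tok)) {
      h <- (h * 131 + b + 7) %% MERSENNE31
    }
    h <- (h * 131 + 1) %% MERSENNE31
  }
  as.integer(h %% (MERSENNE31 - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) stop(..., call. = FALSE)

## run `expr` with a private RNG state seeded by `seed`, restoring the
## caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
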