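# Internal helpers: seeded RNG scoping and seed fan-out.

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a labelled child seed from a master seed
#'
#' One master seed fans out to independent, stable streams: the child seed
#' depends only on the master seed and the label, so adding an operation
#' elsewhere never perturbs an unrelated stream. Result is a non-negative
#' integer below 2^31.
#'
#' @param master integer master seed.
#' @param label character label naming the operation/stream.
#' @return An integer seed.
#' @export
child_seed <- function(master, label) {
  h <- as.integer(master) %% 2147483647L
  for (code in utf8ToInt(as.character(label))) {
    # 31-bit multiplicative string hash (mod Mersenne prime 2^31 - 1)
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
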