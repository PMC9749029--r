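#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so seeded
#' internals do not disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and stage labels
#'
#' Deterministic polynomial string hash, kept below 2^31 so the result is a
#' valid R integer seed. Decouples the random streams of pipeline stages.
#'
#' @param master integer master seed.
#' @param ... character labels (stage, dataset, method ...).
#' @return integer seed.
#' @export
derive_seed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (lab in as.character(c(...))) {
    for (code in utf8ToInt(lab)) {
      s <- (s * 31 + code) %% 2147483647
    }
  }
  as.integer(s)
}
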