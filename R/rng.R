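#' Derive a reproducible substream seed
#'
#' Analyses that draw random numbers accept a single integer seed and fan it
#' out to named substreams (e.g. "geometry" vs "attributes"), so that
#' changing how many draws one stage makes never reshuffles another stage.
#' The derivation is a small deterministic integer hash of the parent seed
#' and the stream label; the result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer parent seed.
#' @param label character stream label.
#' @return an integer seed for the substream.
#' @examples
#' substream_seed(1, "geometry")
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(label),
            length(label) == 1)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package internals never perturb the user's random stream.
#'
#' @param seed integer seed, or `NULL` to use the ambient RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_rng <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
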