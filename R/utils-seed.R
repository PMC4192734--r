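#' Derive a reproducible substream seed
#'
#' All stochastic stages of the pipeline draw their randomness from one
#' top-level seed. Each stage uses a named substream so that partial reruns
#' (e.g. regenerating intensities without regenerating the panel) remain
#' reproducible. The substream seed is a deterministic 31-bit hash of the
#' top-level seed and the stream name.
#'
#' @param seed Integer top-level seed.
#' @param stream Character scalar naming the stage.
#' @return An integer seed in [0, 2^31).
#' @export
#' @examples
#' substreamSeed(1L, "genome")
substreamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(stream)) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate an expression with a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded stages do not
#' perturb user-level randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# shared input checks -------------------------------------------------------

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
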