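#' Derive a child seed from a master seed
#'
#' A single master seed drives every stage of a pipeline run. Each stage
#' (and each participant within a stage) gets its own child seed so that
#' stages can be re-run individually and still reproduce byte-identical
#' output. The derivation folds the master seed and an arbitrary sequence
#' of keys (strings or integers) through a small multiplicative hash; the
#' result is always in `[1, 2^31 - 2]` and so is a valid R RNG seed.
#'
#' @param master integer master seed.
#' @param ... keys identifying the stage: character scalars and/or integers,
#'   e.g. `derive_seed(seed, "participant", 7)`.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "stream")
#' derive_seed(1, "participant", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(master) %% m)
  for (key in list(...)) {
    bytes <- if (is.character(key)) {
      utf8ToInt(paste(key, collapse = "/"))
    } else {
      as.integer(key) %% m
    }
    for (b in bytes) {
      # product stays below 2^31 * 69069 < 2^53: exact in doubles
      h <- (h * 69069 + b * 2654435 + 1) %% m
    }
  }
  as.integer(h %% (m - 2L) + 1L)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do
#' not disturb the caller's RNG stream. With `seed = NULL` the expression
#' runs on the current stream.
#'
#' @param seed integer seed or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Stable short hash of an R object (used to stamp outputs with the config
# that produced them). Not cryptographic; diffable determinism only.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(txt)) h <- (h * 69069 + b * 2654435 + 1) %% m
  sprintf("%08x", as.integer(h))
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
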