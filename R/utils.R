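# Internal helpers: seeding, RNG hygiene, validation.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage- or run-specific seed from a global seed
#'
#' Hashes a text tag into the global seed so that each pipeline stage (and each
#' optimiser run) draws from its own reproducible stream. Adding a new stage
#' never perturbs the streams of existing stages.
#'
#' @param seed integer global seed.
#' @param tag character scalar naming the consumer (e.g. `"simulate"`).
#' @return An integer in `[0, 2^31 - 20)`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  bytes <- utf8ToInt(tag)
  h <- sum(bytes * seq_along(bytes)) + 131 * sum(bytes)
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973) %% 2147483629)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored on exit so no function leaks global randomness.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_positive_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop_input("configuration error: `", name, "` must be a positive integer, got ",
               deparse(x))
  }
  invisible(as.integer(x))
}
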