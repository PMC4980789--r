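#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Every stochastic component of the package receives its own seed derived
#' deterministically from one master seed and a character tag, so that a
#' single `seed` argument makes a whole pipeline reproducible while keeping
#' the random streams of its components independent.
#'
#' @param seed integer master seed.
#' @param tag character label identifying the component ("genotypes",
#'   "split:0.5", ...).
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
sub_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(tag) == 1L)
  v <- utf8ToInt(as.character(tag))
  h <- sum(v * seq_along(v)) %% 1048573
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 1) %% 2147483629 + 1)
}

# stop() with a consistent prefix naming the offending field
bad_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
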