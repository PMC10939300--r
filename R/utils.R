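#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit hash of a character string (polynomial rolling hash).
# Used to derive per-pair child seeds so results do not depend on the order
# in which pathway pairs are visited.
str_hash <- function(x) {
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 131 + k) %% 2147483647L
  as.integer(h)
}

# Child seed from a master seed and one or more id strings.
child_seed <- function(seed, ...) {
  ids <- paste(c(...), collapse = "\r")
  as.integer((as.numeric(seed) * 48271 + str_hash(ids)) %% 2147483647L)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
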