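#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Hashes the master seed together with an arbitrary sequence of labels into
#' a 32-bit integer seed. Used throughout the package so that each stage,
#' participant and condition has its own stable stream: adding a participant
#' or re-running one stage never reshuffles the randomness of another.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return a positive integer seed below 2^31.
#' @export
#' @examples
#' derive_seed(1, "design", 3)
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1, is.finite(seed))
  label <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483629
  as.integer(h + 1)
}

#' Short deterministic hash of a configuration object
#'
#' @param x any R object; hashed via its deparsed representation.
#' @return an 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "niceNames", "showAttributes")),
               collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

# run `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% 2147483647), code)
}
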