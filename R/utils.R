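# Internal helpers shared across pipeline stages.

#' Derive a reproducible substream seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Each stage
#' draws from its own substream, keyed by a short label, so that adding or
#' reordering stages never perturbs the draws of another stage. Substream
#' seeds are kept strictly below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param key character label of the consuming stage.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 10007L
  as.integer((abs(as.integer(seed)) %% 209715L) * 10007L + h)
}

# run code under a local RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "personet_error")
}

config_error <- function(field, msg) {
  abort(sprintf("invalid configuration field '%s': %s", field, msg),
        class = c("personet_config_error", "personet_error"))
}

# zero-padded identifier factory: ids("G", 3, 7) -> "G0000003"
make_ids <- function(prefix, n, width = 6) {
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}
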