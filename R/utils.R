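# Seed the RNG when an explicit seed is supplied; no-op when seed is NULL,
# so functions compose with an externally managed random stream.
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Uniform draw of one element, safe for length-1 numeric vectors (avoids
# base sample()'s 1:n expansion).
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Derive a bounded child seed from a base seed and an offset (keeps every
# derived seed a valid 32-bit integer).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
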