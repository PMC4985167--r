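`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label; stays below 2^31.
derive_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 7919 + sum(utf8ToInt(as.character(stream)))) %%
    2147483629
  as.integer(s)
}

# Cheap deterministic content digest (two independent polynomial hashes).
# Used to fingerprint descriptor configurations so that a model refuses
# queries featurized under a different configuration. Not cryptographic.
content_digest <- function(x) {
  s <- paste(x, collapse = "\x1f")
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  m1 <- 2147483647; m2 <- 2147483629
  h1 <- 0; h2 <- 5381
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% m1
    h2 <- (h2 * 137 + b) %% m2
  }
  sprintf("%08x%08x", h1, h2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
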