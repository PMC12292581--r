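# seed handling: functions that take an explicit seed scope it locally so
# callers' RNG streams are left untouched
local_seed <- function(seed) {
  seed <- as.integer(seed)   # force the promise before the snapshot
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# stable sub-seed derivation, kept below 2^31
derive_seed <- function(seed, step) {
  (as.numeric(seed) * 48271 + step * 9973) %% 2147483629
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# one-hot rows over K classes for 0-based labels
one_hot <- function(labels, n_classes) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}
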