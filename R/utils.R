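# Internal helpers: deterministic RNG scoping and per-modality seed streams.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
# All randomness in the package flows through this so that a single master
# seed reproduces a cohort or an evaluation exactly.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a namespaced sub-seed from a master seed and a stream label, so each
# modality (signals, genetics, demographics, folds, ...) has an independent,
# individually regenerable stream. Kept strictly below 2^31 - 1.
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147480009 # large prime < 2^31
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer((as.numeric(seed) %% m * 7919 + h) %% m)
}

# Stratified fold assignment: every class is spread as evenly as possible
# across folds. Returns an integer vector of fold ids aligned with `y`.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (lev in levels(y)) {
      idx <- which(y == lev)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
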