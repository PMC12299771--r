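# Internal helpers shared across modules.

# Clip a numeric vector/matrix to [lower, upper] elementwise (bounds recycled
# per column for matrices).
clipTo <- function(x, lower, upper) {
  pmin(pmax(x, lower), upper)
}

# Derive a reproducible per-stage seed from a master seed; keeps the result
# a valid 32-bit integer.
stageSeed <- function(seed, stage) {
  offsets <- c(split = 11L, preprocess = 23L, fs = 37L, tune = 53L,
               train = 71L, data = 97L, eval = 113L)
  if (!stage %in% names(offsets))
    stop("unknown stage: ", stage)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% .Machine$integer.max)
}

# Stratified fold assignment: returns an integer vector of fold ids in
# 1..nfolds, balanced within every class, deterministic under the current
# RNG state.
stratifiedFolds <- function(y, nfolds) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state
# afterwards so seeded subroutines do not disturb enclosing random streams.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

jsonWrite <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

jsonRead <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
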