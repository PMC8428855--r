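# Internal helpers: seeding and small numerics.

#' Derive a child seed from a master seed
#'
#' A splittable counter: each (seed, key) pair maps deterministically to an
#' integer below 2^31 - 1 so that independent generator components get
#' independent, reproducible RNG streams from one master seed.
#'
#' @param seed integer master seed.
#' @param key integer stream index.
#' @return integer seed.
#' @export
childSeed <- function(seed, key) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 + as.numeric(key) * 7919 + 1
  as.integer(s %% m)
}

# Evaluate code under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# RMS of a mean-subtracted vector.
rmsCentered <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# log2(CPM + 1) of a counts (or linear expression) matrix, genes x cells.
log2cpm <- function(counts) {
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  log2(sweep(counts, 2, cs, "/") * 1e6 + 1)
}
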