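#' @useDynLib gasfeeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a child seed from a parent seed and an index
#'
#' A dataset-level seed fans out to one child seed per signal so that any
#' subset of signals is reproducible independently of the batch size it was
#' generated in. The map is a fixed affine hash modulo the largest 32-bit
#' prime; all operands stay below 2^53 so the arithmetic is exact in doubles.
#'
#' @param seed parent seed (integer-valued scalar).
#' @param index 1-based child index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  s <- (abs(as.numeric(seed)) %% 2147483647)
  as.integer((1000003 * s + 7919 * as.numeric(index) + 12345) %% 2147483647)
}

# Lightweight structural fingerprint of an R object: two position-weighted
# checksums over its serialized bytes (weights cycle with coprime periods, so
# reorderings change the hash). Used for config hashes and frozen-artifact
# checks; all arithmetic stays below 2^53 and is exact in doubles.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the serialization header (carries R version info)
  bytes <- bytes[-seq_len(14)]
  n <- length(bytes)
  i <- seq_len(n)
  w1 <- ((i %% 65536) * 40503 + 17) %% 65521
  w2 <- ((i %% 8191) * 12289 + i %% 127) %% 8191
  h1 <- (sum((bytes + 1) * w1) + n) %% 2147483647
  h2 <- (sum((bytes + 1) * (w2 + 1)) + 31 * n) %% 2147483647
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

stop_gasfeeg <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gasfeeg_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
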