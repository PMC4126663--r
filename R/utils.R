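# Seed management. One master seed per experiment; per-run seeds are derived
# with a fixed golden-ratio stride modulo 2^31 - 1 so that (a) runs are
# independent of how many other runs exist, and (b) derived seeds stay inside
# the 32-bit integer range whatever small master seed the caller supplies.

.SEED_MODULUS <- 2147483647  # 2^31 - 1
.SEED_STRIDE <- 1327217885   # floor((2^31 - 1) / golden ratio), coprime with modulus

#' Derive a reproducible stream of run seeds from one master seed
#'
#' @param master integer master seed
#' @param n number of seeds
#' @param stream optional stream offset, so distinct consumers (for example
#'   different experimental conditions) draw from disjoint seed sequences
#' @return integer vector of length `n`
#' @export
seed_stream <- function(master, n, stream = 0L) {
  if (!is.numeric(master) || length(master) != 1L || is.na(master))
    stop("`master` must be a single integer seed")
  base <- (abs(as.numeric(master)) + 104729 * as.numeric(stream)) %% .SEED_MODULUS
  idx <- seq_len(n)
  as.integer((base + idx * .SEED_STRIDE) %% .SEED_MODULUS)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had.
with_local_seed <- function(seed, expr) {
  # force the seed before snapshotting the RNG state: evaluating it may
  # itself consume the caller's RNG (e.g. seed = sample.int(...))
  seed <- as.integer(as.numeric(seed) %% .SEED_MODULUS)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be a single number")
  if (positive && x <= 0) stop("`", name, "` must be positive")
  invisible(x)
}
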