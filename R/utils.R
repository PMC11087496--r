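# Small internal helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a temporary RNG seed when one is given, leaving the
# caller's RNG state untouched; with seed = NULL the current RNG is used.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Centered moving average with edge replication; width in samples.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L || length(x) < 2L) return(x)
  k <- stats::filter(x, rep(1 / width, width), sides = 2)
  k <- as.numeric(k)
  # fill the NA edges with the nearest computed value
  idx <- which(!is.na(k))
  if (length(idx) == 0) return(x)
  k[seq_len(idx[1] - 1)] <- k[idx[1]]
  k[seq(idx[length(idx)] + 1, length.out = length(k) - idx[length(idx)])] <-
    k[idx[length(idx)]]
  k
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2)))

# Population standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
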