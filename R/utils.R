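logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

sigmoid <- function(x) 1 / (1 + exp(-x))

# all 2^n binary configurations as an (2^n x n) 0/1 matrix, n <= 20
binary_states <- function(n) {
  stopifnot(n >= 1, n <= 20)
  k <- 2^n
  m <- matrix(0L, nrow = k, ncol = n)
  for (j in seq_len(n)) m[, j] <- bitwAnd(0:(k - 1), bitwShiftL(1L, j - 1L)) > 0L
  storage.mode(m) <- "double"
  m
}

# seeds derived from a master seed, kept well below .Machine$integer.max
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 100000L) * 10000L + 7L * seq_len(n)
}
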