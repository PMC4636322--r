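# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths wherever they check one.

# exact AR(1) discretization of the OU process
# dtheta = lambda (mu - theta) dt + sqrt(2 b T) dW, sampled every dt_s
ou_ensemble <- function(n_synapses, n_samples, b, sigma = 1, mu = 0.5,
                        temperature = 1, dt_s = 1800, theta0 = NULL) {
  lambda <- b / sigma^2
  a <- exp(-lambda * dt_s)
  s_inf <- sigma * sqrt(temperature)
  s_step <- s_inf * sqrt(1 - a^2)
  th <- if (is.null(theta0)) rnorm(n_synapses, mu, s_inf) else
    rep_len(theta0, n_synapses)
  out <- matrix(NA_real_, n_samples, n_synapses)
  out[1, ] <- th
  for (i in seq_len(n_samples - 1)) {
    th <- mu + a * (th - mu) + s_step * rnorm(n_synapses)
    out[i + 1, ] <- th
  }
  out
}

# brute-force expectation of the CD-1 weight statistic for a tiny RBM by
# enumerating the wake and reconstruction kernels
cd1_expectation_oracle <- function(params, visible) {
  H <- length(params$hidden_bias)
  V <- length(params$visible_bias)
  sig <- function(x) 1 / (1 + exp(-x))
  hs <- as.matrix(expand.grid(rep(list(0:1), H)))
  vs <- as.matrix(expand.grid(rep(list(0:1), V)))
  p_h_given_v <- function(v) {
    p1 <- sig(drop(params$weights %*% v) + params$hidden_bias)
    apply(hs, 1, function(h) prod(ifelse(h == 1, p1, 1 - p1)))
  }
  p_v_given_h <- function(h) {
    p1 <- sig(drop(crossprod(params$weights, h)) + params$visible_bias)
    apply(vs, 1, function(v) prod(ifelse(v == 1, p1, 1 - p1)))
  }
  ew <- matrix(0, H, V)
  pw <- p_h_given_v(visible)
  for (i in seq_len(nrow(hs))) {
    h <- hs[i, ]
    wake <- tcrossprod(h, visible)
    pv <- p_v_given_h(h)
    recon <- matrix(0, H, V)
    for (j in seq_len(nrow(vs))) {
      v2 <- vs[j, ]
      ph2 <- p_h_given_v(v2)
      eh2 <- drop(ph2 %*% hs)
      recon <- recon + pv[j] * tcrossprod(eh2, v2)
    }
    ew <- ew + pw[i] * (wake - recon)
  }
  ew
}

# trapezoidal integral (local, independent of the package's helpers)
trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

binary_states_for_test <- function(n) {
  m <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(m) <- NULL
  m
}
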