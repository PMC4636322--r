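test_that("conditional sampling follows the logistic rule", {
  set.seed(1)
  p <- rbm_init(6, 4, weight_sd = 0)
  p$weights[] <- 0
  p$hidden_bias[] <- 0
  p$visible_bias[] <- 0
  v <- rep(1, 6)
  draws <- replicate(4000, sample_hidden_given_visible(p, v))
  expect_equal(rowMeans(draws), rep(0.5, 4), tolerance = 0.05)
  p$hidden_bias[] <- -50
  expect_equal(sample_hidden_given_visible(p, v), rep(0, 4))
  # empirical firing rate tracks sigma(u) within binomial error
  set.seed(2)
  p2 <- rbm_init(5, 3)
  v2 <- rbinom(5, 1, 0.5)
  u <- drop(p2$weights %*% v2) + p2$hidden_bias
  n <- 1e4
  f <- rowMeans(replicate(n, sample_hidden_given_visible(p2, v2)))
  pr <- 1 / (1 + exp(-u))
  expect_true(all(abs(f - pr) <= 3 * sqrt(pr * (1 - pr) / n) + 1e-9))
})

test_that("CD statistics are bounded and vanish at deterministic fixed points", {
  set.seed(3)
  p <- rbm_init(4, 3)
  st <- cd_statistics(p, rbinom(4, 1, 0.5), k = 5)
  expect_true(all(abs(st$wake_w - st$recon_w) <= 1))
  expect_true(all(st$wake_w %in% 0:1))
  # weights forcing a deterministic fixed point: reconstruction == wake
  p2 <- rbm_init(3, 2, weight_sd = 0)
  p2$weights <- matrix(100, 2, 3)
  p2$hidden_bias <- rep(100, 2)
  p2$visible_bias <- rep(100, 3)
  st2 <- cd_statistics(p2, rep(1, 3), k = 5)
  expect_equal(st2$wake_w, st2$recon_w)
  expect_equal(st2$wake_h, st2$recon_h)
})

test_that("CD-1 expectation matches kernel enumeration on a tiny RBM", {
  set.seed(4)
  p <- rbm_init(3, 2)  # 2 hidden, 3 visible
  v <- c(1, 0, 1)
  oracle <- cd1_expectation_oracle(p, v)
  n <- 2e4
  acc <- matrix(0, 2, 3)
  acc2 <- matrix(0, 2, 3)
  for (i in seq_len(n)) {
    st <- cd_statistics(p, v, k = 1)
    d <- st$wake_w - st$recon_w
    acc <- acc + d
    acc2 <- acc2 + d^2
  }
  m <- acc / n
  se <- sqrt(pmax(acc2 / n - m^2, 1e-12) / n)
  expect_true(all(abs(m - oracle) <= 3 * se + 1e-3))
})

test_that("exact likelihood agrees across enumeration routes", {
  # zero-parameter model is uniform over visible states
  p0 <- rbm_init(8, 3, weight_sd = 0, bias_mean = 0, bias_sd = 0)
  expect_equal(exact_log_likelihood(p0, rbinom(8, 1, 0.5)), -8 * log(2))
  set.seed(5)
  for (dims in list(c(3, 2), c(4, 3), c(2, 3))) {
    p <- rbm_init(dims[1], dims[2])
    pats <- binary_states_for_test(dims[1])
    expect_equal(exact_log_likelihood(p, pats, "hidden"),
                 exact_log_likelihood(p, pats, "joint"),
                 tolerance = 1e-10)
    # probabilities over the full visible space sum to one
    ll <- vapply(seq_len(nrow(pats)), function(i)
      exact_log_likelihood(p, pats[i, , drop = FALSE]), numeric(1))
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
  }
  # duplicating the whole pattern set leaves the mean unchanged
  set.seed(6)
  p <- rbm_init(5, 2)
  pats <- matrix(rbinom(20, 1, 0.4), 4, 5)
  expect_equal(exact_log_likelihood(p, rbind(pats, pats)),
               exact_log_likelihood(p, pats))
  expect_error(exact_log_likelihood(rbm_init(3, 21), c(1, 0, 1)), "20")
})

test_that("sampling updates follow the parameter rule", {
  set.seed(7)
  p <- rbm_init(4, 2)
  zero_stats <- structure(list(
    wake_w = matrix(0, 2, 4), recon_w = matrix(0, 2, 4),
    wake_h = rep(0, 2), recon_h = rep(0, 2),
    wake_v = rep(0, 4), recon_v = rep(0, 4)), class = "cd_statistics")
  nz <- list(w = matrix(0, 2, 4), h = rep(0, 2), v = rep(0, 4))
  p2 <- rbm_sampling_update(p, zero_stats, uniform_prior(), noise = nz)
  expect_equal(p2$weights, p$weights)
  expect_equal(p2$hidden_bias, p$hidden_bias)
  # unit wake statistic, zero reconstruction: deterministic part is eta*N
  st <- zero_stats
  st$wake_w <- matrix(1, 2, 4)
  p3 <- rbm_sampling_update(p, st, uniform_prior(), eta = 1e-4, N = 100,
                            noise = nz)
  expect_equal(p3$weights - p$weights, matrix(1e-2, 2, 4))
})

test_that("noise-only updates accumulate random-walk variance 2 eta n", {
  set.seed(8)
  p <- rbm_init(30, 20, weight_sd = 0)
  p$weights[] <- 0
  zero_stats <- structure(list(
    wake_w = matrix(0, 20, 30), recon_w = matrix(0, 20, 30),
    wake_h = rep(0, 20), recon_h = rep(0, 20),
    wake_v = rep(0, 30), recon_v = rep(0, 30)), class = "cd_statistics")
  eta <- 1e-3
  n <- 200
  for (i in seq_len(n))
    p <- rbm_sampling_update(p, zero_stats, uniform_prior(), eta = eta)
  v <- var(as.vector(p$weights))
  expect_equal(v, 2 * eta * n, tolerance = 0.15)
})

test_that("zero-update experiment returns the initial likelihoods", {
  set.seed(9)
  pats <- digit_pattern_generator(1, n_train = 3, n_test = 6,
                                  image_side = 5)
  r <- train_generalization_experiment(pats$train, pats$test,
                                       n_updates = 0, eval_every = 100,
                                       n_hidden = 3, seed = 10)
  expect_length(r$train_ll, 1)
  set.seed(10)
  p0 <- rbm_init(25, 3)
  expect_equal(r$train_ll[1], exact_log_likelihood(p0, pats$train))
  expect_equal(sum(r$weight_histogram$counts), 75)
})
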