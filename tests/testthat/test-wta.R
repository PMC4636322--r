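test_that("EPSP kernel has the right support, zero and peak", {
  expect_equal(epsp_kernel(-0.001), 0)
  expect_equal(epsp_kernel(0), 0)
  # analytic peak time tau_r tau_f / (tau_f - tau_r) * log(tau_f / tau_r)
  tpk <- 0.002 * 0.02 / (0.02 - 0.002) * log(10)
  expect_equal(tpk, 0.00512, tolerance = 1e-2)
  s <- seq(0, 0.05, by = 1e-5)
  expect_equal(s[which.max(epsp_kernel(s))], tpk, tolerance = 1e-2)
})

test_that("divisive inhibition yields exact softmax rates", {
  expect_equal(wta_firing_rates(rep(2, 10)), rep(10, 10))
  set.seed(1)
  for (i in 1:20) {
    u <- rnorm(10, sd = 30)  # overflow-safe even for large potentials
    r <- wta_firing_rates(u)
    expect_equal(sum(r), 100)
    expect_true(all(r >= 0))
  }
  r <- wta_firing_rates(c(5, rep(0, 9)))
  expect_equal(r[1], 100 * exp(5) / (exp(5) + 9), tolerance = 1e-12)
  expect_equal(r[1], 94.28, tolerance = 1e-3)
})

test_that("parameter-to-weight mapping implements retraction", {
  s <- synapse_state(c(-5, -0.001, 0, 0.001, 2), theta0 = 3)
  expect_true(all(s$w_eff[1:3] == 0))
  expect_true(all(s$w_eff[4:5] > 0))
  expect_true(all(diff(s$w) > 0))
  # below-zero parameters map to weights under 0.05
  expect_equal(synapse_state(0)$w, exp(-3))
  expect_lte(synapse_state(0)$w, 0.05)
  # matrix input keeps dimensions
  m <- synapse_state(matrix(c(-1, 1, 2, -2), 2, 2))
  expect_equal(dim(m$w_eff), c(2, 2))
})

test_that("stochastic STDP rule has the documented structure", {
  pr <- gaussian_prior(0.5, 1)
  # no postsynaptic spike: pure prior drift (OU form)
  th <- stdp_sampling_update(0.2, FALSE, x_pre = 1, prior = pr,
                             b = 1e-4, dt = 0.001, noise = 0)
  expect_equal(th, 0.2 + 1e-4 * 0.3 * 0.001)
  # likelihood fixed point: x = alpha e^w leaves theta to the prior drift
  th0 <- 1.2
  w <- exp(th0 - 3)
  th_fp <- stdp_sampling_update(th0, TRUE, x_pre = exp(-2) * exp(w),
                                prior = pr, noise = 0)
  th_np <- stdp_sampling_update(th0, FALSE, x_pre = 0, prior = pr,
                                noise = 0)
  expect_equal(th_fp, th_np)
  # retraction suppresses the likelihood term by the weight ratio e^-7
  jump <- function(th) {
    with_spike <- stdp_sampling_update(th, TRUE, x_pre = 1,
                                       prior = pr, noise = 0,
                                       max_jump = Inf)
    without <- stdp_sampling_update(th, FALSE, x_pre = 1, prior = pr,
                                    noise = 0)
    with_spike - without
  }
  expect_equal(jump(-4) / jump(3), exp(-4 - 3) *
                 (1 - exp(-2) * exp(exp(-7))) /
                 (1 - exp(-2) * exp(1)), tolerance = 1e-6)
  # weight factor ratio w(-4)/w(3) = e^-7 ~ 9e-4 suppresses the drift
  expect_lt(abs(jump(-4)), 2e-3 * abs(jump(3)))
  # clamps: jumps clipped at max_jump, parameters at clip_low
  expect_equal(stdp_sampling_update(-5, FALSE, 0, pr, noise = -10), -5)
})

test_that("a silent circuit fires uniformly at rho_net / K", {
  set.seed(21)
  net <- wta_network(n_inputs = 5, K = 10)
  res <- simulate_network(net, matrix(0, 5, 1), 100, plasticity = FALSE)
  rate <- as.vector(res$counts) / 100
  expect_true(all(abs(rate - 10) <= 3 * sqrt(10 / 100) + 1e-9))
})

test_that("simulation is reproducible and validates dt", {
  net <- wta_network(n_inputs = 3, K = 4)
  set.seed(5)
  a <- simulate_network(net, matrix(20, 3, 2), 0.5, record_spikes = TRUE)
  set.seed(5)
  b <- simulate_network(net, matrix(20, 3, 2), 0.5, record_spikes = TRUE)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$net$state$theta_ff, b$net$state$theta_ff)
  net$params$dt <- 0.002
  expect_error(simulate_network(net, matrix(0, 3, 1), 1), "1 ms")
})

test_that("explicit input spike trains drive the circuit", {
  set.seed(6)
  net <- wta_network(n_inputs = 2, K = 2)
  net$state$theta_ff[] <- 4  # strong synapses
  ev <- data.frame(neuron = rep(1, 40), time = seq(0.005, 0.2, by = 0.005))
  res <- simulate_wta(net, ev, duration = 0.25, record_rates = TRUE)
  # rate conservation holds every step despite strong drive
  expect_equal(colSums(res$rho), rep(100, ncol(res$rho)), tolerance = 1e-9)
})

test_that("adaptation homeostatically evens out firing rates", {
  set.seed(7)
  base <- wta_network(n_inputs = 4, K = 10)
  base$state$theta_ff[1, ] <- 4   # one neuron strongly favored
  rates <- matrix(30, 4, 1)
  noad <- base; noad$params$gamma <- 0
  r1 <- simulate_network(base, rates, 200, plasticity = FALSE)
  r0 <- simulate_network(noad, rates, 200, plasticity = FALSE)
  expect_lt(var(as.vector(r1$counts)), var(as.vector(r0$counts)))
})

test_that("prior-only parameter dynamics is the OU process", {
  # likelihood term disabled: stationary sd sigma sqrt(T) and
  # autocovariance time constant sigma^2 / b
  set.seed(8)
  b <- 5e-3
  net <- wta_network(n_inputs = 40, K = 10, params = list(b = b))
  rates <- matrix(0, 40, 1)
  burn <- simulate_network(net, rates, 400, likelihood = FALSE)$net
  snaps <- list()
  net2 <- burn
  for (i in 1:120) {
    net2 <- simulate_network(net2, rates, 10, likelihood = FALSE)$net
    snaps[[i]] <- as.vector(net2$state$theta_ff)
  }
  tr <- do.call(rbind, snaps)   # 120 samples x 400 synapses, dt = 10 s
  expect_equal(sd(tr), 1, tolerance = 0.1)
  # lag-k autocorrelation of the pooled ensemble decays as exp(-b k dt)
  ac <- sapply(1:6, function(k) {
    a <- tr[seq_len(120 - k), ]; bb <- tr[-seq_len(k), ]
    mean((a - 0.5) * (bb - 0.5)) / mean((tr - 0.5)^2)
  })
  tau_hat <- -1 / coef(lm(log(pmax(ac, 1e-3)) ~ seq_along(ac)))[[2]] * 10
  expect_equal(tau_hat, 1 / b, tolerance = 0.15)
})

test_that("recurrent architecture respects modality and delay contracts", {
  set.seed(9)
  net <- recurrent_wta_network(c(6, 8), wta_per_ensemble = 2, K = 5)
  H <- 2 * 2 * 5
  expect_equal(dim(net$state$theta_ff), c(H, 14))
  # no feedforward synapse crosses modalities
  m <- net$state$mask_ff
  expect_true(all(m[net$ensemble == 1, net$modality_of_input == 2] == 0))
  expect_true(all(m[net$ensemble == 2, net$modality_of_input == 1] == 0))
  expect_equal(net$params$delay_steps, 5L)
  # banned autapses are retracted
  expect_true(all(diag(net$state$theta_lat) <= 0))
  # functional lateral fraction at initialization ~ Phi(mu/sigma)
  off <- net$state$theta_lat[row(net$state$ban_lat) != col(net$state$ban_lat)]
  p_hat <- mean(off > 0)
  p_th <- pnorm(0.5)
  expect_lt(abs(p_hat - p_th),
            3 * sqrt(p_th * (1 - p_th) / length(off)) + 0.02)
})

test_that("lesions remove function and banned synapses never regrow", {
  set.seed(10)
  net <- recurrent_wta_network(c(4, 4), wta_per_ensemble = 1, K = 5)
  expect_error(lesion_neurons(net, 99), "unknown")
  expect_error(lesion_neurons(net, integer(0)), "empty")
  net2 <- lesion_neurons(net, c(1, 2))
  expect_equal(sum(net2$state$alive), 8)
  res <- simulate_network(net2, matrix(20, 8, 1), 2, record_spikes = TRUE)
  expect_false(any(res$spikes$neuron %in% c(1, 2)))
  # lateral lesion with regrowth ban
  net3 <- lesion_lateral_synapses(net, "functional")
  w <- synapse_state(net3$state$theta_lat)$w_eff
  w[net3$state$ban_lat == 0] <- 0
  expect_true(all(w == 0))
  net4 <- simulate_network(net3, matrix(30, 8, 10), 0.2)$net
  banned <- net4$state$ban_lat == 1L
  expect_true(all(net4$state$theta_lat[banned] <= 0))
})

test_that("stimulus reconstruction weights efficacies by rates", {
  set.seed(11)
  net <- wta_network(n_inputs = 6, K = 3)
  expect_equal(reconstruct_stimulus(net, rep(0, 3)), rep(0, 6))
  one <- c(0, 1, 0)
  img <- reconstruct_stimulus(net, one)
  w2 <- synapse_state(net$state$theta_ff[2, ])$w_eff
  expect_equal(img, w2 / max(w2))
})

test_that("PETH is linear in trials and localizes single events", {
  empty <- peth(data.frame(neuron = integer(0), time = numeric(0)),
                n_neurons = 3, duration = 0.5)
  expect_true(all(empty$peth == 0))
  one <- peth(data.frame(neuron = 2, time = 0.1), 3, 0.5)
  expect_lte(abs(one$bin_centers[one$peak_bin[2]] - 0.1), 0.011)
  two <- peth(data.frame(neuron = c(2, 2), time = c(0.1, 0.1)), 3, 0.5)
  expect_equal(two$peth, 2 * one$peth)
})
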