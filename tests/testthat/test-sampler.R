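cfg0 <- sampler_config(b = 1, dt = 0.01)

test_that("discrete step vanishes without drift or noise", {
  model <- gradient_model(uniform_prior())
  th <- c(-0.3, 0.2, 1.5)
  expect_identical(discrete_step(th, model, cfg0, noise = rep(0, 3)), th)
  # Gaussian prior at its mode: zero prior gradient, zero step
  model2 <- gradient_model(gaussian_prior(0.5, 1))
  expect_equal(discrete_step(rep(0.5, 4), model2, cfg0, noise = rep(0, 4)),
               rep(0.5, 4))
})

test_that("steps are deterministic given noise and validate inputs", {
  model <- gradient_model(gaussian_prior(0, 1))
  set.seed(1)
  nz <- rnorm(3)
  th <- c(0.1, -0.2, 0.4)
  expect_identical(discrete_step(th, model, cfg0, noise = nz),
                   discrete_step(th, model, cfg0, noise = nz))
  expect_error(discrete_step(th, model, cfg0, noise = rnorm(2)), "length")
  bad <- gradient_model(function(theta) c(0, NaN, 0))
  expect_error(discrete_step(th, bad, cfg0, noise = nz), "index 2")
})

test_that("batch and online steps agree where the spec says they must", {
  lg <- function(theta, x) x - theta
  model <- gradient_model(gaussian_prior(0, 1), likelihood_grad = lg)
  th <- c(0.3, -0.1)
  nz <- c(0.5, -0.7)
  # N = 1: batch over one input equals the online step with N = 1
  expect_equal(batch_step(th, model, cfg0, list(c(1, 2)), noise = nz),
               discrete_step(th, model, cfg0, minibatch = c(1, 2),
                             noise = nz))
  # N identical inputs: batch drift equals the online (N-multiplied) drift
  cfgN <- sampler_config(b = 1, dt = 0.01, N = 7)
  expect_equal(batch_step(th, model, cfg0,
                          rep(list(c(1, 2)), 7), noise = nz),
               discrete_step(th, model, cfgN, minibatch = c(1, 2),
                             noise = nz))
  expect_error(batch_step(th, model, cfg0, list()), "empty")
})

test_that("run_chain is seeded, thinned and reproducible", {
  model <- gradient_model(gaussian_prior(0.5, 1))
  cfg <- sampler_config(b = 1, dt = 0.01, seed = 99)
  tr1 <- run_chain(0, model, cfg, n_steps = 1, thin = 1)
  expect_equal(nrow(tr1), 1)
  tr <- run_chain(c(0, 1), model, cfg, n_steps = 50, thin = 1)
  tr2 <- run_chain(c(0, 1), model, cfg, n_steps = 50, thin = 1)
  expect_identical(unclass(tr), unclass(tr2))
  trb <- run_chain(c(0, 1), model, cfg, n_steps = 50, thin = 2)
  expect_equal(trb[, 1:2], unclass(tr)[seq(2, 50, by = 2), ])
})

test_that("long prior-only chain matches the analytic stationary law", {
  # 2e5 total scalar steps; mean and variance against Normal(0.5, 1)
  model <- gradient_model(gaussian_prior(0.5, 1))
  cfg <- sampler_config(b = 1, dt = 0.01, seed = 5,
                        max_step = Inf, clip_low = -Inf)
  tr <- run_chain(rep(0.5, 10), model, cfg, n_steps = 2e4, thin = 10,
                  burn_in = 2e3)
  x <- as.vector(tr)
  n_eff <- 10 * 1800 / (2 / (1 * 0.01))  # chains x steps / (2 tau)
  expect_lt(abs(mean(x) - 0.5), 3 / sqrt(n_eff))
  expect_lt(abs(var(x) - 1), 3 * sqrt(2 / n_eff))
})

test_that("tempered reference densities follow closed forms", {
  grid <- seq(-8.5, 9.5, length.out = 4001)
  r1 <- reference_posterior_density(gaussian_prior(0.5, 1),
                                    temperature = 1, grid = grid)
  expect_equal(r1$density, dnorm(grid, 0.5, 1), tolerance = 1e-6)
  # temperature flattens: Gaussian^(1/T) has variance T sigma^2
  r2 <- reference_posterior_density(gaussian_prior(0.5, 1),
                                    temperature = 2, grid = grid)
  expect_equal(r2$density, dnorm(grid, 0.5, sqrt(2)), tolerance = 1e-6)
  # conjugate Gaussian prior x Gaussian likelihood: closed-form posterior
  x_obs <- 1.2; s_lik <- 0.7
  rp <- reference_posterior_density(
    gaussian_prior(0.5, 1),
    loglik_fn = function(th) dnorm(x_obs, th, s_lik, log = TRUE),
    temperature = 1, grid = grid)
  post_var <- 1 / (1 / 1^2 + 1 / s_lik^2)
  post_mean <- post_var * (0.5 / 1^2 + x_obs / s_lik^2)
  expect_equal(rp$density, dnorm(grid, post_mean, sqrt(post_var)),
               tolerance = 1e-6)
  expect_warning(
    reference_posterior_density(gaussian_prior(0, 1), temperature = 1,
                                grid = seq(-1, 1, length.out = 101)),
    "narrow")
})

test_that("Fokker-Planck oracle solves linear and double-well drifts", {
  grid <- seq(-8, 9, length.out = 4001)
  b <- 0.3
  for (Temp in c(0.5, 1, 2)) {
    fp <- fokker_planck_stationary(
      drift_fn = function(th) b * (0.5 - th) / 1,
      diffusion_fn = function(th) rep(b * Temp, length(th)),
      grid = grid)
    expect_equal(fp$density, dnorm(grid, 0.5, sqrt(Temp)),
                 tolerance = 1e-6)
  }
  # halving the diffusion with fixed drift sharpens: variance halves
  fp2 <- fokker_planck_stationary(function(th) b * (0.5 - th),
                                  function(th) rep(b / 2, length(th)),
                                  grid)
  expect_equal(trap(grid, fp2$density * (grid - 0.5)^2), 0.5,
               tolerance = 1e-3)
  # cross-check against the tempered-posterior oracle on a double well
  g2 <- seq(-0.8, 1.8, length.out = 4001)
  pr <- mixture_prior()
  lg <- function(th) (0.6 - th) / 0.5^2
  ll <- function(th) dnorm(0.6, th, 0.5, log = TRUE)
  ref <- reference_posterior_density(pr, ll, 1, g2)
  fp3 <- fokker_planck_stationary(
    function(th) grad_log_density(pr, th) + lg(th),
    function(th) rep(1, length(th)), g2)
  expect_lt(trap(g2, abs(ref$density - fp3$density)) / 2, 1e-6)
  expect_error(fokker_planck_stationary(function(th) th,
                                        function(th) th - 1, grid),
               "positive")
})

test_that("clamps are inert when inactive and binding when not", {
  model <- gradient_model(gaussian_prior(0.5, 1))
  cfg_cl <- sampler_config(b = 1, dt = 0.01, seed = 3)     # defaults
  cfg_un <- sampler_config(b = 1, dt = 0.01, seed = 3,
                           max_step = Inf, clip_low = -Inf)
  tr_cl <- run_chain(rep(0.5, 5), model, cfg_cl, n_steps = 200)
  tr_un <- run_chain(rep(0.5, 5), model, cfg_un, n_steps = 200)
  expect_identical(unclass(tr_cl), unclass(tr_un))
  # clip_low projects and max_step caps
  cfg_b <- sampler_config(b = 1, dt = 0.01, max_step = 0.001,
                          clip_low = -0.05)
  th <- discrete_step(c(0, -0.05), gradient_model(function(t) c(-1e3, -1e3)),
                      cfg_b, noise = c(0, 0))
  expect_equal(th, c(-0.001, -0.05))
})

test_that("tv_distance and density_cdf behave on exact samples", {
  set.seed(11)
  grid <- seq(-4.5, 5.5, length.out = 2001)
  ref <- reference_posterior_density(gaussian_prior(0.5, 1), grid = grid)
  x <- rnorm(5e4, 0.5, 1)
  expect_lt(tv_distance(x, ref), 0.03)
  cdf <- density_cdf(ref)
  expect_equal(cdf(0.5), 0.5, tolerance = 1e-3)
})
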