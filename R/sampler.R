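#' Configuration of the stochastic parameter sampler
#'
#' Bundles the constants of the sampling dynamics
#' \deqn{d\theta_i = \big(b(\theta_i)\,\partial_i \log p_S(\theta)
#'   + N\, b(\theta_i)\,\partial_i \log p_L(x^n\mid\theta)
#'   + T\, b'(\theta_i)\big)\,dt + \sqrt{2 T b(\theta_i)}\, dW_i,}
#' whose unique stationary distribution is the posterior raised to the power
#' `1/T`. `N` is the dataset size multiplier of the online rule (use `N = 1`
#' with [batch_step()]). A parameter-dependent sampling speed is supplied as a
#' function `b_fn` together with its analytic derivative `b_grad_fn`; the
#' `T b'(theta)` drift correction keeps the stationary distribution unchanged.
#'
#' @param b Learning rate (sampling speed), a positive scalar. Ignored by the
#'   drift when `b_fn` is given, but still used for the `max_step` default.
#' @param dt Integration time step (same time units as `b`).
#' @param temperature Diffusion temperature `T >= 0`; `T = 1` samples the
#'   posterior, `T -> 0` approaches MAP convergence.
#' @param N Dataset size for the online rule.
#' @param seed Optional integer seed, used by [run_chain()].
#' @param b_fn,b_grad_fn Optional sampling-speed function `b(theta)` (must be
#'   strictly positive) and its analytic derivative. Both or neither.
#' @param clip_low Lower clamp for parameters after each update (default -5).
#' @param max_step Clamp on the magnitude of each instantaneous parameter
#'   change (default `5 * b`).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(b, dt, temperature = 1, N = 1, seed = NULL,
                           b_fn = NULL, b_grad_fn = NULL,
                           clip_low = -5, max_step = 5 * b) {
  stopifnot(is.numeric(b), length(b) == 1, b > 0,
            is.numeric(dt), length(dt) == 1, dt > 0,
            temperature >= 0, N >= 1, N == round(N), max_step > 0)
  if (xor(is.null(b_fn), is.null(b_grad_fn)))
    stop("supply both `b_fn` and its analytic derivative `b_grad_fn`, or neither")
  structure(list(b = b, dt = dt, temperature = temperature, N = as.integer(N),
                 seed = seed, b_fn = b_fn, b_grad_fn = b_grad_fn,
                 clip_low = clip_low, max_step = max_step, eta = b * dt),
            class = "sampler_config")
}

#' @export
print.sampler_config <- function(x, ...) {
  cat(sprintf(
    "sampler_config: b = %g%s, T = %g, dt = %g (eta = %g), N = %d\n",
    x$b, if (!is.null(x$b_fn)) " [state-dependent b(theta)]" else "",
    x$temperature, x$dt, x$eta, x$N))
  cat(sprintf("  clip_low = %g, max_step = %g, seed = %s\n",
              x$clip_low, x$max_step,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}

#' Gradient model: prior and likelihood score functions
#'
#' @param prior Either a prior object (see [gaussian_prior()]) applied
#'   elementwise, or a function `theta -> gradient vector`.
#' @param likelihood_grad Function `(theta, minibatch) -> gradient vector`
#'   returning the score of one input (or of an input with its sampled hidden
#'   state), or `NULL` for prior-only dynamics.
#' @return An object of class `gradient_model`.
#' @export
gradient_model <- function(prior = uniform_prior(), likelihood_grad = NULL) {
  prior_grad <- if (is.function(prior)) prior
                else function(theta) grad_log_density(prior, theta)
  structure(list(prior_grad = prior_grad, likelihood_grad = likelihood_grad),
            class = "gradient_model")
}

check_grad <- function(g, m, what) {
  if (length(g) != m)
    stop(sprintf("%s gradient has length %d, expected %d", what, length(g), m))
  if (!all(is.finite(g)))
    stop(sprintf("non-finite %s gradient at parameter index %d",
                 what, which(!is.finite(g))[1]))
  g
}

sampler_drift_diffusion <- function(theta, cfg) {
  if (is.null(cfg$b_fn)) {
    list(b = rep(cfg$b, length(theta)), bprime = rep(0, length(theta)))
  } else {
    bv <- cfg$b_fn(theta)
    if (any(bv <= 0)) stop("b(theta) must be strictly positive")
    list(b = bv, bprime = cfg$b_grad_fn(theta))
  }
}

apply_step <- function(theta, dtheta, cfg) {
  dtheta <- pmin(pmax(dtheta, -cfg$max_step), cfg$max_step)
  theta2 <- pmax(theta + dtheta, cfg$clip_low)
  if (!all(is.finite(theta2)))
    stop(sprintf("non-finite parameter after update at index %d",
                 which(!is.finite(theta2))[1]))
  theta2
}

#' One discrete-time update of the online sampling rule
#'
#' Performs the Euler--Maruyama step
#' \deqn{\Delta\theta_i = \Delta t\,[\,b(\theta_i) \partial_i \log p_S
#'  + N b(\theta_i) \partial_i \log p_L(x^n\mid\theta) + T b'(\theta_i)\,]
#'  + \sqrt{2 T \Delta t\, b(\theta_i)}\;\nu_i,}
#' then clamps each `|Delta theta_i|` at `cfg$max_step` and each parameter at
#' `cfg$clip_low`. Deterministic given `(theta, minibatch, noise)`.
#'
#' @param theta Numeric parameter vector.
#' @param model A [gradient_model()].
#' @param cfg A [sampler_config()].
#' @param minibatch One input `x^n` (passed to the likelihood gradient);
#'   ignored when the model has no likelihood term.
#' @param noise Standard-normal vector of the same length as `theta`.
#' @return Updated parameter vector.
#' @export
discrete_step <- function(theta, model, cfg, minibatch = NULL,
                          noise = stats::rnorm(length(theta))) {
  m <- length(theta)
  if (length(noise) != m)
    stop(sprintf("noise has length %d, expected %d", length(noise), m))
  bb <- sampler_drift_diffusion(theta, cfg)
  drift <- bb$b * check_grad(model$prior_grad(theta), m, "prior") +
    cfg$temperature * bb$bprime
  if (!is.null(model$likelihood_grad)) {
    drift <- drift + cfg$N * bb$b *
      check_grad(model$likelihood_grad(theta, minibatch), m, "likelihood")
  }
  dtheta <- cfg$dt * drift + sqrt(2 * cfg$temperature * cfg$dt * bb$b) * noise
  apply_step(theta, dtheta, cfg)
}

#' One batch update of the sampling rule
#'
#' As [discrete_step()], but the likelihood drift is the sum of scores over
#' the complete dataset, with no `N` multiplier.
#'
#' @inheritParams discrete_step
#' @param dataset List (or vector treated as a list) of all inputs
#'   `x^1, ..., x^N`.
#' @return Updated parameter vector.
#' @export
batch_step <- function(theta, model, cfg, dataset,
                       noise = stats::rnorm(length(theta))) {
  if (length(dataset) == 0) stop("empty dataset in batch_step")
  m <- length(theta)
  if (length(noise) != m)
    stop(sprintf("noise has length %d, expected %d", length(noise), m))
  bb <- sampler_drift_diffusion(theta, cfg)
  drift <- bb$b * check_grad(model$prior_grad(theta), m, "prior") +
    cfg$temperature * bb$bprime
  if (!is.null(model$likelihood_grad)) {
    lsum <- rep(0, m)
    for (x in dataset)
      lsum <- lsum + check_grad(model$likelihood_grad(theta, x), m,
                                "likelihood")
    drift <- drift + bb$b * lsum
  }
  dtheta <- cfg$dt * drift + sqrt(2 * cfg$temperature * cfg$dt * bb$b) * noise
  apply_step(theta, dtheta, cfg)
}

#' Run a sampling chain
#'
#' Iterates [discrete_step()] from `theta0`, drawing one standard-normal
#' noise vector per step in fixed parameter order from a generator seeded by
#' `cfg$seed`, so runs are bit-reproducible. Because priors factorize and the
#' noise is drawn elementwise, a vector `theta0` with a prior-only model runs
#' `length(theta0)` independent scalar chains in parallel.
#'
#' @inheritParams discrete_step
#' @param theta0 Initial parameter vector.
#' @param n_steps Number of steps (`>= 1`).
#' @param thin Keep every `thin`-th state.
#' @param data_stream `NULL`, a list of inputs cycled in order, or a function
#'   `step -> minibatch`.
#' @param burn_in Number of initial steps discarded before thinning.
#' @return Matrix with one retained state per row (class
#'   `sampler_trajectory`, with attributes `thin` and `burn_in`).
#' @export
run_chain <- function(theta0, model, cfg, n_steps, thin = 1,
                      data_stream = NULL, burn_in = 0) {
  stopifnot(n_steps >= 1, thin >= 1, burn_in >= 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- length(theta0)
  kept <- floor((n_steps - burn_in) / thin)
  out <- matrix(NA_real_, nrow = kept, ncol = m)
  theta <- theta0
  j <- 0L
  get_batch <- if (is.null(data_stream)) function(s) NULL
    else if (is.function(data_stream)) data_stream
    else function(s) data_stream[[(s - 1L) %% length(data_stream) + 1L]]
  for (s in seq_len(n_steps)) {
    theta <- discrete_step(theta, model, cfg, minibatch = get_batch(s),
                           noise = stats::rnorm(m))
    if (s > burn_in && (s - burn_in) %% thin == 0L) {
      j <- j + 1L
      out[j, ] <- theta
    }
  }
  structure(out[seq_len(j), , drop = FALSE], class = "sampler_trajectory",
            thin = thin, burn_in = burn_in)
}

new_reference_density <- function(grid, density) {
  Z <- pracma::trapz(grid, density)
  density <- density / Z
  structure(list(grid = grid, density = density, normalizer_Z = Z),
            class = "reference_density")
}

#' @export
print.reference_density <- function(x, ...) {
  cat(sprintf("reference_density on [%g, %g] (%d grid points), Z = %g\n",
              min(x$grid), max(x$grid), length(x$grid), x$normalizer_Z))
  invisible(x)
}

#' Tempered posterior density on a grid (analytic oracle)
#'
#' Computes `p(theta) \propto [p_S(theta) * p_L(x | theta)]^(1/T)` for a
#' scalar parameter on a grid and normalizes by trapezoidal quadrature. This
#' is the stationary distribution the sampler must reproduce, computed
#' without simulating.
#'
#' @param prior A prior object.
#' @param loglik_fn Vectorized function `theta -> log p_L(x | theta)`, or
#'   `NULL` for a prior-only target.
#' @param temperature Temperature `T > 0`.
#' @param grid Ordered numeric grid covering essentially all posterior mass.
#' @return A `reference_density` (grid, normalized density, normalizer).
#' @export
reference_posterior_density <- function(prior, loglik_fn = NULL,
                                        temperature = 1, grid) {
  stopifnot(temperature > 0, !is.unsorted(grid))
  lp <- log_density(prior, grid)
  if (!is.null(loglik_fn)) lp <- lp + loglik_fn(grid)
  lp <- lp / temperature
  q <- exp(lp - max(lp))
  if (max(q[c(1, length(q))]) > 1e-4 * max(q))
    warning("grid too narrow: boundary density exceeds 1e-4 of the maximum")
  new_reference_density(grid, q)
}

#' Stationary density of a 1-D diffusion (Fokker--Planck oracle)
#'
#' For the Ito diffusion `dtheta = A(theta) dt + sqrt(2 D(theta)) dW`, the
#' zero-flux stationary solution of the Fokker--Planck equation is
#' `p(theta) \propto (1 / D(theta)) exp( integral A/D dtheta )`, computed by
#' cumulative trapezoidal integration and normalized. This oracle is
#' independent of any sampling: it only uses the drift and diffusion
#' functions, and is the reference against which simulated chains are
#' validated.
#'
#' @param drift_fn Vectorized drift `A(theta)` (the full drift, including any
#'   `T b'(theta)` correction).
#' @param diffusion_fn Vectorized diffusion coefficient `D(theta) > 0` (for
#'   the sampling rule, `D = T b(theta)`).
#' @param grid Ordered numeric grid.
#' @return A `reference_density`.
#' @export
fokker_planck_stationary <- function(drift_fn, diffusion_fn, grid) {
  stopifnot(!is.unsorted(grid))
  D <- diffusion_fn(grid)
  if (any(D <= 0)) stop("diffusion coefficient must be strictly positive")
  integ <- drift_fn(grid) / D
  ci <- pracma::cumtrapz(grid, integ)[, 1]
  lp <- ci - log(D)
  new_reference_density(grid, exp(lp - max(lp)))
}

#' Cumulative distribution function of a reference density
#'
#' @param ref A `reference_density`.
#' @return A vectorized function `theta -> P(Theta <= theta)` suitable for
#'   [stats::ks.test()].
#' @export
density_cdf <- function(ref) {
  cdf <- pracma::cumtrapz(ref$grid, ref$density)[, 1]
  cdf <- cdf / cdf[length(cdf)]
  stats::approxfun(ref$grid, cdf, yleft = 0, yright = 1, rule = 2)
}

#' Total variation distance between a sample histogram and a density
#'
#' Bins the samples on `breaks` spanning the reference grid and compares bin
#' masses with the integrals of the reference density over the same bins.
#'
#' @param samples Numeric sample vector.
#' @param ref A `reference_density`.
#' @param breaks Number of equal-width bins.
#' @return Total variation distance in `[0, 1]`.
#' @export
tv_distance <- function(samples, ref, breaks = 40) {
  edges <- seq(min(ref$grid), max(ref$grid), length.out = breaks + 1)
  cdf <- density_cdf(ref)
  pref <- diff(cdf(edges))
  pref <- pref / sum(pref)
  cnt <- tabulate(findInterval(samples, edges, all.inside = TRUE),
                  nbins = breaks)
  0.5 * sum(abs(cnt / sum(cnt) - pref))
}
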