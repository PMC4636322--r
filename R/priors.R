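#' Structural priors over synaptic parameters
#'
#' Priors encode structural rules for network parameters (e.g. preferred
#' weight magnitudes, sparse connectivity). They enter the sampling dynamics
#' only through the gradient of their log-density, so every prior object
#' provides [log_density()] and [grad_log_density()]. Priors factorize over
#' parameters: all objects are scalar priors applied elementwise to a
#' parameter vector.
#'
#' @param mean,sd Mean and standard deviation of the Gaussian.
#' @return An object of class `synsampler_prior`.
#' @examples
#' pr <- gaussian_prior(0.5, 1)
#' grad_log_density(pr, 0)   # (mu - theta) / sigma^2 = 0.5
#' @export
gaussian_prior <- function(mean = 0.5, sd = 1) {
  stopifnot(is.finite(mean), is.finite(sd), sd > 0)
  structure(list(mean = mean, sd = sd),
            class = c("gaussian_prior", "synsampler_prior"))
}

#' Gaussian mixture prior
#'
#' A mixture of Gaussians over a scalar parameter. The bimodal two-component
#' form (modes near 0 and 1, narrow components) models weight distributions
#' with a large population of silent/small synapses and a small population of
#' strong ones. Defaults are equal weights, means 1 and 0, and component
#' standard deviations 0.15.
#'
#' @param weights Mixture weights; must be non-negative and sum to 1.
#' @param means,sds Component means and standard deviations.
#' @return An object of class `synsampler_prior`.
#' @export
mixture_prior <- function(weights = c(0.5, 0.5), means = c(1, 0),
                          sds = c(0.15, 0.15)) {
  stopifnot(length(weights) == length(means), length(means) == length(sds),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-12, all(sds > 0))
  structure(list(weights = weights, means = means, sds = sds),
            class = c("mixture_prior", "synsampler_prior"))
}

#' Uninformative (uniform, improper) prior
#'
#' Its gradient is identically zero, so sampling under it reduces to
#' likelihood-driven dynamics plus diffusion (the maximum-likelihood limit of
#' the drift). `log_density()` returns 0 by convention.
#'
#' @return An object of class `synsampler_prior`.
#' @export
uniform_prior <- function() {
  structure(list(), class = c("uniform_prior", "synsampler_prior"))
}

#' Log-density of a prior
#'
#' @param prior A prior object.
#' @param theta Numeric vector of parameter values.
#' @return Numeric vector of log-densities (0 for the uniform prior).
#' @export
log_density <- function(prior, theta) UseMethod("log_density")

#' @export
log_density.gaussian_prior <- function(prior, theta) {
  stats::dnorm(theta, prior$mean, prior$sd, log = TRUE)
}

#' @export
log_density.mixture_prior <- function(prior, theta) {
  lw <- vapply(seq_along(prior$weights), function(j) {
    log(prior$weights[j]) +
      stats::dnorm(theta, prior$means[j], prior$sds[j], log = TRUE)
  }, numeric(length(theta)))
  lw <- matrix(lw, nrow = length(theta))
  m <- apply(lw, 1, max)
  m + log(rowSums(exp(lw - m)))
}

#' @export
log_density.uniform_prior <- function(prior, theta) {
  rep(0, length(theta))
}

#' Gradient of the log-density of a prior
#'
#' For the Gaussian prior this is `(mean - theta) / sd^2`; for the mixture it
#' is the responsibility-weighted sum of component gradients; for the uniform
#' prior it is exactly zero.
#'
#' @inheritParams log_density
#' @return Numeric vector, same length as `theta`.
#' @export
grad_log_density <- function(prior, theta) UseMethod("grad_log_density")

#' @export
grad_log_density.gaussian_prior <- function(prior, theta) {
  (prior$mean - theta) / prior$sd^2
}

#' @export
grad_log_density.mixture_prior <- function(prior, theta) {
  lw <- vapply(seq_along(prior$weights), function(j) {
    log(prior$weights[j]) +
      stats::dnorm(theta, prior$means[j], prior$sds[j], log = TRUE)
  }, numeric(length(theta)))
  lw <- matrix(lw, nrow = length(theta))
  m <- apply(lw, 1, max)
  resp <- exp(lw - m)
  resp <- resp / rowSums(resp)
  grads <- vapply(seq_along(prior$weights), function(j) {
    (prior$means[j] - theta) / prior$sds[j]^2
  }, numeric(length(theta)))
  rowSums(resp * matrix(grads, nrow = length(theta)))
}

#' @export
grad_log_density.uniform_prior <- function(prior, theta) {
  rep(0, length(theta))
}

#' Draw samples from a prior
#'
#' Used to initialize synaptic parameters ("initial parameters drawn from the
#' prior"). The uniform prior is improper and cannot be sampled.
#'
#' @param prior A prior object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_prior <- function(prior, n) UseMethod("sample_prior")

#' @export
sample_prior.gaussian_prior <- function(prior, n) {
  stats::rnorm(n, prior$mean, prior$sd)
}

#' @export
sample_prior.mixture_prior <- function(prior, n) {
  j <- sample.int(length(prior$weights), n, replace = TRUE,
                  prob = prior$weights)
  stats::rnorm(n, prior$means[j], prior$sds[j])
}

#' @export
sample_prior.uniform_prior <- function(prior, n) {
  stop("the uniform prior is improper and cannot be sampled")
}

#' @export
print.synsampler_prior <- function(x, ...) {
  cls <- class(x)[1]
  if (cls == "gaussian_prior") {
    cat(sprintf("Gaussian prior: mean %.3g, sd %.3g\n", x$mean, x$sd))
  } else if (cls == "mixture_prior") {
    cat(sprintf("Gaussian mixture prior (%d components)\n",
                length(x$weights)))
    cat("  weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
    cat("  means:  ", paste(signif(x$means, 3), collapse = ", "), "\n")
    cat("  sds:    ", paste(signif(x$sds, 3), collapse = ", "), "\n")
  } else {
    cat("Uninformative (uniform, improper) prior: gradient identically 0\n")
  }
  invisible(x)
}
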