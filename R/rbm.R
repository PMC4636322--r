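#' Restricted Boltzmann machine with sampled parameters
#'
#' An RBM with one layer of binary visible units and one layer of binary
#' hidden units, bidirectional symmetric weights, and logistic-sigmoid
#' conditionals. Parameters are trained by the online sampling rule: the
#' contrastive-divergence estimate of the likelihood gradient is combined
#' with a prior gradient on the weights and Gaussian noise of variance
#' `2 eta` per update.
#'
#' @param n_visible,n_hidden Layer sizes.
#' @param weight_mean,weight_sd Initial weights are Normal(`weight_mean`,
#'   `weight_sd`); defaults 0 and 0.25.
#' @param bias_mean,bias_sd Initial biases are Normal(`bias_mean`,
#'   `bias_sd`); defaults -1 and 0.25.
#' @return An object of class `rbm` with elements `weights`
#'   (`n_hidden x n_visible`), `hidden_bias`, `visible_bias`.
#' @export
rbm_init <- function(n_visible, n_hidden, weight_mean = 0, weight_sd = 0.25,
                     bias_mean = -1, bias_sd = 0.25) {
  structure(list(
    weights = matrix(stats::rnorm(n_hidden * n_visible, weight_mean,
                                  weight_sd), n_hidden, n_visible),
    hidden_bias = stats::rnorm(n_hidden, bias_mean, bias_sd),
    visible_bias = stats::rnorm(n_visible, bias_mean, bias_sd)),
    class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat(sprintf("rbm: %d visible, %d hidden units\n",
              length(x$visible_bias), length(x$hidden_bias)))
  invisible(x)
}

#' Sample hidden units given visible units
#'
#' Each hidden unit fires independently with probability
#' `sigma(sum_j w_ij y_j + b_i)`.
#'
#' @param params An [rbm_init()] object.
#' @param visible Binary vector of visible activities.
#' @return Binary vector of hidden activities.
#' @export
sample_hidden_given_visible <- function(params, visible) {
  stopifnot(length(visible) == ncol(params$weights))
  p <- sigmoid(drop(params$weights %*% visible) + params$hidden_bias)
  as.numeric(stats::runif(length(p)) < p)
}

#' Sample visible units given hidden units
#'
#' @param params An [rbm_init()] object.
#' @param hidden Binary vector of hidden activities.
#' @return Binary vector of visible activities.
#' @export
sample_visible_given_hidden <- function(params, hidden) {
  stopifnot(length(hidden) == nrow(params$weights))
  p <- sigmoid(drop(crossprod(params$weights, hidden)) + params$visible_bias)
  as.numeric(stats::runif(length(p)) < p)
}

#' Contrastive-divergence statistics (CD-k)
#'
#' Wake phase: the visible layer is clamped to the input and the hidden layer
#' is sampled once. Reconstruction phase: starting from that hidden state,
#' `k` alternating cycles of visible and hidden updates are performed; the
#' states after the final cycle are the reconstruction samples. All phases
#' use sampled binary states.
#'
#' @param params An [rbm_init()] object.
#' @param visible Binary input vector.
#' @param k Number of reconstruction cycles (default 5).
#' @return An object of class `cd_statistics` with the wake and
#'   reconstruction outer products (`wake_w`, `recon_w`) and unit states
#'   (`wake_h`, `recon_h`, `wake_v`, `recon_v`).
#' @export
cd_statistics <- function(params, visible, k = 5) {
  stopifnot(k >= 1)
  z <- sample_hidden_given_visible(params, visible)
  zr <- z
  vr <- visible
  for (cycle in seq_len(k)) {
    vr <- sample_visible_given_hidden(params, zr)
    zr <- sample_hidden_given_visible(params, vr)
  }
  structure(list(wake_w = tcrossprod(z, visible), recon_w = tcrossprod(zr, vr),
                 wake_h = z, recon_h = zr, wake_v = visible, recon_v = vr),
            class = "cd_statistics")
}

#' One parameter-sampling update of an RBM
#'
#' Applies
#' `Delta w_ij = eta * (d/dw log p_S(w) + N * (z_i x_j - zhat_i xhat_j)) +
#' sqrt(2 eta) nu_ij` to the weights, and the analogous rule without a prior
#' term to the biases (biases carry no prior).
#'
#' @param params An [rbm_init()] object.
#' @param stats A [cd_statistics()] object.
#' @param prior Prior object for the weights (elementwise).
#' @param eta Learning rate per update (`eta = b * dt`), default 1e-4.
#' @param N Dataset-size multiplier of the online rule, default 100.
#' @param noise Optional list with entries `w`, `h`, `v` of standard-normal
#'   deviates (matching dimensions); drawn internally when `NULL`.
#' @return Updated `rbm` object.
#' @export
rbm_sampling_update <- function(params, stats, prior = uniform_prior(),
                                eta = 1e-4, N = 100, noise = NULL) {
  stopifnot(eta > 0, N >= 1)
  W <- params$weights
  if (is.null(noise)) {
    noise <- list(w = matrix(stats::rnorm(length(W)), nrow(W), ncol(W)),
                  h = stats::rnorm(length(params$hidden_bias)),
                  v = stats::rnorm(length(params$visible_bias)))
  }
  pg <- matrix(grad_log_density(prior, as.vector(W)), nrow(W), ncol(W))
  sq <- sqrt(2 * eta)
  params$weights <- W + eta * (pg + N * (stats$wake_w - stats$recon_w)) +
    sq * noise$w
  params$hidden_bias <- params$hidden_bias +
    eta * N * (stats$wake_h - stats$recon_h) + sq * noise$h
  params$visible_bias <- params$visible_bias +
    eta * N * (stats$wake_v - stats$recon_v) + sq * noise$v
  params
}

#' Exact mean log-likelihood of binary patterns under an RBM
#'
#' Computes `log p(x)` exactly. With `method = "hidden"` the hidden layer is
#' enumerated: the partition function and the unnormalized marginal are sums
#' over all `2^H` hidden configurations (feasible for `H <= 20`). With
#' `method = "joint"` both layers are enumerated (tiny models only); the two
#' routes agree to numerical precision and serve as mutual cross-checks.
#'
#' @param params An [rbm_init()] object.
#' @param patterns Binary matrix, one pattern per row (a single pattern may
#'   be given as a vector).
#' @param method `"hidden"` (default) or `"joint"`.
#' @return Mean of `log p(x)` over the patterns.
#' @export
exact_log_likelihood <- function(params, patterns,
                                 method = c("hidden", "joint")) {
  method <- match.arg(method)
  if (is.null(dim(patterns))) patterns <- matrix(patterns, nrow = 1)
  H <- length(params$hidden_bias)
  V <- length(params$visible_bias)
  stopifnot(ncol(patterns) == V)
  if (method == "hidden") {
    if (H > 20)
      stop("hidden-layer enumeration supports at most 20 hidden units; ",
           "use fewer hidden units or an estimator outside this package")
    hs <- binary_states(H)                                 # 2^H x H
    # log Z by enumerating hidden states and summing out the visibles
    act_v <- hs %*% params$weights                          # 2^H x V
    act_v <- sweep(act_v, 2, params$visible_bias, "+")
    logZ <- logsumexp(drop(hs %*% params$hidden_bias) +
                      rowSums(softplus(act_v)))
    # unnormalized log marginal of each pattern, hiddens summed analytically
    act_h <- patterns %*% t(params$weights)                 # P x H
    act_h <- sweep(act_h, 2, params$hidden_bias, "+")
    ll <- drop(patterns %*% params$visible_bias) +
      rowSums(softplus(act_h)) - logZ
    mean(ll)
  } else {
    if (H > 12 || V > 12)
      stop("joint enumeration is intended for tiny cross-check models")
    hs <- binary_states(H)
    vs <- binary_states(V)
    # log unnormalized joint over the full state space
    joint <- hs %*% params$weights %*% t(vs) +
      drop(hs %*% params$hidden_bias) +
      rep(1, nrow(hs)) %o% drop(vs %*% params$visible_bias)
    logZ <- logsumexp(as.vector(joint))
    ll <- vapply(seq_len(nrow(patterns)), function(p) {
      x <- patterns[p, ]
      logsumexp(drop(hs %*% params$weights %*% x) +
                drop(hs %*% params$hidden_bias) +
                sum(params$visible_bias * x)) - logZ
    }, numeric(1))
    mean(ll)
  }
}

#' Generalization experiment: learning curves under a weight prior
#'
#' Trains an RBM on a small set of repeatedly presented patterns with the
#' parameter-sampling rule and tracks exact train/test mean log-likelihood.
#' With an uninformative prior this reproduces the overfitting signature
#' (test performance peaks, then degrades with prolonged learning); with a
#' bimodal weight prior the test performance is maintained and the final
#' weight histogram concentrates near the prior modes.
#'
#' @param train,test Binary pattern matrices (patterns in rows, equal width).
#' @param prior Weight prior (elementwise).
#' @param n_updates Number of single-pattern update steps.
#' @param eval_every Evaluation cadence in update steps.
#' @param eta,N,cd_k Sampling-rule constants (defaults 1e-4, 100, 5).
#' @param n_hidden Number of hidden units (default 9).
#' @param seed Optional integer seed.
#' @return List with `steps`, `train_ll`, `test_ll`, final `params`, and
#'   `weight_histogram` (80 equal bins on `[-4, 4]`: `mids`, `counts`).
#' @export
train_generalization_experiment <- function(train, test,
                                            prior = uniform_prior(),
                                            n_updates = 20000,
                                            eval_every = 1000,
                                            eta = 1e-4, N = 100, cd_k = 5,
                                            n_hidden = 9, seed = NULL) {
  stopifnot(ncol(train) == ncol(test))
  if (!is.null(seed)) set.seed(seed)
  params <- rbm_init(ncol(train), n_hidden)
  eval_steps <- c(0, if (n_updates >= eval_every)
    seq(eval_every, n_updates, by = eval_every))
  train_ll <- test_ll <- numeric(length(eval_steps))
  train_ll[1] <- exact_log_likelihood(params, train)
  test_ll[1] <- exact_log_likelihood(params, test)
  j <- 1L
  for (s in seq_len(n_updates)) {
    x <- train[sample.int(nrow(train), 1), ]
    params <- rbm_sampling_update(params, cd_statistics(params, x, k = cd_k),
                                  prior = prior, eta = eta, N = N)
    if (s %% eval_every == 0) {
      j <- j + 1L
      train_ll[j] <- exact_log_likelihood(params, train)
      test_ll[j] <- exact_log_likelihood(params, test)
    }
  }
  edges <- seq(-4, 4, length.out = 81)
  w <- pmin(pmax(as.vector(params$weights), -4), 4)
  counts <- tabulate(findInterval(w, edges, all.inside = TRUE), nbins = 80)
  list(steps = eval_steps, train_ll = train_ll, test_ll = test_ll,
       params = params,
       weight_histogram = list(mids = (edges[-81] + edges[-1]) / 2,
                               counts = counts))
}
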