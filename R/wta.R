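#' @useDynLib synsampler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

default_wta_params <- function() {
  list(dt = 0.001, rho_net = 100, tau_r = 0.002, tau_f = 0.02,
       adapt_tau_r = 12, adapt_tau_f = 30, gamma = -8,
       b = 1e-4, N = 100, alpha = exp(-2), theta0 = 3,
       prior_mean = 0.5, prior_sd = 1, temperature = 1,
       clip_low = -5, delay_steps = 0L)
}

#' Double-exponential EPSP kernel
#'
#' `epsilon(s) = Theta(s) (exp(-s/tau_f) - exp(-s/tau_r))`, the shape of one
#' postsynaptic potential; zero for `s < 0`, zero at `s = 0`, peaking at
#' `s = tau_r tau_f / (tau_f - tau_r) * log(tau_f / tau_r)`.
#'
#' @param s Time since the presynaptic spike, in seconds (vectorized).
#' @param tau_r,tau_f Rise and fall time constants in seconds (defaults
#'   0.002 and 0.02).
#' @return Kernel values.
#' @export
epsp_kernel <- function(s, tau_r = 0.002, tau_f = 0.02) {
  stopifnot(tau_f > tau_r, tau_r > 0)
  ifelse(s >= 0, exp(-s / tau_f) - exp(-s / tau_r), 0)
}

#' Instantaneous firing rates under divisive inhibition
#'
#' `rho_k = rho_net * exp(u_k) / sum_l exp(u_l)`, computed overflow-safe.
#' The rates sum exactly to `rho_net` for any membrane potentials.
#'
#' @param u Vector of membrane potentials.
#' @param rho_net Total circuit rate in Hz (default 100).
#' @return Rate vector in Hz.
#' @export
wta_firing_rates <- function(u, rho_net = 100) {
  stopifnot(all(is.finite(u)))
  e <- exp(u - max(u))
  rho_net * e / sum(e)
}

#' Synapse state under the exponential parameter-to-weight mapping
#'
#' `w = exp(theta - theta0)`; the effective (transmitting) weight is
#' `w_eff = max(0, w - exp(-theta0))`, which is exactly zero whenever
#' `theta <= 0`: negative parameters encode retracted, non-functional
#' synapses whose efficacy is clipped to zero.
#'
#' @param theta Parameter value(s).
#' @param theta0 Mapping offset (default 3).
#' @return List with `theta`, `w`, `w_eff`.
#' @export
synapse_state <- function(theta, theta0 = 3) {
  w <- exp(theta - theta0)
  list(theta = theta, w = w, w_eff = pmax(w - exp(-theta0), 0))
}

#' One discrete update of the stochastic STDP sampling rule
#'
#' Reference (R-level) implementation of the synaptic sampling rule for
#' spiking networks: over a step of length `dt` the parameter receives the
#' prior drift `b (mu - theta)/sigma^2 dt` and diffusion
#' `sqrt(2 b T dt) nu`; at a postsynaptic spike it additionally receives the
#' likelihood jump `b N w (x_pre - alpha exp(w))`, clipped at
#' `+/- max_jump`. The compiled simulator applies the identical rule; this
#' function is the single-synapse contract used for testing and analysis.
#'
#' @param theta Current parameter value(s).
#' @param post_spike Logical: did the postsynaptic neuron spike in this step?
#' @param x_pre Weight-normalized presynaptic EPSP trace at the spike time.
#' @param prior A [gaussian_prior()].
#' @param b,N,alpha,theta0 Rule constants (defaults 1e-4, 100, `exp(-2)`, 3).
#' @param dt Step length in seconds.
#' @param temperature Diffusion temperature (default 1).
#' @param noise Standard-normal deviate(s).
#' @param max_jump Clip on the instantaneous likelihood jump (default `5 b`).
#' @param clip_low Lower parameter clamp (default -5).
#' @return Updated parameter value(s).
#' @export
stdp_sampling_update <- function(theta, post_spike, x_pre,
                                 prior = gaussian_prior(0.5, 1),
                                 b = 1e-4, N = 100, alpha = exp(-2),
                                 theta0 = 3, dt = 0.001, temperature = 1,
                                 noise = stats::rnorm(length(theta)),
                                 max_jump = 5 * b, clip_low = -5) {
  dth <- b * grad_log_density(prior, theta) * dt +
    sqrt(2 * b * temperature * dt) * noise
  if (post_spike) {
    w <- exp(theta - theta0)
    jump <- b * N * w * (x_pre - alpha * exp(w))
    dth <- dth + pmin(pmax(jump, -max_jump), max_jump)
  }
  pmax(theta + dth, clip_low)
}

init_traces <- function(H, n_in, delay_steps) {
  list(in_rise = numeric(n_in), in_fall = numeric(n_in),
       lat_rise = numeric(H), lat_fall = numeric(H),
       beta_rise = numeric(H), beta_fall = numeric(H),
       delay_buf = matrix(0, H, delay_steps + 1L), ring_pos = 0L)
}

#' Spiking winner-take-all circuit
#'
#' A single ensemble of `K` stochastic spike-response neurons under
#' idealized divisive inhibition, fully connected to `n_inputs` afferents.
#' Initial synaptic parameters are drawn independently from the prior.
#'
#' @param n_inputs Number of input neurons.
#' @param K Circuit size (default 10).
#' @param prior Gaussian structural prior; also sets the prior drift of the
#'   sampling rule.
#' @param params Named list overriding entries of the default neuron/rule
#'   constants (`dt`, `rho_net`, `tau_r`, `tau_f`, `adapt_tau_r`,
#'   `adapt_tau_f`, `gamma`, `b`, `N`, `alpha`, `theta0`, `temperature`,
#'   `clip_low`).
#' @return Object of class `wta_network`.
#' @export
wta_network <- function(n_inputs, K = 10, prior = gaussian_prior(0.5, 1),
                        params = list()) {
  p <- utils::modifyList(default_wta_params(), params)
  p$prior_mean <- prior$mean
  p$prior_sd <- prior$sd
  if (is.null(p$max_jump)) p$max_jump <- 5 * p$b
  st <- c(list(
    theta_ff = matrix(sample_prior(prior, K * n_inputs), K, n_inputs),
    mask_ff = matrix(1L, K, n_inputs),
    theta_lat = NULL, ban_lat = NULL,
    alive = rep(1L, K), circuit = rep(1L, K)),
    init_traces(K, n_inputs, 0L))
  structure(list(state = st, params = p, n_inputs = n_inputs, K = K,
                 modality = NULL),
            class = "wta_network")
}

#' Recurrent multi-ensemble network of WTA circuits
#'
#' Several ensembles of WTA circuits, each ensemble receiving feedforward
#' input exclusively from its own input modality, with unconstrained
#' (potentially all-to-all, delayed) lateral excitatory synapses among all
#' hidden neurons. All synapses, feedforward and lateral, follow the same
#' sampling rule; lateral transmission and the lateral plasticity trace use
#' the same delay. A single ensemble without lateral synapses reduces to
#' [wta_network()].
#'
#' @param modality_sizes Integer vector: number of input neurons per
#'   modality (one ensemble per modality).
#' @param wta_per_ensemble WTA circuits per ensemble (default 4).
#' @param K Neurons per WTA circuit (default 10).
#' @param lateral_delay Lateral synaptic delay in seconds (default 0.005).
#' @param prior Gaussian structural prior.
#' @param params Overrides as in [wta_network()].
#' @return Object of class `wta_network` (with lateral synapses).
#' @export
recurrent_wta_network <- function(modality_sizes, wta_per_ensemble = 4,
                                  K = 10, lateral_delay = 0.005,
                                  prior = gaussian_prior(0.5, 1),
                                  params = list()) {
  p <- utils::modifyList(default_wta_params(), params)
  p$prior_mean <- prior$mean
  p$prior_sd <- prior$sd
  if (is.null(p$max_jump)) p$max_jump <- 5 * p$b
  n_mod <- length(modality_sizes)
  H <- n_mod * wta_per_ensemble * K
  n_in <- sum(modality_sizes)
  ensemble <- rep(seq_len(n_mod), each = wta_per_ensemble * K)
  circuit <- rep(seq_len(n_mod * wta_per_ensemble), each = K)
  modality_of_input <- rep(seq_len(n_mod), modality_sizes)
  mask_ff <- matrix(0L, H, n_in)
  for (m in seq_len(n_mod))
    mask_ff[ensemble == m, modality_of_input == m] <- 1L
  p$delay_steps <- as.integer(round(lateral_delay / p$dt))
  ban <- matrix(0L, H, H)
  diag(ban) <- 1L  # no autapses
  theta_lat <- matrix(sample_prior(prior, H * H), H, H)
  diag(theta_lat) <- p$clip_low  # banned synapses are retracted
  st <- c(list(
    theta_ff = matrix(sample_prior(prior, H * n_in), H, n_in),
    mask_ff = mask_ff,
    theta_lat = theta_lat,
    ban_lat = ban,
    alive = rep(1L, H), circuit = as.integer(circuit)),
    init_traces(H, n_in, p$delay_steps))
  structure(list(state = st, params = p, n_inputs = n_in, K = K,
                 ensemble = ensemble,
                 modality_of_input = modality_of_input),
            class = "wta_network")
}

#' @export
print.wta_network <- function(x, ...) {
  H <- length(x$state$alive)
  cat(sprintf("wta_network: %d hidden neurons (%d alive) in %d circuit(s), %d inputs\n",
              H, sum(x$state$alive), max(x$state$circuit), x$n_inputs))
  if (!is.null(x$state$theta_lat))
    cat(sprintf("  lateral synapses: %d functional, %d banned (delay %d ms)\n",
                n_functional_lateral(x), sum(x$state$ban_lat),
                x$params$delay_steps))
  invisible(x)
}

#' Simulate a network on a sequence of rate frames
#'
#' Time-stepped simulation: per step the EPSP and adaptation traces decay
#' exactly, membrane potentials and softmax rates are computed, spikes are
#' drawn by Bernoulli thinning (`p = rho_k dt`), and (when plasticity is on)
#' synaptic parameters are updated: likelihood jumps at postsynaptic
#' spikes, prior drift and diffusion integrated per frame. Input spikes are
#' drawn as Poisson trains from the per-frame rates, or supplied explicitly
#' as an event list.
#'
#' @param net A [wta_network()] / [recurrent_wta_network()].
#' @param rates Matrix `n_inputs x n_frames` of input rates in Hz (may be a
#'   single column).
#' @param frame_duration Duration of each frame in seconds (scalar or
#'   vector per frame).
#' @param plasticity,likelihood Enable the sampling rule / its
#'   activity-dependent term (prior-only dynamics when `likelihood =
#'   FALSE`).
#' @param record_spikes,record_rates Return output spikes / per-step rate
#'   matrix.
#' @param input_events Optional data frame with columns `neuron` (1-based)
#'   and `time` (seconds from simulation start); used instead of Poisson
#'   draws.
#' @return List: updated `net`, `counts` (spike counts, neurons x frames),
#'   optional `spikes` data frame (`neuron`, `time`), optional `rho`
#'   (neurons x steps), and `thinning_warning`.
#' @export
simulate_network <- function(net, rates, frame_duration,
                             plasticity = TRUE, likelihood = TRUE,
                             record_spikes = FALSE, record_rates = FALSE,
                             input_events = NULL) {
  if (is.null(dim(rates))) rates <- matrix(rates, ncol = 1)
  stopifnot(nrow(rates) == net$n_inputs)
  dt <- net$params$dt
  if (dt > 0.001 + 1e-12)
    stop("integration step dt must be at most 1 ms")
  steps <- as.integer(round(rep(frame_duration,
                                length.out = ncol(rates)) / dt))
  ev <- NULL
  if (!is.null(input_events)) {
    s <- pmin(as.integer(floor(input_events$time / dt)), sum(steps) - 1L)
    o <- order(s)
    ev <- cbind(step = s[o], input = as.integer(input_events$neuron[o]) - 1L)
  }
  res <- wta_sim_chunk(net$state, net$params, rates, steps,
                       plasticity, likelihood, record_spikes, record_rates,
                       ev)
  if (isTRUE(res$thinning_warning))
    warning("rho * dt exceeded 0.2: Bernoulli thinning of the Poisson ",
            "process is inaccurate at this step size")
  net$state <- res$state
  out <- list(net = net, counts = res$counts,
              thinning_warning = res$thinning_warning)
  if (record_spikes)
    out$spikes <- data.frame(neuron = res$spikes$neuron,
                             time = (res$spikes$step + 0.5) * dt)
  if (record_rates) out$rho <- res$rho
  out
}

#' Simulate a circuit driven by explicit input spike trains
#'
#' Convenience wrapper around [simulate_network()] for a single constant
#' window with inputs given as an event list.
#'
#' @param net A [wta_network()].
#' @param input_spikes Data frame with `neuron` (1-based input index) and
#'   `time` (s).
#' @param duration Simulated duration in seconds.
#' @param plasticity_on Apply the sampling rule (default `FALSE`).
#' @param ... Passed to [simulate_network()].
#' @return See [simulate_network()].
#' @export
simulate_wta <- function(net, input_spikes, duration, plasticity_on = FALSE,
                         ...) {
  rates <- matrix(0, net$n_inputs, 1)
  simulate_network(net, rates, duration, plasticity = plasticity_on,
                   input_events = input_spikes, ...)
}

n_functional_lateral <- function(net) {
  sum(net$state$theta_lat > 0 & net$state$ban_lat == 0L &
        outer(net$state$alive == 1L, net$state$alive == 1L, "&") &
        diag(length(net$state$alive)) == 0)
}

#' Lesion: remove neurons
#'
#' Removes the given hidden neurons and all their incident synapses from the
#' network: they emit no spikes, contribute no lateral input, and their
#' synapses are excluded from all future plasticity.
#'
#' @param net A [wta_network()].
#' @param neuron_ids Integer ids (1-based) of hidden neurons to remove.
#' @return The lesioned network.
#' @export
lesion_neurons <- function(net, neuron_ids) {
  H <- length(net$state$alive)
  if (length(neuron_ids) == 0) stop("empty lesion selection")
  if (any(neuron_ids < 1 | neuron_ids > H)) stop("unknown neuron id")
  net$state$alive[neuron_ids] <- 0L
  net$state$beta_rise[neuron_ids] <- 0
  net$state$beta_fall[neuron_ids] <- 0
  net$state$lat_rise[neuron_ids] <- 0
  net$state$lat_fall[neuron_ids] <- 0
  net$state$delay_buf[neuron_ids, ] <- 0
  net
}

#' Lesion: remove lateral synapses with a regrowth ban
#'
#' Retracts the selected lateral synapses (parameters set to the lower
#' clamp) and flags them non-regrowable: banned synapses are excluded from
#' every future parameter update and can never become functional again.
#'
#' @param net A [wta_network()] with lateral synapses.
#' @param selection `"functional"` (default: all currently functional,
#'   `theta > 0`, lateral synapses) or a two-column matrix of (post, pre)
#'   index pairs.
#' @return The lesioned network.
#' @export
lesion_lateral_synapses <- function(net, selection = "functional") {
  if (is.null(net$state$theta_lat)) stop("network has no lateral synapses")
  if (identical(selection, "functional")) {
    sel <- which(net$state$theta_lat > 0, arr.ind = TRUE)
  } else {
    sel <- selection
    H <- length(net$state$alive)
    if (nrow(sel) == 0) stop("empty lesion selection")
    if (any(sel < 1 | sel > H)) stop("unknown synapse id")
  }
  net$state$ban_lat[sel] <- 1L
  net$state$theta_lat[sel] <- net$params$clip_low
  net
}

#' Reconstruct an input-space stimulus from hidden activity
#'
#' Multiplies the effective efficacies of the feedforward synapses from one
#' input modality by the instantaneous firing rates of the corresponding
#' hidden neurons and normalizes the result to `[0, 1]` for display.
#'
#' @param net A [wta_network()].
#' @param hidden_rates Rate (or mean spike count) vector over all hidden
#'   neurons, non-negative.
#' @param modality Which input modality to reconstruct (default the only /
#'   first one).
#' @return Numeric vector over that modality's input neurons, in `[0, 1]`.
#' @export
reconstruct_stimulus <- function(net, hidden_rates, modality = 1) {
  stopifnot(all(hidden_rates >= 0),
            length(hidden_rates) == length(net$state$alive))
  w_eff <- synapse_state(net$state$theta_ff, net$params$theta0)$w_eff
  w_eff[net$state$mask_ff == 0L] <- 0
  w_eff[net$state$alive == 0L, ] <- 0
  img <- drop(crossprod(w_eff, hidden_rates))
  if (!is.null(net$modality_of_input))
    img <- img[net$modality_of_input == modality]
  if (max(img) > 0) img <- img / max(img)
  img
}

#' Peri-event time histogram
#'
#' Gaussian-filters the spike trains of each trial and sums them in a
#' time-discrete matrix; also reports each neuron's maximum-amplitude bin.
#'
#' @param spikes Data frame with `neuron`, `time` (s, trial-aligned) and
#'   `trial`.
#' @param n_neurons Number of neurons (rows of the output).
#' @param duration Trial duration in seconds.
#' @param filter_sd Gaussian filter width in seconds (default 0.05).
#' @param bin Bin length in seconds (default 0.01).
#' @return List: `peth` (`n_neurons x n_bins`, trial-summed filtered
#'   rates), `bin_centers`, `peak_bin` (per-neuron argmax index).
#' @export
peth <- function(spikes, n_neurons, duration, filter_sd = 0.05, bin = 0.01) {
  centers <- seq(bin / 2, duration - bin / 2 + 1e-12, by = bin)
  m <- matrix(0, n_neurons, length(centers))
  if (nrow(spikes)) {
    for (k in unique(spikes$neuron)) {
      ts <- spikes$time[spikes$neuron == k]
      m[k, ] <- colSums(matrix(
        stats::dnorm(rep(centers, each = length(ts)) - ts, sd = filter_sd),
        nrow = length(ts)))
    }
  }
  list(peth = m, bin_centers = centers, peak_bin = max.col(m, "first"))
}
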