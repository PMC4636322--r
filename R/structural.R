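#' Synapse formation and elimination events from parameter trajectories
#'
#' A synapse is functional when its parameter is positive. Events are
#' detected on the sampling grid itself (no sub-grid interpolation): a
#' formation is a crossing from `theta <= 0` at one sample to `theta > 0` at
#' the next, an elimination the converse.
#'
#' @param theta_trajectory Matrix of parameter samples, one row per sample
#'   time, one column per synapse (a single synapse may be a vector).
#' @param sample_times Strictly increasing vector of sample times, length
#'   `nrow(theta_trajectory)`.
#' @return List with data frames `formation` and `elimination`, each with
#'   columns `synapse` and `time` (the time of the sample at which the new
#'   state was first observed).
#' @export
detect_events <- function(theta_trajectory, sample_times) {
  if (is.null(dim(theta_trajectory)))
    theta_trajectory <- matrix(theta_trajectory, ncol = 1)
  stopifnot(length(sample_times) == nrow(theta_trajectory),
            all(diff(sample_times) > 0))
  on <- theta_trajectory > 0
  ev <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    data.frame(synapse = as.vector(idx[, 2]),
               time = as.vector(sample_times[idx[, 1] + 1L]))
  }
  n <- nrow(on)
  if (n < 2) return(list(formation = ev(matrix(FALSE, 0, 2)),
                         elimination = ev(matrix(FALSE, 0, 2))))
  form <- !on[-n, , drop = FALSE] & on[-1, , drop = FALSE]
  elim <- on[-n, , drop = FALSE] & !on[-1, , drop = FALSE]
  list(formation = ev(form), elimination = ev(elim))
}

#' Formation-rate time series
#'
#' Counts formation events per window of length `window`, optionally
#' normalized by the number of potential synapses.
#'
#' @param events Formation event data frame from [detect_events()].
#' @param window Window length (time units of the events).
#' @param t_max End of the analysis interval (defaults to the last event).
#' @param n_potential Optional number of potential synapses; when given the
#'   counts are divided by it.
#' @return Data frame with `time` (window end) and `rate` (count per
#'   window, or fraction when normalized).
#' @export
formation_rate <- function(events, window, t_max = NULL, n_potential = NULL) {
  stopifnot(window > 0)
  if (is.null(t_max)) t_max <- if (nrow(events)) max(events$time) else window
  edges <- seq(0, t_max + window * 1e-9, by = window)
  if (edges[length(edges)] < t_max) edges <- c(edges, t_max)
  cnt <- tabulate(findInterval(events$time, edges, left.open = TRUE,
                               all.inside = TRUE),
                  nbins = length(edges) - 1)
  rate <- if (is.null(n_potential)) cnt else cnt / n_potential
  data.frame(time = edges[-1], rate = rate)
}

#' Survival curve of newly formed synapses
#'
#' For a cohort of formation events, computes at each lag the fraction of
#' tracked synapses whose parameter is still positive at
#' `formation_time + lag`, on the same sampling grid the trajectories were
#' recorded on. Survival at lag 0 is 1 by definition.
#'
#' @param formation_events Data frame with columns `synapse`, `time` (a
#'   subset of [detect_events()] output defines the cohort).
#' @param theta_trajectory Sample matrix as in [detect_events()].
#' @param sample_times Sample-time vector of the trajectory.
#' @param horizon Largest lag to evaluate, a multiple of the grid spacing.
#' @return Object of class `survival_table`: data frame with `lag`,
#'   `surviving_fraction`, `n_at_risk`; attribute `n_cohort`.
#' @export
survival_curve <- function(formation_events, theta_trajectory, sample_times,
                           horizon) {
  if (is.null(dim(theta_trajectory)))
    theta_trajectory <- matrix(theta_trajectory, ncol = 1)
  dt <- sample_times[2] - sample_times[1]
  lags <- seq(0, horizon, by = dt)
  if (nrow(formation_events) == 0) {
    warning("no formation events: empty survival table")
    out <- data.frame(lag = numeric(0), surviving_fraction = numeric(0),
                      n_at_risk = integer(0))
    return(structure(out, class = c("survival_table", "data.frame"),
                     n_cohort = 0L))
  }
  on <- theta_trajectory > 0
  r0 <- match(round(formation_events$time, 9), round(sample_times, 9))
  if (anyNA(r0)) stop("formation times must lie on the trajectory grid")
  syn <- formation_events$synapse
  # a synapse survives lag L only if present at every grid sample up to L:
  # once eliminated it leaves the surviving set for all later lags
  alive <- rep(TRUE, length(r0))
  frac <- nrisk <- numeric(length(lags))
  nmax <- nrow(on)
  for (j in seq_along(lags)) {
    rows <- r0 + (j - 1L)
    ok <- rows <= nmax
    alive[ok] <- alive[ok] & on[cbind(rows[ok], syn[ok])]
    nrisk[j] <- sum(ok)
    frac[j] <- if (nrisk[j]) mean(alive[ok]) else NA_real_
  }
  # lag 0 is the formation sample itself, where theta > 0 by definition
  out <- data.frame(lag = lags, surviving_fraction = frac, n_at_risk = nrisk)
  structure(out, class = c("survival_table", "data.frame"),
            n_cohort = nrow(formation_events))
}

r_squared <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(if (ss_res < 1e-10) 1 else 0)
  1 - ss_res / ss_tot
}

#' Fit a survival curve
#'
#' Fits either a power law `s(t) = a t^(-gamma)` (lag 0 excluded; the fit is
#' initialized by linear regression in log-log space and refined by
#' nonlinear least squares) or a two-term exponential
#' `s(t) = a exp(-t/tau1) + c exp(-t/tau2)`.
#'
#' @param table A [survival_curve()] result (or data frame with `lag`,
#'   `surviving_fraction`).
#' @param model `"power_law"` or `"two_term_exponential"`.
#' @return Object of class `survival_fit`: list with `model`, `params`
#'   (named vector), `r_squared`, `fitted` (data frame `lag`, `fit`).
#' @export
fit_survival <- function(table, model = c("power_law",
                                          "two_term_exponential")) {
  model <- match.arg(model)
  tab <- table[is.finite(table$surviving_fraction), ]
  if (nrow(tab) < 5) stop("need at least 5 lag points to fit")
  if (model == "power_law") {
    tab <- tab[tab$lag > 0 & tab$surviving_fraction > 0, ]
    lf <- stats::lm(log(surviving_fraction) ~ log(lag), data = tab)
    start <- list(a = exp(stats::coef(lf)[[1]]), g = -stats::coef(lf)[[2]])
    fit <- minpack.lm::nlsLM(surviving_fraction ~ a * lag^(-g), data = tab,
                             start = start,
                             control = minpack.lm::nls.lm.control(maxiter =
                                                                    200))
    params <- stats::coef(fit)
    names(params) <- c("a", "gamma")
    fitted_v <- stats::fitted(fit)
  } else {
    s <- tab$surviving_fraction
    span <- max(tab$lag)
    if (stats::sd(s) < 1e-12) {
      # degenerate flat curve: zero-residual fit by construction
      params <- c(a = s[1] / 2, tau1 = 1e6 * span, c = s[1] / 2,
                  tau2 = 1e6 * span)
      return(structure(list(model = model, params = params, r_squared = 1,
                            fitted = data.frame(lag = tab$lag, fit = s)),
                       class = "survival_fit"))
    }
    starts <- list(
      list(a = max(s[1] - min(s), 1e-3), t1 = span / 10,
           cc = max(min(s), 1e-3), t2 = span * 3),
      list(a = max(s[1] * 0.6, 1e-3), t1 = span / 4,
           cc = max(s[length(s)], 1e-3), t2 = span * 10),
      list(a = 0.5, t1 = span / 20, cc = 0.3, t2 = span))
    fit <- NULL
    for (start in starts) {
      fit <- try(minpack.lm::nlsLM(
        surviving_fraction ~ a * exp(-lag / t1) + cc * exp(-lag / t2),
        data = tab, start = start,
        lower = c(0, span * 1e-4, 0, span * 1e-4),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) break
    }
    if (inherits(fit, "try-error"))
      stop("two-term exponential fit did not converge: ",
           attr(fit, "condition")$message)
    params <- stats::coef(fit)
    names(params) <- c("a", "tau1", "c", "tau2")
    fitted_v <- stats::fitted(fit)
  }
  structure(list(model = model, params = params,
                 r_squared = r_squared(tab$surviving_fraction, fitted_v),
                 fitted = data.frame(lag = tab$lag, fit = fitted_v)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("survival_fit [%s]: r^2 = %.4f\n", x$model, x$r_squared))
  print(signif(x$params, 4))
  invisible(x)
}
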