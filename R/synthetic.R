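#' Tuning-curve population over a low-dimensional sensory space
#'
#' A population of input neurons with Gaussian tuning curves whose centers
#' are scattered uniformly over the unit cube. A sensory experience is a
#' point in that cube; the population response is the tuning-curve support at
#' the point, normalized across the population to `[0, rate_max]` Hz, plus a
#' constant background rate.
#'
#' @param n_inputs Population size (default 1000).
#' @param dim Dimension of the sensory space (default 3).
#' @param tuning_sd Tuning-curve width `sigma` (default 0.3).
#' @param tuning_form Radial-basis convention `exp(-(d/sigma)^2)` (default)
#'   or the normal-density convention `exp(-d^2 / (2 sigma^2))`. The radial
#'   form gives a sparser population code: under the broader normal
#'   convention, most of the population responds above the STDP rule's
#'   potentiation threshold for every stimulus, so synaptic connectivity
#'   densifies toward completeness instead of maintaining distinct
#'   persistent and transient synapse populations.
#' @param rate_max Peak rate after normalization in Hz (default 80).
#' @param rate_background Additive background rate in Hz (default 5).
#' @param pattern_duration Duration of one experience presentation in
#'   seconds (default 0.2).
#' @param normalize `"per_pattern"` (default; the population maximum of each
#'   presented pattern maps to `rate_max`) or `"per_neuron"` (each neuron's
#'   tuning curve individually peaks at `rate_max` at its center).
#' @return Object of class `tuning_environment`.
#' @export
tuning_environment <- function(n_inputs = 1000, dim = 3, tuning_sd = 0.3,
                               rate_max = 80, rate_background = 5,
                               pattern_duration = 0.2,
                               normalize = c("per_pattern", "per_neuron"),
                               tuning_form = c("radial", "normal")) {
  stopifnot(n_inputs >= 1, dim >= 1, tuning_sd > 0)
  tuning_form <- match.arg(tuning_form)
  structure(list(
    centers = matrix(stats::runif(n_inputs * dim), n_inputs, dim),
    tuning_sd = tuning_sd, rate_max = rate_max,
    rate_background = rate_background,
    pattern_duration = pattern_duration,
    denom = if (tuning_form == "radial") tuning_sd^2 else 2 * tuning_sd^2,
    normalize = match.arg(normalize)), class = "tuning_environment")
}

#' Population firing rates for sensory experiences
#'
#' @param env A [tuning_environment()].
#' @param points Matrix of experience points (rows), or a single point as a
#'   vector. Points are clipped to the unit cube.
#' @return Rate matrix, `n_inputs x n_points`, in Hz; every entry lies in
#'   `[rate_background, rate_max + rate_background]`.
#' @export
experience_to_rates <- function(env, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- pmin(pmax(points, 0), 1)
  stopifnot(ncol(points) == ncol(env$centers))
  # squared distances centers x points
  d2 <- outer(rowSums(env$centers^2), rowSums(points^2), "+") -
    2 * env$centers %*% t(points)
  resp <- exp(-d2 / env$denom)
  if (env$normalize == "per_pattern") {
    resp <- sweep(resp, 2, apply(resp, 2, max), "/")
  }
  env$rate_max * resp + env$rate_background
}

#' Mixture-of-Gaussians world over the sensory space
#'
#' Object clusters in the sensory space: each component mean is drawn per
#' coordinate from Normal(0.5, 0.2); each covariance is `0.04 I + 0.01 xi`
#' with `xi` a matrix of standard-normal entries, then symmetrized and
#' projected to the nearest positive-definite matrix (eigenvalue floor
#' 1e-4). Components are selected with equal probability.
#'
#' @param n_components Number of clusters (3 for a standard environment).
#' @param dim Space dimension (default 3).
#' @return Object of class `cluster_world` with `means` (list) and `chols`
#'   (list of upper Cholesky factors).
#' @export
cluster_world <- function(n_components = 3, dim = 3) {
  stopifnot(n_components >= 1)
  means <- chols <- vector("list", n_components)
  for (j in seq_len(n_components)) {
    means[[j]] <- stats::rnorm(dim, 0.5, 0.2)
    xi <- matrix(stats::rnorm(dim * dim), dim, dim)
    C <- 0.04 * diag(dim) + 0.01 * xi
    C <- (C + t(C)) / 2
    e <- eigen(C, symmetric = TRUE)
    C <- e$vectors %*% diag(pmax(e$values, 1e-4), dim) %*% t(e$vectors)
    chols[[j]] <- chol(C)
  }
  structure(list(means = means, chols = chols, dim = dim),
            class = "cluster_world")
}

#' Enrich a world by adding clusters
#'
#' An enriched environment strictly extends the standard one: the original
#' components are kept and `n_extra` new clusters are appended.
#'
#' @param world A [cluster_world()].
#' @param n_extra Number of clusters to add (default 4).
#' @return The enriched `cluster_world`.
#' @export
enrich_world <- function(world, n_extra = 4) {
  extra <- cluster_world(n_extra, dim = world$dim)
  world$means <- c(world$means, extra$means)
  world$chols <- c(world$chols, extra$chols)
  world
}

#' Draw sensory experience points from a world
#'
#' Selects a component uniformly at random, then draws from its multivariate
#' Gaussian.
#'
#' @param world A [cluster_world()].
#' @param n Number of experiences.
#' @return `n x dim` matrix of points.
#' @export
sample_world <- function(world, n) {
  stopifnot(n >= 1)
  k <- length(world$means)
  comp <- sample.int(k, n, replace = TRUE)
  z <- matrix(stats::rnorm(n * world$dim), n, world$dim)
  out <- matrix(NA_real_, n, world$dim)
  for (j in seq_len(k)) {
    idx <- which(comp == j)
    if (length(idx))
      out[idx, ] <- z[idx, , drop = FALSE] %*% world$chols[[j]] +
        rep(world$means[[j]], each = length(idx))
  }
  out
}

#' Poisson spike trains from fixed rates
#'
#' Draws independent homogeneous Poisson spike trains for one pattern window
#' during which rates are held fixed. Optionally pads the pattern with
#' low-rate noise before and after.
#'
#' @param rates Rate vector in Hz (one entry per input neuron).
#' @param duration Pattern duration in seconds.
#' @param pad Padding duration in seconds added before and after (default 0).
#' @param pad_rate Padding rate in Hz (default 1).
#' @return Data frame with columns `neuron` (1-based id) and `time` (s,
#'   within `[0, duration + 2 pad]`), ordered by time.
#' @export
rates_to_spikes <- function(rates, duration, pad = 0, pad_rate = 1) {
  stopifnot(duration > 0, all(rates >= 0))
  segs <- if (pad > 0) {
    list(list(r = rep(pad_rate, length(rates)), t0 = 0, d = pad),
         list(r = rates, t0 = pad, d = duration),
         list(r = rep(pad_rate, length(rates)), t0 = pad + duration, d = pad))
  } else list(list(r = rates, t0 = 0, d = duration))
  neuron <- integer(0); time <- numeric(0)
  for (s in segs) {
    n <- stats::rpois(length(s$r), s$r * s$d)
    ids <- rep(seq_along(s$r), n)
    neuron <- c(neuron, ids)
    time <- c(time, s$t0 + stats::runif(length(ids)) * s$d)
  }
  o <- order(time)
  data.frame(neuron = neuron[o], time = time[o])
}

# one stroke-like binary prototype on a side x side grid: a connected path
# from the top to the bottom row, starting near the middle column with a
# style-specific slant and curvature (digit-1-like: different styles overlap
# substantially but are never identical); "h" transposes to a left-right
# stroke
stroke_prototype <- function(side, thickness = 1, orientation = "v") {
  img <- matrix(0, side, side)
  col <- side / 2 + stats::rnorm(1, 0, side / 10)
  slant <- stats::rnorm(1, 0, 0.4)
  curve <- stats::rnorm(1, 0, 0.05)
  for (r in seq_len(side)) {
    col <- col + slant + curve * (r - side / 2) +
      sample(c(-1, 0, 0, 1), 1) * 0.5
    c0 <- min(max(round(col), 1), side)
    cc <- c0:min(side, c0 + thickness - 1)
    img[r, cc] <- 1
  }
  if (orientation == "h") img <- t(img)
  as.vector(img)
}

#' Synthetic digit-like binary pattern sets
#'
#' Stand-in for handwritten-digit data: each class is a small family of
#' stroke-like binary prototypes on a square pixel grid; instances are
#' prototypes with independent per-pixel flip noise. Pixel statistics are
#' bimodal at 0 and 1, the structure a bimodal weight prior targets. Train
#' and test sets use disjoint prototype subsets, so the test set contains
#' styles never seen during training.
#'
#' @param n_classes Number of pattern classes (default 1).
#' @param train_prototypes,test_prototypes Prototypes per class in each set
#'   (defaults 1 and 5).
#' @param n_train,n_test Instances per class (defaults 5 and 50).
#' @param image_side Pixels per side (default 14).
#' @param flip_noise Per-pixel flip probability in `[0, 0.5)` (default 0.05).
#' @return List with binary matrices `train`, `test` (patterns in rows),
#'   `train_protos`, `test_protos`, and `source_intensity` (the flip-noise
#'   smoothed Bernoulli means of the train prototypes).
#' @export
digit_pattern_generator <- function(n_classes = 1, train_prototypes = 1,
                                    test_prototypes = 5, n_train = 5,
                                    n_test = 50, image_side = 14,
                                    flip_noise = 0.05) {
  stopifnot(flip_noise >= 0, flip_noise < 0.5)
  V <- image_side^2
  make_set <- function(protos, n_per_class) {
    out <- matrix(0, 0, V)
    for (p in protos) {
      inst <- matrix(rep(p, n_per_class), n_per_class, V, byrow = TRUE)
      flips <- matrix(stats::runif(n_per_class * V) < flip_noise,
                      n_per_class, V)
      inst[flips] <- 1 - inst[flips]
      out <- rbind(out, inst)
    }
    out
  }
  train_protos <- test_protos <- list()
  train <- test <- matrix(0, 0, V)
  for (cl in seq_len(n_classes)) {
    tp <- replicate(train_prototypes,
                    stroke_prototype(image_side, thickness = 2),
                    simplify = FALSE)
    sp <- replicate(test_prototypes,
                    stroke_prototype(image_side, thickness = 2),
                    simplify = FALSE)
    train_protos <- c(train_protos, tp)
    test_protos <- c(test_protos, sp)
    train <- rbind(train, make_set(tp, ceiling(n_train / train_prototypes)))
    test <- rbind(test, make_set(sp, ceiling(n_test / test_prototypes)))
  }
  si <- Reduce(`+`, train_protos) / length(train_protos)
  list(train = train[seq_len(n_train * n_classes), , drop = FALSE],
       test = test[seq_len(n_test * n_classes), , drop = FALSE],
       train_protos = train_protos, test_protos = test_protos,
       source_intensity = si * (1 - flip_noise) + (1 - si) * flip_noise)
}

#' Synthetic bimodal (audio/visual) stimulus pairs
#'
#' Stand-in for paired spoken/handwritten digit presentations. Each class has
#' an "auditory" prototype: a temporally structured rate trajectory over
#' `n_auditory` channels (smooth random Gaussian bumps in channel-time),
#' rendered per presentation at a duration drawn uniformly from
#' `[320, 520]` ms, and a "visual" prototype: a static stroke image mapped to
#' `[0, rate_visual_max]` Hz. Presentations add multiplicative amplitude
#' noise; the two modalities are presented simultaneously.
#'
#' @param n_classes Number of classes (default 2).
#' @param n_auditory Auditory channels (default 30).
#' @param visual_side Visual image side in pixels (default 6).
#' @param frame_ms Frame length of the auditory rate trajectory in ms
#'   (default 40).
#' @param rate_auditory_max,rate_visual_max Peak rates in Hz (defaults 80,
#'   50).
#' @param amplitude_jitter SD of the per-presentation log-normal amplitude
#'   factor (default 0.1).
#' @return Object of class `bimodal_task`: per-class auditory prototype
#'   matrices (`channels x frames` at the reference duration 420 ms), visual
#'   prototypes, and the presentation sampler [draw_bimodal_presentation()]
#'   parameters.
#' @export
bimodal_pattern_generator <- function(n_classes = 2, n_auditory = 30,
                                      visual_side = 6, frame_ms = 40,
                                      rate_auditory_max = 80,
                                      rate_visual_max = 50,
                                      amplitude_jitter = 0.1) {
  ref_frames <- round(420 / frame_ms)
  aud <- vis <- list()
  for (cl in seq_len(n_classes)) {
    # smooth class-specific channel-time rate surface from random bumps;
    # bump channels concentrate in a class-specific band (with soft edges),
    # mimicking the distinct formant trajectories of different utterances
    tt <- seq(0, 1, length.out = ref_frames)
    surf <- matrix(0, n_auditory, ref_frames)
    band <- n_auditory * c(cl - 1, cl) / n_classes
    for (b in seq_len(4 + n_auditory %/% 10)) {
      c0 <- stats::runif(1, band[1] + 0.5, band[2] + 0.5)
      t0 <- stats::runif(1)
      amp <- stats::runif(1, 0.5, 1)
      surf <- surf + amp *
        exp(-outer((seq_len(n_auditory) - c0)^2 /
                     (2 * (n_auditory / (3 * n_classes))^2),
                   (tt - t0)^2 / (2 * 0.15^2), "+"))
    }
    aud[[cl]] <- rate_auditory_max * surf / max(surf)
    vis[[cl]] <- rate_visual_max *
      matrix(stroke_prototype(visual_side, thickness = 2,
                              orientation = if (cl %% 2) "v" else "h"),
             ncol = 1)
  }
  structure(list(n_classes = n_classes, auditory = aud, visual = vis,
                 frame_ms = frame_ms, amplitude_jitter = amplitude_jitter,
                 n_auditory = n_auditory, n_visual = visual_side^2),
            class = "bimodal_task")
}

#' Draw one bimodal presentation
#'
#' @param task A [bimodal_pattern_generator()] object.
#' @param class Class label in `1..n_classes`.
#' @param duration_ms Presentation duration in ms; drawn uniformly from
#'   `[320, 520]` when `NULL`.
#' @param jitter Apply per-presentation amplitude jitter (default `TRUE`;
#'   with `FALSE` and a fixed duration the presentation is deterministic).
#' @return List with `rates` (`(n_auditory + n_visual) x frames` Hz),
#'   `frame_ms`, `duration_ms`, `class`. Auditory channels come first.
#' @export
draw_bimodal_presentation <- function(task, class, duration_ms = NULL,
                                      jitter = TRUE) {
  stopifnot(class >= 1, class <= task$n_classes)
  if (is.null(duration_ms)) duration_ms <- stats::runif(1, 320, 520)
  frames <- max(1, round(duration_ms / task$frame_ms))
  proto <- task$auditory[[class]]
  # time-warp the reference trajectory to the drawn duration
  idx <- pmin(ncol(proto),
              pmax(1, round(seq(1, ncol(proto), length.out = frames))))
  a <- proto[, idx, drop = FALSE]
  v <- matrix(task$visual[[class]], task$n_visual, frames)
  if (jitter) {
    fac_a <- exp(stats::rnorm(1, 0, task$amplitude_jitter))
    fac_v <- exp(stats::rnorm(1, 0, task$amplitude_jitter))
    a <- a * fac_a
    v <- v * fac_v
  }
  list(rates = rbind(a, v), frame_ms = task$frame_ms,
       duration_ms = frames * task$frame_ms, class = class)
}
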