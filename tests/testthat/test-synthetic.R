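test_that("tuning-curve rates respect range and calibration", {
  set.seed(41)
  env <- tuning_environment(200)
  # a point exactly at a center: that neuron responds at 80 + 5 Hz
  pt <- env$centers[17, ]
  r <- experience_to_rates(env, pt)
  expect_equal(r[17, 1], 85)
  expect_true(all(r >= 5 - 1e-9 & r <= 85 + 1e-9))
  # a far-off neuron sits at background
  env2 <- tuning_environment(3, tuning_sd = 0.05)
  env2$centers <- rbind(c(0, 0, 0), c(1, 1, 1), c(0.01, 0, 0))
  r2 <- experience_to_rates(env2, c(0, 0, 0))
  expect_equal(r2[2, 1], 5, tolerance = 1e-6)
  # per-neuron normalization leaves off-center responses below maximum
  env3 <- tuning_environment(50, normalize = "per_neuron")
  r3 <- experience_to_rates(env3, c(0.5, 0.5, 0.5))
  expect_true(all(r3 >= 5 & r3 <= 85))
})

test_that("cluster worlds sample their mixture correctly", {
  set.seed(42)
  w <- cluster_world(3)
  expect_length(w$means, 3)
  # enriched worlds strictly extend the standard world
  ee <- enrich_world(w, 4)
  expect_length(ee$means, 7)
  expect_identical(ee$means[1:3], w$means)
  expect_identical(ee$chols[1:3], w$chols)
  # degenerate covariance: samples collapse onto the component means
  w0 <- w
  for (j in 1:3) w0$chols[[j]] <- diag(3) * 1e-12
  s <- sample_world(w0, 300)
  d <- sapply(1:3, function(j)
    sqrt(colSums((t(s) - w0$means[[j]])^2)))
  expect_lt(max(apply(d, 1, min)), 1e-9)
  # equal-probability component choice
  cnt <- table(apply(d, 1, which.min))
  expect_true(all(abs(cnt - 100) <= 3 * sqrt(300 * (1 / 3) * (2 / 3))))
  # single-component world: CLT check on the sample mean
  w1 <- cluster_world(1)
  s1 <- sample_world(w1, 4000)
  sds <- apply(s1, 2, sd)
  expect_true(all(abs(colMeans(s1) - w1$means[[1]]) <=
                    3 * sds / sqrt(4000)))
})

test_that("Poisson spike generation is calibrated and reproducible", {
  set.seed(43)
  expect_equal(nrow(rates_to_spikes(c(0, 0), 5)), 0)
  sp <- rates_to_spikes(c(100), 10)
  expect_lt(abs(nrow(sp) - 1000), 3 * sqrt(1000))
  set.seed(7); a <- rates_to_spikes(c(20, 40), 2, pad = 0.025)
  set.seed(7); b <- rates_to_spikes(c(20, 40), 2, pad = 0.025)
  expect_identical(a, b)
  expect_true(all(a$time >= 0 & a$time <= 2.05))
  expect_true(!is.unsorted(a$time))
})

test_that("digit-like patterns have bimodal pixels and disjoint styles", {
  set.seed(44)
  g0 <- digit_pattern_generator(1, flip_noise = 0, n_train = 4,
                                train_prototypes = 2)
  expect_true(all(g0$train %in% 0:1))
  expect_true(all(apply(g0$train[1:2, ], 1, function(x)
    any(vapply(g0$train_protos, identical, logical(1), y = x)))))
  g <- digit_pattern_generator(1, flip_noise = 0.05, n_train = 5,
                               train_prototypes = 5, n_test = 50)
  on_frac <- mean(g$test)
  expect_gt(on_frac, 0.05)
  expect_lt(on_frac, 0.5)
  # train and test prototype styles are disjoint
  for (tp in g$train_protos)
    expect_false(any(vapply(g$test_protos, identical, logical(1), y = tp)))
  expect_equal(dim(g$test), c(50, 196))
})

test_that("bimodal presentations have paper-compatible durations and are separable", {
  set.seed(45)
  task <- bimodal_pattern_generator(2, n_auditory = 20, visual_side = 5)
  p1 <- draw_bimodal_presentation(task, 1, duration_ms = 400,
                                  jitter = FALSE)
  p2 <- draw_bimodal_presentation(task, 1, duration_ms = 400,
                                  jitter = FALSE)
  expect_identical(p1, p2)
  durs <- replicate(200, draw_bimodal_presentation(task, 1)$duration_ms)
  expect_true(all(durs >= 320 - 20 & durs <= 520 + 20))
  # classes linearly separable from mean rate vectors by construction
  feats <- function(cl) t(replicate(25, rowMeans(
    draw_bimodal_presentation(task, cl)$rates)))
  f1 <- feats(1); f2 <- feats(2)
  m1 <- colMeans(f1[1:12, ]); m2 <- colMeans(f2[1:12, ])
  test <- rbind(f1[13:25, ], f2[13:25, ])
  lab <- rep(1:2, each = 13)
  sc <- test %*% (m2 - m1) - sum((m1 + m2) * (m2 - m1)) / 2
  expect_gt(mean(ifelse(sc > 0, 2, 1) == lab), 0.9)
})

test_that("generators are pure functions of the seed", {
  set.seed(46); e1 <- tuning_environment(30)
  set.seed(46); e2 <- tuning_environment(30)
  expect_identical(e1, e2)
  set.seed(47); w1 <- cluster_world(3)
  set.seed(47); w2 <- cluster_world(3)
  expect_identical(w1, w2)
  set.seed(48); d1 <- digit_pattern_generator(1)
  set.seed(48); d2 <- digit_pattern_generator(1)
  expect_identical(d1, d2)
})
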