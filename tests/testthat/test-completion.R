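test_that("feedback learning is saturating, monotone and replayable", {
  fb <- feedback_net(12, 8, f_w = 0.7, seed = 1)
  x <- c(rep(1L, 4), rep(0L, 8))
  z <- c(1L, 1L, rep(0L, 6))
  fb1 <- learn_feedback(fb, x, z)
  expect_true(all(fb1$W %in% c(0, 1)))
  expect_true(all(fb1$W[!fb1$mask] == 0))
  expect_identical(learn_feedback(fb1, x, z)$W, fb1$W)   # idempotent
  expect_identical(learn_feedback(fb, x, integer(8))$W, fb$W)
  expect_error(learn_feedback(fb, x, c(1L, 0L)), "dimension")
  # full-sequence replay: fb weight is 1 iff connected and some item had
  # both ends active at its learning step
  m <- 80; n <- 60; M <- 25
  ens <- gen_random_patterns(M, m, 0.1, seed = 2)
  pls <- draw_plateaus(M, n, 0.1, seed = 3)
  mk <- build_connectivity(m, n, 0.6, seed = 4)
  fb0 <- feedback_net(m, n, seed = 5)
  # replicate the two-step protocol by hand to collect the (x, z) pairs
  set.seed(6)
  W <- matrix(0, n, m); expected <- matrix(0, m, n)
  cfg <- plasticity_config()
  for (k in seq_len(M)) {
    W <- btsp_step(W, mk, ens$items[k, ], which(pls$mask[k, ]), cfg)
    z <- as.integer(W %*% ens$items[k, ] > 2)
    expected <- pmax(expected, outer(ens$items[k, ], z) * fb0$mask)
  }
  set.seed(6)
  trained <- learn_sequence_with_feedback(ens, pls, mk, fb0, cfg = cfg,
                                          v_th = 2)
  expect_identical(trained$fb$W, expected)
  expect_identical(trained$net$W, W)
  # feedback weights never decrease along the sequence (checked above via
  # pmax construction agreeing with the incremental learner)
})

test_that("reconstruction inverts masked cues at low load", {
  m <- 300; n <- 600; M <- 20
  ens <- gen_random_patterns(M, m, 0.05, seed = 11)
  pls <- draw_plateaus(M, n, 0.05, seed = 12)
  mk <- build_connectivity(m, n, 0.6, seed = 13)
  fb0 <- feedback_net(m, n, seed = 14)
  tr <- learn_sequence_with_feedback(ens, pls, mk, fb0, v_th = 3, seed = 15)
  expect_true(all(reconstruct(tr$fb, integer(n), v_f = 3) == 0L))
  # unmasked stored item reconstructs exactly
  z_full <- recall(tr$net, ens$items[1, ])
  expect_gt(sum(z_full), 0)
  expect_identical(reconstruct(tr$fb, z_full, v_f = 3), ens$items[1, ])
  # a masked cue reconstructs better than it cues: scaled error < 1
  errs <- vapply(1:10, function(k) {
    cue <- mask_pattern(ens$items[k, ], 0.33, seed = 50 + k)
    z <- recall(tr$net, cue$vector)
    r <- reconstruct(tr$fb, z, v_f = 3)
    scaled_reconstruction_error(ens$items[k, ], cue, r)
  }, numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("scaled reconstruction error anchors at 0, 1 and undefined", {
  x <- c(1L, 1L, 0L, 0L); xp <- c(1L, 0L, 0L, 0L)
  expect_equal(scaled_reconstruction_error(x, xp, r = x), 0)
  expect_equal(scaled_reconstruction_error(x, xp, r = xp), 1)
  expect_warning(e <- scaled_reconstruction_error(x, x, r = xp), "undefined")
  expect_true(is.na(e))
})

test_that("adaptive threshold lines pass through the scan optima", {
  # the line evaluated at the sparsity of one-third-masked default cues
  coefs <- list(alpha = 692.3, beta = 26.6)
  expect_equal(adaptive_threshold(coefs, 0.005 * (1 - 0.33)), 28.92,
               tolerance = 1e-3)
  expect_equal(adaptive_threshold(list(alpha = 0, beta = 7), 0.1), 7)
  # a fitted line reproduces its own scan points within grid resolution
  m <- 300; n <- 500; M <- 60
  ens <- gen_random_patterns(M, m, 0.06, seed = 21)
  pls <- draw_plateaus(M, n, 0.06, seed = 22)
  mk <- build_connectivity(m, n, 0.6, seed = 23)
  fb0 <- feedback_net(m, n, seed = 24)
  tr <- learn_sequence_with_feedback(ens, pls, mk, fb0, v_th = 3, seed = 25)
  fit <- fit_adaptive_thresholds(tr$net, tr$fb, ens,
                                 masking_fractions = c(0.1, 0.3, 0.5),
                                 scan_range = c(1, 20), seed = 26)
  expect_identical(nrow(fit$points), 3L)
  expect_true(all(is.finite(fit$points$v_mem)))
  pred_mem <- adaptive_threshold(fit$memory, fit$points$ones_fraction)
  res <- stats::lm(fit$points$v_mem ~ fit$points$ones_fraction)
  expect_equal(pred_mem, unname(stats::fitted(res)), tolerance = 1e-8)
})

test_that("completion recovers masked inputs when the feedback matrix is
           far from saturation", {
  # at this scale the per-connection feedback activation odds after M
  # items (~0.025) leave a wide margin between the drive onto true and
  # spurious input bits, so one generative step repairs most of the mask
  m <- 5000; n <- 7800; M <- 1000
  tp <- theory_params(m, n, M, 0.01, 0.005, 0.6)
  vth <- as.integer(optimize_threshold(tp, v_max = 60))
  ens <- gen_random_patterns(M, m, 0.01, seed = 71)
  pls <- draw_plateaus(M, n, 0.005, seed = 72)
  mk <- build_connectivity(m, n, 0.6, seed = 73)
  fb0 <- feedback_net(m, n, seed = 74)
  tr <- learn_sequence_with_feedback(ens, pls, mk, fb0, v_th = vth,
                                     seed = 75)
  set.seed(76)
  sc <- btspcam:::scan_threshold_pair(tr$net, tr$fb, ens, 0.33,
                                      sample(M, 40), v_cand = 1:40)
  net_fd <- tr$net; net_fd$v_th <- as.integer(sc$v_mem)
  errs <- vapply(1:60, function(k) {
    cue <- mask_pattern(ens$items[k, ], 0.33, seed = 500 + k)
    r <- reconstruct(tr$fb, recall(net_fd, cue$vector), sc$v_in)
    scaled_reconstruction_error(ens$items[k, ], cue, r)
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})
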