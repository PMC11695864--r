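test_that("plateau schedules are Bernoulli(f_q) and reproducible", {
  pls <- draw_plateaus(M = 1000, n = 400, f_q = 0.05, seed = 2)
  sizes <- rowSums(pls$mask)
  expect_lt(abs(mean(sizes) - 20), 3 * sd(sizes) / sqrt(length(sizes)))
  expect_true(all(rowSums(draw_plateaus(5, 30, 1, seed = 1)$mask) == 30))
  expect_true(all(rowSums(draw_plateaus(5, 30, 0, seed = 1)$mask) == 0))
  expect_identical(draw_plateaus(10, 20, 0.3, seed = 4)$mask,
                   draw_plateaus(10, 20, 0.3, seed = 4)$mask)
})

test_that("a BTSP step flips only gated plateau rows at active inputs", {
  m <- 6; n <- 4
  mask <- matrix(TRUE, n, m)
  W <- matrix(0, n, m); W[2, 1] <- 1
  x <- c(1L, 1L, 0L, 0L, 0L, 0L)
  core <- plasticity_config(rule = "core")
  W2 <- btsp_step(W, mask, x, Q = 2L, cfg = core)
  expect_identical(W2[2, ], c(0, 1, 0, 0, 0, 0))   # LTD at w=1, LTP at w=0
  expect_identical(W2[-2, ], W[-2, ])              # rows outside Q untouched
  # no plateau, no plasticity
  expect_identical(btsp_step(W, mask, x, Q = integer(0), cfg = core), W)
  # weights never appear outside the connectivity mask
  mask2 <- mask; mask2[2, 2] <- FALSE
  W3 <- btsp_step(matrix(0, n, m), mask2, x, Q = 1:4, cfg = core)
  expect_identical(W3[2, 2], 0)
  expect_true(all(W3[!mask2] == 0))
  expect_error(btsp_step(W, mask, c(1L, 0L), Q = 1L), "length")
})

test_that("core steps are involutions and equal the gated rule in law", {
  s <- tiny_setup(cfg = plasticity_config(rule = "core"))
  x <- s$ens$items[1, ]
  W1 <- core_btsp_step(s$net$W, s$mask, x, Q = c(3L, 9L))
  W2 <- core_btsp_step(W1, s$mask, x, Q = c(3L, 9L))
  expect_identical(W2, s$net$W)                    # double flip = identity
  # stochastic rule at f_q vs core rule at f_q/2: same trace-size law
  reps <- 20
  tsize <- function(rule, fq, seed) {
    cfg <- plasticity_config(rule = rule)
    ens <- gen_random_patterns(60, 150, 0.08, seed = seed)
    pls <- draw_plateaus(60, 120, fq, seed = seed + 500L)
    mk <- build_connectivity(150, 120, 0.6, seed = seed + 900L)
    net <- learn_sequence(ens, pls, mk, cfg = cfg, v_th = 3,
                          seed = seed + 1300L)
    trace_size(net, ens)
  }
  t_eq1 <- vapply(1:reps, function(r) tsize("eq1", 0.1, r), numeric(1))
  t_core <- vapply(1:reps, function(r) tsize("core", 0.05, 100 + r),
                   numeric(1))
  se <- sqrt(var(t_eq1) / reps + var(t_core) / reps)
  expect_lt(abs(mean(t_eq1) - mean(t_core)), 3 * se)
})

test_that("learned weights equal the parity of logged update events", {
  s <- tiny_setup(M = 40, keep_log = TRUE, seed = 21)
  expect_true(all(s$net$W %in% c(0, 1)))
  expect_true(all(s$net$W[!s$mask] == 0))
  expect_identical(replay_parity(s$net$update_log, s$net$n, s$net$m),
                   s$net$W)
  # an empty sequence leaves the zero matrix
  net0 <- learn_sequence(empty_ensemble(50),
                         draw_plateaus(0, 30, 0.1, seed = 1),
                         build_connectivity(50, 30, 0.6, seed = 2))
  expect_true(all(net0$W == 0))
  expect_error(learn_sequence(gen_random_patterns(3, 50, 0.1, seed = 1),
                              draw_plateaus(4, 30, 0.1, seed = 2),
                              build_connectivity(50, 30, 0.6, seed = 3)),
               "disagree")
})

test_that("strong-weight density follows the parity closed form", {
  m <- 400; n <- 300; M <- 400; f_p <- 0.05; f_q <- 0.05
  dens <- vapply(1:8, function(r) {
    s <- tiny_setup(m = m, n = n, M = M, f_p = f_p, f_q = f_q,
                    seed = 100 + r)
    strong_weight_fraction(s$net)
  }, numeric(1))
  pred <- 0.5 * (1 - (1 - f_p * f_q)^M)
  expect_lt(abs(mean(dens) - pred), 3 * sd(dens) / sqrt(length(dens)))
})

test_that("multi-release-site changes match the closed form", {
  mr <- multi_release_site_change(n_sites = 8, n_trials = 20000, seed = 3)
  expect_equal(mr$expected_change, 4 - mr$initial_sum)
  # the all-weak and all-strong strata can only potentiate / depress; at
  # the half-filled stratum the flip is exactly zero
  expect_equal(mr$mean_change[mr$initial_sum == 4], 0)
  # every stratum's Monte-Carlo mean stays within 3 SE of p*(n - 2k)
  se <- abs(8 - 2 * mr$initial_sum) * 0.5 / sqrt(mr$n_trials)
  expect_true(all(abs(mr$mean_change - mr$expected_change) <=
                    3 * se + 1e-9))
})

test_that("asymmetric LTP/LTD probabilities shift the weight balance", {
  cfg_ltd <- plasticity_config(p_ltp = 0.3, p_ltd = 0.8)
  cfg_sym <- plasticity_config()
  dens <- function(cfg, seed) {
    s <- tiny_setup(m = 200, n = 150, M = 150, f_p = 0.08, f_q = 0.1,
                    cfg = cfg, seed = seed)
    strong_weight_fraction(s$net)
  }
  d_ltd <- mean(vapply(1:5, function(r) dens(cfg_ltd, r), numeric(1)))
  d_sym <- mean(vapply(1:5, function(r) dens(cfg_sym, 50 + r), numeric(1)))
  expect_lt(d_ltd, d_sym)       # stronger LTD prunes more strong weights
  expect_error(plasticity_config(p_ltp = 0.3), "together")
})
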