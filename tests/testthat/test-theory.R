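test_that("parity lemma matches brute-force enumeration exactly", {
  for (N in 0:12) for (p in seq(0, 1, by = 0.1)) {
    expect_equal(prob_even(N, p), enum_prob_even(N, p), tolerance = 1e-14)
    expect_equal(prob_even(N, p) + prob_odd(N, p), 1, tolerance = 1e-14)
  }
  expect_equal(prob_even(0, 0.7), 1)
  expect_equal(prob_even(5, 0.5), 0.5)
  expect_equal(prob_even(2, 0.3), 0.58)          # P(0) + P(2) = 0.49 + 0.09
})

test_that("strong-weight probabilities behave across the load range", {
  expect_equal(p_e(1, 0.005, 0.005), 1)          # no later interference
  expect_equal(p_o(1, 0.005, 0.005), 0)
  expect_equal(p_e(30000, 0.005, 0.005), 0.736187, tolerance = 1e-6)
  for (M in c(1, 10, 1000)) {
    expect_equal(p_e(M, 0.01, 0.02) + p_o(M, 0.01, 0.02), 1)
  }
  # Monte-Carlo parity oracle at the default operating point
  set.seed(99)
  flips <- rbinom(1e6, 30000 - 1, 0.005 * 0.005 / 2)
  mc <- mean(flips %% 2 == 0)
  expect_lt(abs(mc - p_e(30000, 0.005, 0.005)), 3 * 0.5 / sqrt(1e6))
  # no underflow at brain scale
  expect_true(is.finite(p_e(8e5, 5e-5, 0.005)))
  expect_gt(p_e(8e5, 5e-5, 0.005), 0.5)
})

test_that("conditional firing probabilities are binomial survivals", {
  expect_equal(p_f1(5, 5, 0.6, 0.9), 0)          # sum cannot exceed I
  expect_equal(p_f1(3, 3, 1, 1), 0)              # strictly greater is needed
  expect_equal(p_f1(1, 0, 1, 0.6), 0.6)          # P(X >= 1) = p
  I <- 0:50
  expect_true(all(p_f1(I, 4, 0.6, 0.74) >= p_f2(I, 4, 0.6, 0.26)))
})

test_that("average firing probability matches an independent convolution
           oracle on small instances", {
  for (case in list(list(m = 12, M = 4, v = 1), list(m = 20, M = 6, v = 2),
                    list(m = 15, M = 3, v = 0))) {
    tp <- theory_params(case$m, 10, case$M, 0.3, 0.4, 0.6, v_th = case$v)
    expect_equal(as.numeric(p_favg(tp)),
                 enum_p_favg(case$m, case$M, 0.3, 0.4, 0.6, case$v),
                 tolerance = 1e-9)
  }
  # no plateaus ever and a single stored item: nothing can fire
  tp0 <- theory_params(20, 10, 1, 0.3, 0, 0.6, v_th = 0)
  expect_equal(as.numeric(p_favg(tp0)), 0)
  # monotone non-increasing in the threshold
  tp <- theory_params(2500, 3900, 1000, 0.02, 0.01, 0.6)
  vals <- vapply(1:40, function(v) {
    tp$v_th <- v; as.numeric(p_favg(tp))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_lt(attr(p_favg({tp$v_th <- 10L; tp}), "truncation_error"), 1e-10)
})

test_that("expected Hamming distances respect their algebraic limits", {
  tp <- theory_params(2500, 3900, 1000, 0.02, 0.01, 0.6, v_th = 10)
  # more masking, more damage; f_d = 0 is the (small, nonzero) baseline of
  # the independence approximation
  hd0 <- expected_hd_masked(tp, f_d = 0)
  hd33 <- expected_hd_masked(tp, f_d = 0.33)
  expect_lte(hd0, hd33)
  # a fully masked cue recalls nothing: HD equals the expected trace size
  expect_equal(expected_hd_masked(tp, f_d = 1),
               tp$n * as.numeric(p_favg(tp)), tolerance = 1e-12)
  # pairwise distance is the two-coin formula
  pf <- as.numeric(p_favg(tp))
  expect_equal(expected_hd_pairs(tp), 2 * tp$n * pf * (1 - pf))
})

test_that("overlapping-item probabilities and predictions reduce at c = 0", {
  expect_equal(p_hat_e(1, 0.1), 1)
  expect_equal(p_hat_e(3, 0.1), 0.905)
  expect_equal(p_hat_o(0, 0.1), 0)
  expect_error(p_hat_e(0, 0.1), "s must be >= 1")
  tp0 <- theory_params(2500, 3900, 800, 0.02, 0.01, 0.6, v_th = 9, c = 0)
  op <- overlapping_predictions(tp0, f_d = 0.33)
  expect_identical(op$p_favg, as.numeric(p_favg(tp0)))
  expect_equal(op$expected_hd_masked, expected_hd_masked(tp0, f_d = 0.33),
               tolerance = 1e-14)
  expect_identical(op$expected_hd_pairs, expected_hd_pairs(tp0))
  # the predicted relative dissimilarity grows with the overlap fraction
  ratios <- vapply(c(0, 0.1, 0.2, 0.3), function(fc) {
    c1 <- floor(2500 * fc * 0.02)
    tp <- theory_params(2500, 3900, 800, 0.02, 0.01, 0.6, v_th = 9, c = c1)
    pred <- overlapping_predictions(tp, f_d = 0.33)
    pred$expected_hd_masked / pred$expected_hd_pairs
  }, numeric(1))
  expect_true(all(diff(ratios) >= -1e-9))
})

test_that("threshold optimisation is a true argmin with small-tie rule", {
  tp <- theory_params(2500, 3900, 2000, 0.02, 0.01, 0.6)
  v <- optimize_threshold(tp, f_d = 0.33, v_max = 60)
  obj <- attr(v, "objective")
  expect_identical(as.integer(v), which.min(obj))
  # local optimality at the returned threshold
  vi <- as.integer(v)
  if (vi > 1) expect_gte(obj[vi - 1], obj[vi])
  if (vi < 60) expect_gte(obj[vi + 1], obj[vi])
  # exhaustive rescan oracle
  rescan <- vapply(1:60, function(vv) {
    tp$v_th <- vv
    expected_hd_masked(tp, f_d = 0.33) / expected_hd_pairs(tp)
  }, numeric(1))
  expect_equal(obj, rescan, tolerance = 1e-12)
  expect_identical(vi, which.min(rescan))
})

test_that("the theory evaluates at brain scale in seconds", {
  elapsed <- system.time({
    res <- run_scaleup_theory(M_values = c(4e5, 8e5), f_d = 2/3)
  })[["elapsed"]]
  expect_lt(elapsed, 60)
  expect_true(all(is.finite(unlist(res))))
  expect_true(all(res$relative_dissimilarity > 0))
})
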