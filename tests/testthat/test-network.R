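test_that("recall uses a strict threshold on the weighted sum", {
  W <- rbind(c(1, 1, 0))
  mask <- matrix(TRUE, 1, 3)
  x <- c(1L, 1L, 1L)
  expect_identical(recall(btsp_network(W, mask, v_th = 1), x), 1L)  # 2 > 1
  expect_identical(recall(btsp_network(W, mask, v_th = 2), x), 0L)  # 2 = 2
  net0 <- btsp_network(matrix(0, 4, 3), matrix(TRUE, 4, 3), v_th = 0)
  expect_true(all(recall(net0, x) == 0L))
  s <- tiny_setup()
  expect_true(all(recall(s$net, integer(s$net$m)) == 0L))
  expect_error(recall(s$net, c(1L, 0L)), "length")
  expect_error(btsp_network(matrix(1, 2, 2), matrix(FALSE, 2, 2)),
               "outside the connectivity mask")
})

test_that("connectivity masks have the requested density", {
  expect_true(all(build_connectivity(10, 10, 1, seed = 1)))
  expect_false(any(build_connectivity(10, 10, 0, seed = 1)))
  mk <- build_connectivity(2500, 400, 0.6, seed = 2)
  deg <- rowSums(mk)
  expect_lt(abs(mean(deg) - 1500), 3 * sd(deg) / sqrt(length(deg)))
})

test_that("masked cues can only lose spikes, never gain them", {
  s <- tiny_setup(M = 60, v_th = 1, seed = 31)
  for (k in c(1, 7, 20)) {
    x <- s$ens$items[k, ]
    xp <- mask_pattern(x, 0.4, seed = k)$vector
    u_full <- as.numeric(s$net$W %*% x)
    u_mask <- as.numeric(s$net$W %*% xp)
    expect_true(all(u_mask <= u_full))
    z_full <- recall(s$net, x); z_mask <- recall(s$net, xp)
    expect_true(all(z_mask <= z_full))
  }
})

test_that("relative dissimilarity behaves at its anchor points", {
  s <- tiny_setup(M = 80, m = 300, n = 200, f_p = 0.08, f_q = 0.08,
                  v_th = 3, seed = 41)
  # unmasked cues reproduce the stored traces exactly: ratio 0
  rd0 <- relative_dissimilarity(s$net, s$ens, f_d = 0, n_pairs = 300,
                                seed = 1)
  expect_false(rd0$degenerate)
  expect_identical(rd0$numerator, 0)
  expect_identical(rd0$ratio, 0)
  # cueing with unrelated stored items estimates the same quantity as the
  # pairwise denominator: ratio ~ 1
  Z <- recall_many(s$net, s$ens$items)
  perm <- c(2:80, 1)
  num <- mean(colSums(Z != Z[, perm]))
  pairs <- replicate(400, sample.int(80, 2))
  den <- mean(vapply(seq_len(400), function(p)
    sum(Z[, pairs[1, p]] != Z[, pairs[2, p]]), numeric(1)))
  expect_lt(abs(num / den - 1), 0.25)
  # degenerate denominator is flagged
  netz <- btsp_network(matrix(0, 5, 10), matrix(TRUE, 5, 10), v_th = 0)
  enz <- gen_random_patterns(6, 10, 0.3, seed = 2)
  expect_warning(rdz <- relative_dissimilarity(netz, enz, f_d = 0.5,
                                               n_pairs = 20, seed = 3),
                 "ratio undefined")
  expect_true(rdz$degenerate)
  expect_true(is.na(rdz$ratio))
})

test_that("trace size and strong-weight fraction start at zero and grow", {
  mask <- build_connectivity(100, 60, 0.6, seed = 5)
  net0 <- btsp_network(matrix(0, 60, 100), mask, v_th = 1)
  ens <- gen_random_patterns(10, 100, 0.1, seed = 6)
  expect_identical(trace_size(net0, ens), 0)
  expect_identical(strong_weight_fraction(net0), 0)
  s <- tiny_setup(seed = 51)
  expect_gt(strong_weight_fraction(s$net), 0)
})

test_that("overlap ratio and repulsion index cover their edge cases", {
  z <- c(1L, 0L, 1L, 1L)
  expect_equal(overlap_ratio(z, z, 3), 1)
  expect_warning(o <- overlap_ratio(z, z, 0), "undefined")
  expect_true(is.na(o))
  expect_equal(repulsion_index(0.2, 0.2), 1)   # equal overlaps: no repulsion
  expect_warning(r <- repulsion_index(0.2, 0), "undefined")
  expect_true(is.na(r))
})

test_that("weighted-sum histograms split items by plateau", {
  s <- tiny_setup(M = 100, m = 300, n = 100, f_p = 0.1, f_q = 0.15,
                  seed = 61)
  j <- which(colSums(s$pls$mask) > 3)[1]
  h <- weighted_sum_histogram(s$net, s$ens, j)
  expect_identical(length(h$plateau) + length(h$no_plateau), 100L)
  expect_identical(length(h$plateau), sum(s$pls$mask[, j]))
  # no plateaus anywhere: the plateau histogram is empty
  pls0 <- draw_plateaus(10, 50, 0, seed = 1)
  ens0 <- gen_random_patterns(10, 80, 0.1, seed = 2)
  mk0 <- build_connectivity(80, 50, 0.6, seed = 3)
  net0 <- learn_sequence(ens0, pls0, mk0)
  h0 <- weighted_sum_histogram(net0, ens0, 1, plateaus = pls0)
  expect_identical(length(h0$plateau), 0L)
})
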