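# Shared fixture builders and independent oracles.

# a small learned network with all ingredients returned
tiny_setup <- function(m = 120, n = 80, M = 30, f_p = 0.1, f_q = 0.1,
                       f_w = 0.6, v_th = 2, seed = 1, keep_log = FALSE,
                       cfg = plasticity_config()) {
  ens <- gen_random_patterns(M, m, f_p, seed = seed)
  pls <- draw_plateaus(M, n, f_q, seed = seed + 1L)
  mask <- build_connectivity(m, n, f_w, seed = seed + 2L)
  net <- learn_sequence(ens, pls, mask, cfg = cfg, v_th = v_th,
                        seed = seed + 3L, keep_log = keep_log)
  list(ens = ens, pls = pls, mask = mask, net = net)
}

# empty ensemble (M = 0) for degenerate cases
empty_ensemble <- function(m) {
  btspcam:::new_pattern_ensemble(matrix(integer(0), nrow = 0, ncol = m),
                                 f_p = 0)
}

# parity replay: recompute final weights from an update log
replay_parity <- function(log, n, m) {
  W <- matrix(0, n, m)
  if (is.null(log) || nrow(log) == 0) return(W)
  counts <- stats::aggregate(item ~ neuron + input, log, length)
  for (r in seq_len(nrow(counts)))
    W[counts$neuron[r], counts$input[r]] <- counts$item[r] %% 2
  W
}

# brute-force binomial parity by explicit combinatorial sums
enum_prob_even <- function(N, p) {
  if (N == 0) return(1)
  k <- seq(0, N, by = 2)
  sum(choose(N, k) * p^k * (1 - p)^(N - k))
}

# distribution of a sum of I independent Bernoulli(q) successes via
# explicit polynomial convolution (no pbinom); returns P(X > v)
conv_surv <- function(v, I, q) {
  pmf <- 1
  for (i in seq_len(I)) pmf <- c(pmf * (1 - q), 0) + c(0, pmf * q)
  if (v >= I) 0 else sum(pmf[(v + 2):(I + 1)])
}

# independent evaluation of the average firing probability on a small
# instance: full I-sum over choose(), convolution-based firing
enum_p_favg <- function(m, M, f_p, f_q, f_w, v_th) {
  pe <- 0.5 * (1 + (1 - f_p * f_q)^(M - 1))
  po <- 0.5 * (1 - (1 - f_p * f_q)^(M - 1))
  tot <- 0
  for (I in 0:m) {
    wI <- choose(m, I) * f_p^I * (1 - f_p)^(m - I)
    tot <- tot + wI * (f_q * conv_surv(v_th, I, f_w * pe) +
                       (1 - f_q) * conv_surv(v_th, I, f_w * po))
  }
  tot
}
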