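# Feedback connections, one-shot Hebbian feedback learning, input
# reconstruction, and adaptive linear thresholds.

#' Construct a feedback network
#'
#' Random feedback connections from the `n` memory neurons back to the
#' `m` input neurons, drawn independently of the feedforward mask at the
#' same density (0.6 by default).  Feedback weights are binary, start at
#' zero, and saturate at one.
#'
#' @param m number of input neurons.
#' @param n number of memory neurons.
#' @param f_w feedback connection density.
#' @param seed optional seed.
#' @return A list of class `feedback_net` with `W` and `mask`
#'   (`m x n` each).
#' @export
feedback_net <- function(m, n, f_w = 0.6, seed = NULL) {
  check_count(m, "m"); check_count(n, "n"); check_prob(f_w, "f_w")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(m * n) < f_w, nrow = m, ncol = n)
  structure(list(W = matrix(0, m, n), mask = mask, m = m, n = n, f_w = f_w),
            class = "feedback_net")
}

#' One-shot Hebbian feedback learning step
#'
#' For a single item: every existing feedback connection whose pre- and
#' postsynaptic neurons are both active (`z_j = 1` and `x_i = 1`) is
#' incremented and clipped at the saturation value 1; all other weights
#' are unchanged.  Repeated application with the same `(x, z)` is
#' therefore idempotent, and weights never decrease.
#'
#' @param fb a [feedback_net()].
#' @param x binary input item (length `m`).
#' @param z binary memory trace (length `n`) computed with the *current*
#'   feedforward weights right after the item's BTSP step.
#' @return The updated `feedback_net`.
#' @export
learn_feedback <- function(fb, x, z) {
  if (length(x) != fb$m || length(z) != fb$n)
    stop("dimension mismatch between item/trace and feedback network")
  idx <- which(x == 1); jdx <- which(z == 1)
  if (length(idx) && length(jdx))
    fb$W[idx, jdx] <- pmin(1, fb$W[idx, jdx, drop = FALSE] +
                              fb$mask[idx, jdx, drop = FALSE])
  fb
}

#' Learn a sequence with feedforward BTSP plus feedback Hebb
#'
#' The two-step protocol: each item is presented once and persists for
#' two steps.  Step one applies BTSP to the feedforward weights; step two
#' recomputes the item's trace with the just-updated weights and applies
#' the saturating Hebbian rule to the feedback weights.
#'
#' @inheritParams learn_sequence
#' @param fb a [feedback_net()].
#' @param v_th memory-layer firing threshold used when computing the
#'   traces during learning.
#' @return A list with the trained `net` ([btsp_network()]) and `fb`.
#' @export
learn_sequence_with_feedback <- function(patterns, plateaus, mask, fb,
                                         cfg = plasticity_config(), v_th,
                                         seed = NULL) {
  stopifnot(inherits(patterns, "pattern_ensemble"),
            inherits(plateaus, "plateau_schedule"),
            inherits(fb, "feedback_net"))
  if (patterns$M != plateaus$M) stop("patterns and plateaus disagree in M")
  if (!is.null(seed)) set.seed(seed)
  n <- plateaus$n
  W <- matrix(0, nrow = n, ncol = patterns$m)
  fb_W <- fb$W; fb_mask <- fb$mask      # local copies: updated in place
  for (k in seq_len(patterns$M)) {
    x <- patterns$items[k, ]
    S <- which(x == 1L)
    Q <- which(plateaus$mask[k, ])
    if (length(Q) && length(S)) {
      g <- gate_draws(length(Q), cfg)
      sub <- W[Q, S, drop = FALSE]
      con <- mask[Q, S, drop = FALSE]
      flip <- con & ((sub == 0 & g$ltp) | (sub == 1 & g$ltd))
      sub[flip] <- 1 - sub[flip]
      W[Q, S] <- sub
    }
    jdx <- which(weighted_sums(W, x) > v_th)
    if (length(S) && length(jdx))
      fb_W[S, jdx] <- pmin(1, fb_W[S, jdx, drop = FALSE] +
                              fb_mask[S, jdx, drop = FALSE])
  }
  fb$W <- fb_W
  net <- btsp_network(W = W, mask = mask, v_th = v_th)
  net$plateaus <- plateaus
  net$cfg <- cfg
  list(net = net, fb = fb)
}

#' Reconstruct an input pattern from a memory trace
#'
#' One generative step: each input neuron turns on iff its weighted sum
#' of feedback inputs from the trace strictly exceeds the input-layer
#' threshold `v_f`.
#'
#' @param fb a trained [feedback_net()].
#' @param z_cue binary memory trace (typically the recall of a masked
#'   cue).
#' @param v_f input-layer firing threshold.
#' @return Integer reconstruction of length `m`.
#' @export
reconstruct <- function(fb, z_cue, v_f) {
  if (length(z_cue) != fb$n) stop("trace length does not match feedback net")
  as.integer(weighted_sums(fb$W, z_cue) > v_f)
}

#' Scaled reconstruction error
#'
#' `HD(r, x) / HD(x, x')`: the reconstruction error relative to the
#' damage in the cue.  Values below 1 mean the feedback pass recovered
#' information that the cue had lost.
#'
#' @param x original item.
#' @param x_prime degraded cue.
#' @param r reconstruction.
#' @return The ratio; `NA` with a warning when `HD(x, x') = 0`.
#' @export
scaled_reconstruction_error <- function(x, x_prime, r) {
  if (inherits(x_prime, "cue")) x_prime <- x_prime$vector
  den <- hamming(x, x_prime)
  if (den == 0) {
    warning("cue equals the original item; scaled error undefined")
    return(NA_real_)
  }
  hamming(r, x) / den
}

#' Fit adaptive linear threshold functions
#'
#' Both layers use thresholds that adapt to cue sparsity through a
#' linear function `v = alpha * q + beta` of the average fraction `q` of
#' 1's in the cues.  For each masking fraction, `q` is estimated from a
#' random sample of the items (20% by default), both layer thresholds
#' are grid-scanned over `scan_range`, the pair minimising the mean
#' reconstruction distance `HD(x, r(x'))` is recorded, and a least-squares
#' line through the per-masking-fraction optima gives `(alpha, beta)` for
#' each layer.
#'
#' @param net a trained [btsp_network()].
#' @param fb the matching trained [feedback_net()].
#' @param ensemble the stored `pattern_ensemble`.
#' @param masking_fractions masking fractions supplying the fit points.
#' @param sample_fraction fraction of items sampled per masking fraction.
#' @param scan_range integer range scanned for both thresholds.
#' @param seed optional seed.
#' @return A list with data frame `points` (f_d, ones_fraction, best
#'   memory/input thresholds, best HD) and coefficient lists `memory`
#'   and `input`, each `(alpha, beta)`.
#' @export
fit_adaptive_thresholds <- function(net, fb, ensemble,
                                    masking_fractions = c(0.1, 0.2, 0.33,
                                                          0.4, 0.5),
                                    sample_fraction = 0.2,
                                    scan_range = c(1, 100), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- lapply(masking_fractions, function(fd) {
    ks <- sample(ensemble$M, max(2, ceiling(sample_fraction * ensemble$M)))
    best <- scan_threshold_pair(net, fb, ensemble, fd, ks,
                                v_cand = seq(scan_range[1], scan_range[2]))
    data.frame(f_d = fd, ones_fraction = best$ones_fraction,
               v_mem = best$v_mem, v_in = best$v_in, hd = best$hd,
               row.names = NULL)
  })
  pts <- do.call(rbind, pts)
  fit_line <- function(y) {
    if (length(unique(pts$ones_fraction)) < 2)
      return(list(alpha = 0, beta = mean(y)))
    co <- stats::coef(stats::lm(y ~ pts$ones_fraction))
    list(alpha = unname(co[2]), beta = unname(co[1]))
  }
  list(points = pts,
       memory = fit_line(pts$v_mem),
       input = fit_line(pts$v_in))
}

# Joint grid scan of the memory- and input-layer thresholds minimising
# the mean reconstruction distance HD(x, r(x')) over the sampled items.
# The weighted sums are computed once; every (v_mem, v_in) pair is then a
# cheap comparison.
scan_threshold_pair <- function(net, fb, ensemble, f_d, items,
                                v_cand = 1:100) {
  cues <- lapply(items, function(k)
    mask_pattern(ensemble$items[k, ], f_d)$vector)
  q <- mean(vapply(cues, sum, numeric(1))) / ensemble$m
  U_mem <- vapply(cues, function(cu) weighted_sums(net$W, cu),
                  numeric(net$n))
  x_true <- t(ensemble$items[items, , drop = FALSE]) == 1
  best <- list(hd = Inf, v_mem = NA_integer_, v_in = NA_integer_,
               ones_fraction = q)
  for (vm in v_cand) {
    Z <- U_mem > vm
    if (!any(Z)) break                    # larger vm only empties traces
    U_in <- vapply(seq_along(items), function(ii) {
      jdx <- which(Z[, ii])
      if (!length(jdx)) numeric(fb$m)
      else rowSums(fb$W[, jdx, drop = FALSE])
    }, numeric(fb$m))
    # r_i = 1 iff U_in > v_in; errors per threshold from cumulative counts
    maxu <- as.integer(max(U_in))
    tab_true <- tabulate(as.integer(U_in[x_true]) + 1L, nbins = maxu + 1L)
    tab_false <- tabulate(as.integer(U_in[!x_true]) + 1L, nbins = maxu + 1L)
    cum_true <- cumsum(tab_true)
    cum_false <- cumsum(tab_false)
    n_false <- sum(tab_false)
    for (vi in v_cand) {
      at <- min(vi, maxu) + 1L
      hd <- (cum_true[at] + (n_false - cum_false[at])) / length(items)
      if (hd < best$hd) best <- list(hd = hd, v_mem = vm, v_in = vi,
                                     ones_fraction = q)
    }
  }
  best
}

#' Evaluate an adaptive threshold line
#'
#' @param coefs a list with `alpha` and `beta`.
#' @param ones_fraction average fraction of 1's in the cues.
#' @return The threshold `alpha * ones_fraction + beta`.
#' @export
adaptive_threshold <- function(coefs, ones_fraction) {
  coefs$alpha * ones_fraction + coefs$beta
}
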