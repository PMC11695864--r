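# Closed-form theory of the memory traces: binomial parity lemma,
# active-weight and firing probabilities, expected Hamming distances,
# overlapping-item extensions, and threshold optimization.
#
# All powers of (1 - p) are evaluated in log space so the formulas remain
# accurate at brain scale (m ~ 10^6, M ~ 10^5).

#' Probability that a binomial count is even / odd
#'
#' For `X ~ Binomial(N, p)`:
#' `P(X even) = (1 + (1 - 2p)^N) / 2` and
#' `P(X odd)  = (1 - (1 - 2p)^N) / 2`.
#' The parity of the number of update events is what determines a binary
#' weight after a sequence of flips, which makes these two functions the
#' backbone of the whole theory.
#'
#' @param N number of Bernoulli trials (non-negative integer, vectorised).
#' @param p success probability.
#' @return Probability in \[0, 1\].
#' @export
prob_even <- function(N, p) {
  check_prob(p, "p")
  if (any(N < 0)) stop("N must be >= 0")
  0.5 * (1 + (1 - 2 * p)^N)
}

#' @rdname prob_even
#' @export
prob_odd <- function(N, p) {
  1 - prob_even(N, p)
}

#' Theory parameter set
#'
#' Collects every parameter of the closed-form analysis: network sizes
#' (`m` inputs, `n` memory neurons), number of stored items `M`, input
#' density `f_p`, plateau probability `f_q`, connection probability
#' `f_w`, masking fraction `f_d`, firing threshold `v_th`, and the
#' common-ones count `c` for overlapping ensembles (0 for independent
#' items).  The density of the non-common bits,
#' `f_hat_p = (m f_p - c) / (m - c)`, is derived automatically.
#'
#' @param m,n,M counts.
#' @param f_p,f_q,f_w,f_d probabilities / fractions.
#' @param v_th integer firing threshold (may be `NULL` until optimised).
#' @param c number of common 1's shared by all items (default 0).
#' @return A list of class `theory_params`.
#' @export
theory_params <- function(m, n, M, f_p, f_q, f_w, f_d = 0.33, v_th = NULL,
                          c = 0) {
  check_count(m, "m"); check_count(n, "n"); check_count(M, "M")
  check_prob(f_p, "f_p"); check_prob(f_q, "f_q"); check_prob(f_w, "f_w")
  check_prob(f_d, "f_d")
  check_count(c, "c", min = 0)
  if (c >= m) stop("c must be smaller than m")
  f_hat_p <- if (c == 0) f_p else (m * f_p - c) / (m - c)
  if (f_hat_p < 0 || f_hat_p > 1)
    stop("derived f_hat_p = ", signif(f_hat_p, 4), " is outside [0, 1]")
  structure(list(m = m, n = n, M = M, f_p = f_p, f_q = f_q, f_w = f_w,
                 f_d = f_d, v_th = if (is.null(v_th)) NULL else
                   as.integer(v_th),
                 c = as.integer(c), f_hat_p = f_hat_p),
            class = "theory_params")
}

# (1 - q)^N computed in log space; q in [0, 1], N >= 0
pow1m <- function(q, N) {
  if (q >= 1) return(as.numeric(N == 0))
  exp(N * log1p(-q))
}

#' Probability that a synapse on a plateau neuron is strong after learning
#'
#' `p_e = (1 + (1 - f_p f_q)^(M-1)) / 2` is the probability that a
#' connected synapse from an active input bit onto a memory neuron that
#' received (and acted on) a plateau potential for that item remains
#' strong after all `M` items have been learned: the item's own update
#' sets the weight to 1 and each of the other `M - 1` items flips it with
#' probability `f_p f_q / 2`, so the weight survives iff the number of
#' later flips is even.  `p_o` is the complementary case (no plateau for
#' the item): the weight is strong iff an odd number of other items
#' flipped it.
#'
#' @param M number of stored items.
#' @param f_p input density.
#' @param f_q plateau probability.
#' @return Probability in \[0, 1\].
#' @export
p_e <- function(M, f_p, f_q) {
  check_count(M, "M")
  0.5 * (1 + pow1m(f_p * f_q, M - 1))
}

#' @rdname p_e
#' @export
p_o <- function(M, f_p, f_q) {
  check_count(M, "M")
  0.5 * (1 - pow1m(f_p * f_q, M - 1))
}

#' Conditional firing probabilities of a memory neuron
#'
#' Given that the cue has `I` active bits, a memory neuron that received
#' a plateau for the item fires with probability
#' `p_f1 = 1 - F(v_th; I, f_w p_e)` (binomial survival function, strict
#' threshold), and one that did not with
#' `p_f2 = 1 - F(v_th; I, f_w p_o)`.
#'
#' @param I number of active bits in the cue (vectorised).
#' @param v_th firing threshold.
#' @param f_w connection probability.
#' @param p_active per-synapse strong probability (`p_e` or `p_o`).
#' @return Probability in \[0, 1\].
#' @export
p_f1 <- function(I, v_th, f_w, p_active) {
  1 - stats::pbinom(v_th, I, f_w * p_active)
}

#' @rdname p_f1
#' @export
p_f2 <- p_f1

# Truncated support-size distribution: I within mean +/- 10 SD.
# Returns the index vector, the binomial weights, and the neglected mass.
i_range <- function(m, f_p) {
  mu <- m * f_p
  sd <- sqrt(m * f_p * (1 - f_p))
  lo <- max(0, floor(mu - 10 * sd))
  hi <- min(m, ceiling(mu + 10 * sd))
  Is <- lo:hi
  w <- stats::dbinom(Is, m, f_p)
  list(I = Is, w = w, tail = max(0, 1 - sum(w)))
}

#' Average firing probability of a memory neuron
#'
#' Marginalises the conditional firing probabilities over the plateau
#' indicator (probability `f_q`) and the binomial support size
#' `I ~ Binomial(m, f_p)`:
#' `p_favg = sum_I P(I) (f_q p_f1(I) + (1 - f_q) p_f2(I))`.
#' The `I`-sum is truncated to the mean +/- 10 standard deviations; the
#' neglected binomial mass (an upper bound on the truncation error) is
#' attached as attribute `"truncation_error"`.
#'
#' `n * p_favg` predicts the mean memory-trace size.
#'
#' @param params a [theory_params()] with `v_th` set.
#' @return Probability, with attribute `truncation_error`.
#' @export
p_favg <- function(params) {
  stopifnot(inherits(params, "theory_params"))
  if (is.null(params$v_th)) stop("params$v_th is not set")
  pe <- p_e(params$M, params$f_p, params$f_q)
  po <- p_o(params$M, params$f_p, params$f_q)
  ir <- i_range(params$m, params$f_p)
  val <- sum(ir$w * (params$f_q * p_f1(ir$I, params$v_th, params$f_w, pe) +
                     (1 - params$f_q) * p_f1(ir$I, params$v_th, params$f_w, po)))
  attr(val, "truncation_error") <- ir$tail
  val
}

#' Expected Hamming distance between traces of an item and its masked cue
#'
#' For a masking fraction `f_d`, a neuron contributes to the distance
#' when it fires for the full item but not for the masked cue (the
#' reverse is impossible for one-sided masking because the weighted sum
#' can only decrease).  Treating the two firing events as independent
#' within each plateau branch:
#' `E(HD) = n sum_I P(I) [ f_q F(v; I', fw pe)(1 - F(v; I, fw pe))
#'                       + (1-f_q) F(v; I', fw po)(1 - F(v; I, fw po)) ]`
#' with `I' = round(I (1 - f_d))` active bits surviving the mask.
#'
#' @param params a [theory_params()] with `v_th` set.
#' @param f_d masking fraction (defaults to `params$f_d`).
#' @return Expected Hamming distance (count, not a fraction).
#' @export
expected_hd_masked <- function(params, f_d = NULL) {
  stopifnot(inherits(params, "theory_params"))
  if (is.null(params$v_th)) stop("params$v_th is not set")
  if (is.null(f_d)) f_d <- params$f_d
  check_prob(f_d, "f_d")
  pe <- p_e(params$M, params$f_p, params$f_q)
  po <- p_o(params$M, params$f_p, params$f_q)
  ir <- i_range(params$m, params$f_p)
  Im <- round(ir$I * (1 - f_d))
  v <- params$v_th; fw <- params$f_w
  term <- params$f_q * stats::pbinom(v, Im, fw * pe) *
            (1 - stats::pbinom(v, ir$I, fw * pe)) +
          (1 - params$f_q) * stats::pbinom(v, Im, fw * po) *
            (1 - stats::pbinom(v, ir$I, fw * po))
  params$n * sum(ir$w * term)
}

#' Expected Hamming distance between traces of two different items
#'
#' Two independently drawn stored items fire a given neuron
#' independently with probability `p_favg`, so
#' `E(HD) = 2 n p_favg (1 - p_favg)`.
#'
#' @param params a [theory_params()] with `v_th` set.
#' @return Expected Hamming distance.
#' @export
expected_hd_pairs <- function(params) {
  p <- as.numeric(p_favg(params))
  2 * params$n * p * (1 - p)
}

#' Conditional strong-weight probabilities for overlapping items
#'
#' Overlapping-ensemble analogues of [p_e()] / [p_o()], conditioned on
#' the number `s` of items for which the neuron received a plateau
#' potential: `p_hat_e(s) = (1 + (1 - f_hat_p)^(s-1)) / 2` (the item's
#' own plateau is one of the `s`) and
#' `p_hat_o(s) = (1 - (1 - f_hat_p)^s) / 2`.
#'
#' @param s plateau count for the neuron (`s >= 1` for `p_hat_e`).
#' @param f_hat_p density of the non-common bits.
#' @return Probability in \[0, 1\].
#' @export
p_hat_e <- function(s, f_hat_p) {
  if (any(s < 1))
    stop("p_hat_e conditions on the item's own plateau; s must be >= 1")
  check_prob(f_hat_p, "f_hat_p")
  0.5 * (1 + (1 - f_hat_p)^(s - 1))
}

#' @rdname p_hat_e
#' @export
p_hat_o <- function(s, f_hat_p) {
  if (any(s < 0)) stop("s must be >= 0")
  check_prob(f_hat_p, "f_hat_p")
  0.5 * (1 - (1 - f_hat_p)^s)
}

# P(B_c + B_nc > v) where B_c ~ Binom(c1, fw) counts active common inputs
# (all common synapses strong) and B_nc ~ Binom(I, fw * p) the non-common
# ones.  Vectorised over I.
fire_with_common <- function(v, c1, I, fw, p) {
  if (c1 == 0) return(1 - stats::pbinom(v, I, fw * p))
  k <- 0:c1
  wk <- stats::dbinom(k, c1, fw)
  out <- numeric(length(I))
  for (i in seq_along(k))
    out <- out + wk[i] * (1 - stats::pbinom(v - k[i], I, fw * p))
  out
}

# P(B_c + B_nc <= v), the complementary cdf convolution
cdf_with_common <- function(v, c1, I, fw, p) {
  if (c1 == 0) return(stats::pbinom(v, I, fw * p))
  k <- 0:c1
  wk <- stats::dbinom(k, c1, fw)
  out <- numeric(length(I))
  for (i in seq_along(k))
    out <- out + wk[i] * stats::pbinom(v - k[i], I, fw * p)
  out
}

#' Theory predictions for overlapping memory items
#'
#' Extends the firing-probability and Hamming-distance predictions to
#' ensembles in which all items share `c` common 1's.  The common-bit
#' synapses of a neuron are updated by *every* item in its plateau set
#' `S(j)`, so after learning they are all strong or all weak together,
#' according to the parity of `|S(j)|`; for a neuron with a plateau for
#' the probe item `|S(j)| = 1 + Binomial(M-1, f_q)` and the common block
#' is strong with probability `prob_even(M-1, f_q)`, while without the
#' plateau it is strong with probability `prob_odd(M-1, f_q)`.  When
#' strong, the block contributes `Binomial(c, f_w)` active inputs.  The
#' non-common bits act through the plateau-count-marginalised versions of
#' `p_hat_e` / `p_hat_o`, which collapse exactly to [p_e()] / [p_o()]
#' (and the whole prediction to the random-item formulas) when `c = 0`.
#'
#' @param params a [theory_params()] with `v_th` set and `c >= 0`.
#' @param f_d masking fraction (defaults to `params$f_d`).
#' @return A list with `p_favg`, `expected_hd_masked`,
#'   `expected_hd_pairs`.
#' @export
overlapping_predictions <- function(params, f_d = NULL) {
  stopifnot(inherits(params, "theory_params"))
  if (is.null(params$v_th)) stop("params$v_th is not set")
  if (is.null(f_d)) f_d <- params$f_d
  m <- params$m; n <- params$n; M <- params$M
  c1 <- params$c; fw <- params$f_w; fq <- params$f_q; v <- params$v_th
  fhp <- params$f_hat_p
  # non-common strong probabilities, marginalised over the plateau count
  pe_nc <- 0.5 * (1 + pow1m(fq * fhp, M - 1))
  po_nc <- 0.5 * (1 - pow1m(fq * fhp, M - 1))
  # probability that the common block is strong
  strong_e <- prob_even(M - 1, fq)   # own plateau makes |S(j)| = 1 + even
  strong_o <- prob_odd(M - 1, fq)
  ir <- i_range(m - c1, fhp)          # non-common ones count
  Inc <- ir$I
  Inc_m <- round(Inc * (1 - f_d))
  c_m <- round(c1 * (1 - f_d))        # common 1's surviving the mask
  branch <- function(strong_p, p_nc) {
    fire_full_s <- fire_with_common(v, c1, Inc, fw, p_nc)
    fire_full_w <- 1 - stats::pbinom(v, Inc, fw * p_nc)
    silent_mask_s <- cdf_with_common(v, c_m, Inc_m, fw, p_nc)
    silent_mask_w <- stats::pbinom(v, Inc_m, fw * p_nc)
    hd_s <- fire_full_s * silent_mask_s
    hd_w <- fire_full_w * silent_mask_w
    # written as base + strong_p * (difference) so that c = 0 collapses
    # bit-exactly onto the random-item formulas
    list(favg = fire_full_w + strong_p * (fire_full_s - fire_full_w),
         hd = hd_w + strong_p * (hd_s - hd_w))
  }
  be <- branch(strong_e, pe_nc)
  bo <- branch(strong_o, po_nc)
  favg <- sum(ir$w * (fq * be$favg + (1 - fq) * bo$favg))
  hd_masked <- n * sum(ir$w * (fq * be$hd + (1 - fq) * bo$hd))
  list(p_favg = favg,
       expected_hd_masked = hd_masked,
       expected_hd_pairs = 2 * n * favg * (1 - favg))
}

#' Optimise the firing threshold
#'
#' Selects the integer threshold that minimises the predicted relative
#' dissimilarity `E(HD masked) / E(HD pairs)` at a fixed masking fraction
#' (1/3 by default) and the maximal load `M`.  Ties are broken toward
#' the smaller threshold.  Uses the overlapping-item predictions when
#' `params$c > 0`.
#'
#' @param params a [theory_params()] (its `v_th` is ignored).
#' @param f_d masking fraction used for the objective (default 0.33).
#' @param v_max largest threshold scanned (default 200).
#' @return The optimal integer threshold, with the objective curve
#'   attached as attribute `"objective"`.
#' @export
optimize_threshold <- function(params, f_d = 0.33, v_max = 200) {
  stopifnot(inherits(params, "theory_params"))
  obj <- vapply(seq_len(v_max), function(v) {
    p <- params; p$v_th <- as.integer(v)
    if (params$c > 0) {
      pred <- overlapping_predictions(p, f_d = f_d)
      num <- pred$expected_hd_masked; den <- pred$expected_hd_pairs
    } else {
      num <- expected_hd_masked(p, f_d = f_d)
      den <- expected_hd_pairs(p)
    }
    if (!is.finite(den) || den <= 0) NA_real_ else num / den
  }, numeric(1))
  if (all(is.na(obj)))
    stop("all thresholds give degenerate predictions; cannot optimise")
  best <- which.min(obj)          # which.min takes the first (smallest) tie
  structure(as.integer(best), objective = obj)
}
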