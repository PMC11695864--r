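# Classical comparators: Hopfield network with covariance-rule weights,
# random projections with fixed threshold or Top-K output, and the random
# linear readout robustness measure.

#' Store patterns in a Hopfield network
#'
#' Covariance-rule weights for sparse binary patterns:
#' `w_ji = (1/m) sum_h (x_hi - f_p)(x_hj - f_p)` for `i != j`, zero on
#' the diagonal.  The network is recurrent over the `m` pattern bits
#' themselves (the stored items are their own attractors), and can be
#' diluted with a symmetric connectivity mask of density `f_w` to match
#' the BTSP network's connection probability.
#'
#' @param patterns a `pattern_ensemble` (items of length `m`).
#' @param f_p input density used for the covariance offset.
#' @param f_w optional connection probability; `NULL` for full coupling.
#' @param seed optional seed for the connectivity mask.
#' @return A list of class `hopfield_net` with weight matrix `W` (`m x m`),
#'   the mask, and `binary = FALSE`.
#' @export
hfn_store <- function(patterns, f_p, f_w = NULL, seed = NULL) {
  stopifnot(inherits(patterns, "pattern_ensemble"))
  X <- patterns$items
  m <- ncol(X)
  Xc <- X - f_p
  W <- crossprod(Xc) / m          # (1/m) sum_h (x_hi - f_p)(x_hj - f_p)
  diag(W) <- 0
  mask <- NULL
  if (!is.null(f_w)) {
    check_prob(f_w, "f_w")
    if (!is.null(seed)) set.seed(seed)
    up <- matrix(stats::runif(m * m) < f_w, m, m)
    mask <- up
    mask[lower.tri(mask)] <- t(up)[lower.tri(mask)]   # symmetric dilution
    diag(mask) <- FALSE
    W[!mask] <- 0
  }
  structure(list(W = W, mask = mask, m = m, binary = FALSE),
            class = "hopfield_net")
}

#' Recall from a Hopfield network
#'
#' Synchronous thresholded updates: all neurons set their state to 1 iff
#' their weighted sum strictly exceeds `theta`, iterated `max_iter` times
#' (default 100) or until a fixed point.  Synchronous dynamics can fall
#' into a 2-cycle; this is detected and flagged, and the last state is
#' returned.
#'
#' @param net a [hfn_store()] result.
#' @param cue binary vector of length `m`.
#' @param theta state-update threshold.
#' @param max_iter iteration cap.
#' @return The final binary state with attributes `iterations`,
#'   `fixed_point` and `two_cycle`.
#' @export
hfn_recall <- function(net, cue, theta, max_iter = 100) {
  if (inherits(cue, "cue")) cue <- cue$vector
  if (length(cue) != net$m) stop("cue length does not match network size")
  s <- as.numeric(cue)
  prev <- NULL
  fixed <- FALSE; cycle <- FALSE; it <- 0
  for (it in seq_len(max_iter)) {
    s_new <- as.numeric(net$W %*% s > theta)
    if (all(s_new == s)) { fixed <- TRUE; s <- s_new; break }
    if (!is.null(prev) && all(s_new == prev)) { cycle <- TRUE; s <- s_new; break }
    prev <- s
    s <- s_new
  }
  structure(as.integer(s), iterations = it, fixed_point = fixed,
            two_cycle = cycle)
}

#' Grid-search the Hopfield state threshold
#'
#' Scans `grid` and returns the threshold maximising the number of items
#' recalled correctly from masked cues, where "correct" means the final
#' state is within Hamming distance `m * 0.001` of the stored pattern.
#'
#' @param net a `hopfield_net`.
#' @param patterns the stored `pattern_ensemble`.
#' @param f_d masking fraction for the recall cues (default 0.33).
#' @param grid candidate thresholds (default 101 values on \[0, 0.02\]).
#' @param items optional subset of item indices to evaluate.
#' @param max_iter iteration cap per recall.
#' @param seed optional seed for the cue masking.
#' @return The best threshold, with the per-threshold success counts
#'   attached as attribute `"successes"`.
#' @export
hfn_optimize_theta <- function(net, patterns, f_d = 0.33,
                               grid = seq(0, 0.02, length.out = 101),
                               items = NULL, max_iter = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) items <- seq_len(patterns$M)
  tol <- net$m * 0.001
  cues <- lapply(items, function(k)
    mask_pattern(patterns$items[k, ], f_d)$vector)
  succ <- vapply(grid, function(th) {
    sum(vapply(seq_along(items), function(ii) {
      s <- hfn_recall(net, cues[[ii]], th, max_iter = max_iter)
      hamming(s, patterns$items[items[ii], ]) <= tol
    }, logical(1)))
  }, numeric(1))
  structure(grid[which.max(succ)], successes = succ)
}

#' Binarize Hopfield weights
#'
#' Sign quantisation to \{-1, 0, +1\} (zeros stay zero).  Used to
#' demonstrate the capacity collapse of Hopfield networks under binary
#' weight constraints.
#'
#' @param net a `hopfield_net`.
#' @return The net with `W` replaced by `sign(W)` and `binary = TRUE`.
#' @export
hfn_binarize <- function(net) {
  net$W <- sign(net$W)
  net$binary <- TRUE
  net
}

#' Build a random projection
#'
#' A fixed binary `n x m` matrix with i.i.d. Bernoulli(`density`)
#' entries.  For a fair comparison with BTSP the density is matched to
#' the overall fraction of 1-weights that BTSP learning produces
#' (strong-weight fraction times connection probability).
#'
#' @param density probability of a 1 entry.
#' @param m input dimension.
#' @param n output dimension.
#' @param seed optional seed.
#' @param threshold output binarisation threshold (strict `>`), settable
#'   later via [rp_optimize_threshold()].
#' @return A list of class `random_projection`.
#' @export
rp_build <- function(density, m, n, seed = NULL, threshold = 0) {
  check_prob(density, "density")
  if (!is.null(seed)) set.seed(seed)
  R <- matrix(as.numeric(stats::runif(n * m) < density), nrow = n, ncol = m)
  structure(list(R = R, m = m, n = n, density = density,
                 threshold = threshold),
            class = "random_projection")
}

#' Threshold-binarised random projection output
#'
#' @param rp a [rp_build()] result.
#' @param cue binary input vector.
#' @param threshold override of the stored threshold.
#' @return Integer trace of length `n`.
#' @export
rp_recall <- function(rp, cue, threshold = NULL) {
  if (inherits(cue, "cue")) cue <- cue$vector
  if (length(cue) != rp$m) stop("cue length does not match projection")
  th <- if (is.null(threshold)) rp$threshold else threshold
  as.integer(rp$R %*% cue > th)
}

#' Grid-search the random-projection threshold
#'
#' Chooses the integer output threshold minimising the relative
#' dissimilarity of the projected traces under masked cues at `f_d`
#' (the same criterion used for the BTSP threshold).
#'
#' @param rp a `random_projection`.
#' @param ensemble the `pattern_ensemble` to be represented.
#' @param f_d masking fraction (default 0.33).
#' @param items optional subset of items used for the search.
#' @param n_pairs random pairs for the dissimilarity denominator.
#' @param seed optional seed.
#' @return The `random_projection` with its `threshold` set; the
#'   objective curve is attached as attribute `"objective"`.
#' @export
rp_optimize_threshold <- function(rp, ensemble, f_d = 0.33, items = NULL,
                                  n_pairs = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) items <- seq_len(ensemble$M)
  X <- ensemble$items[items, , drop = FALSE]
  U <- rp$R %*% t(X)                     # n x items
  Um <- vapply(seq_along(items), function(ii)
    as.numeric(rp$R %*% mask_pattern(X[ii, ], f_d)$vector),
    numeric(rp$n))
  cand <- seq(0, max(U))
  pairs <- matrix(replicate(n_pairs, sample.int(length(items), 2)), nrow = 2)
  obj <- vapply(cand, function(th) {
    Z <- U > th; Zm <- Um > th
    # thresholds that empty the traces are degenerate, not optimal: a
    # memory with (on average) less than one active output neuron per
    # item cannot represent anything, however small its distance ratio
    if (mean(colSums(Z)) < 1) return(NA_real_)
    num <- mean(colSums(Z != Zm))
    den <- mean(vapply(seq_len(n_pairs), function(p)
      sum(Z[, pairs[1, p]] != Z[, pairs[2, p]]), numeric(1)))
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  if (all(is.na(obj))) stop("degenerate projection: no usable threshold")
  rp$threshold <- cand[which.min(obj)]
  attr(rp$threshold, "objective") <- obj
  rp
}

#' Top-K binarised random projection output
#'
#' Exactly the `K` output units with the largest projection values are
#' set to 1 (ties broken toward the lowest index), emulating a global
#' winner-take-all stage; `K = floor(n f_q)` matches the expected number
#' of plateau neurons per item.  An all-zero cue yields an all-zero
#' trace.
#'
#' @param rp a `random_projection`.
#' @param cue binary input vector.
#' @param K number of active outputs.
#' @return Integer trace with exactly `K` (or 0) ones.
#' @export
rp_topk <- function(rp, cue, K) {
  if (inherits(cue, "cue")) cue <- cue$vector
  check_count(K, "K")
  if (K > rp$n) stop("K cannot exceed the number of output units")
  u <- as.numeric(rp$R %*% cue)
  z <- integer(rp$n)
  if (sum(cue) == 0) return(z)
  top <- order(-u, seq_along(u))[seq_len(K)]
  z[top] <- 1L
  z
}

#' Robustness of a generic downstream readout
#'
#' A thresholded linear readout with random integer weights (uniform on
#' -8..8, threshold 0) classifies each trace.  The error is the fraction
#' of items whose binary label changes between the trace of the full item
#' and the trace of its masked cue, averaged over `n_readouts`
#' independent readouts.
#'
#' @param traces_full,traces_masked matrices with one trace per column,
#'   identically ordered.
#' @param n_readouts number of random readouts averaged (default 20).
#' @param seed optional seed.
#' @return Mean error fraction, with per-readout errors as attribute
#'   `"per_readout"`.
#' @export
readout_robustness <- function(traces_full, traces_masked, n_readouts = 20,
                               seed = NULL) {
  stopifnot(all(dim(traces_full) == dim(traces_masked)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(traces_full)
  errs <- vapply(seq_len(n_readouts), function(r) {
    w <- sample(-8:8, n, replace = TRUE)
    lab_full <- drop(w %*% traces_full) > 0
    lab_mask <- drop(w %*% traces_masked) > 0
    mean(lab_full != lab_mask)
  }, numeric(1))
  structure(mean(errs), per_readout = errs)
}
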