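# Feedforward recall and trace-level metrics.

#' Construct a BTSP memory network
#'
#' A pool of `n` disconnected McCulloch-Pitts memory neurons receiving
#' binary-weight synapses from `m` input neurons through a fixed random
#' connectivity mask.  A neuron fires iff its weighted input sum strictly
#' exceeds the firing threshold `v_th`.
#'
#' @param W numeric `n x m` matrix of binary weights.
#' @param mask logical `n x m` connectivity mask; weights must be 0
#'   wherever the mask is `FALSE`.
#' @param v_th integer firing threshold (strict `>`).
#' @return A list of class `btsp_network`.
#' @export
btsp_network <- function(W, mask, v_th = 0L) {
  stopifnot(is.matrix(W), is.matrix(mask), all(dim(W) == dim(mask)))
  if (v_th < 0) stop("v_th must be >= 0")
  if (any(W[!mask] != 0)) stop("weights present outside the connectivity mask")
  structure(list(W = W, mask = mask, n = nrow(W), m = ncol(W),
                 v_th = as.integer(v_th)),
            class = "btsp_network")
}

#' @export
print.btsp_network <- function(x, ...) {
  cat(sprintf("<btsp_network> %d inputs -> %d memory neurons, v_th = %d\n",
              x$m, x$n, x$v_th))
  cat(sprintf("  connectivity density %.3f, strong-weight fraction %.4f\n",
              mean(x$mask), strong_weight_fraction(x)))
  invisible(x)
}

#' Build a random connectivity mask
#'
#' Each of the `n x m` potential synapses exists independently with
#' probability `f_w` (default 0.6, giving memory neurons an expected
#' in-degree of `0.6 m`).
#'
#' @param m number of input neurons.
#' @param n number of memory neurons.
#' @param f_w connection probability.
#' @param seed optional integer seed.
#' @return Logical `n x m` matrix.
#' @export
build_connectivity <- function(m, n, f_w, seed = NULL) {
  check_count(m, "m"); check_count(n, "n"); check_prob(f_w, "f_w")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::runif(n * m) < f_w, nrow = n, ncol = m)
}

#' Recall a memory trace
#'
#' The memory trace of a cue is the binary vector of memory neurons whose
#' weighted input sum strictly exceeds `v_th`.
#'
#' @param net a [btsp_network()].
#' @param x binary cue vector of length `m` (or a `cue` object).
#' @return Integer vector of length `n` with entries in \{0, 1\}.
#' @export
recall <- function(net, x) {
  if (inherits(x, "cue")) x <- x$vector
  if (length(x) != net$m)
    stop("cue length ", length(x), " does not match input size ", net$m)
  as.integer(weighted_sums(net$W, x) > net$v_th)
}

# weighted input sums exploiting cue sparsity: only the active columns
# of W contribute
weighted_sums <- function(W, x) {
  S <- which(x == 1)
  if (length(S) == 0) return(numeric(nrow(W)))
  if (length(S) == 1) return(W[, S])
  rowSums(W[, S, drop = FALSE])
}

#' Recall traces for many cues at once
#'
#' @param net a [btsp_network()].
#' @param X matrix with one cue per row.
#' @return Integer `n x nrow(X)` matrix, one trace per column.
#' @export
recall_many <- function(net, X) {
  if (ncol(X) != net$m) stop("cue length does not match input size")
  Z <- net$W %*% t(X) > net$v_th
  storage.mode(Z) <- "integer"
  Z
}

#' Hamming distance between two binary vectors
#' @param z1,z2 binary vectors of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("vectors differ in length")
  sum(z1 != z2)
}

#' Relative dissimilarity of recalled traces
#'
#' The Hamming distance between the trace of each stored item and the
#' trace of its degraded cue, divided by the average Hamming distance
#' between traces of two different stored items.  A ratio of 0.5 means a
#' cue's trace is indistinguishable from that of an unrelated item; good
#' recall requires values well below 0.5.  All traces are computed after
#' the whole sequence has been learned.  The pairwise denominator is
#' estimated from `n_pairs` random distinct pairs.
#'
#' @param net a [btsp_network()] after learning.
#' @param ensemble the stored `pattern_ensemble`.
#' @param f_d masking fraction used to degrade each cue.
#' @param mode `"masked"` (one-sided) or `"two_sided"` cues.
#' @param items indices of items to probe (default: all).
#' @param n_pairs number of random pairs for the denominator.
#' @param seed optional integer seed.
#' @return A list with `ratio`, `numerator`, `denominator`, per-item
#'   distances `hd_masked`, and a `degenerate` flag (`TRUE` when the
#'   denominator is zero, in which case `ratio` is `NA`).
#' @export
relative_dissimilarity <- function(net, ensemble, f_d, mode = "masked",
                                   items = NULL, n_pairs = 1000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(items)) items <- seq_len(ensemble$M)
  Z <- recall_many(net, ensemble$items[items, , drop = FALSE])
  cue_of <- function(k) {
    x <- ensemble$items[k, ]
    if (mode == "masked") mask_pattern(x, f_d)$vector
    else perturb_pattern(x, f_d)$vector
  }
  hd_masked <- vapply(seq_along(items), function(ii) {
    zp <- recall(net, cue_of(items[ii]))
    sum(zp != Z[, ii])
  }, numeric(1))
  numerator <- mean(hd_masked)
  if (length(items) < 2) stop("need at least two items for the denominator")
  pairs <- matrix(replicate(n_pairs, sample.int(length(items), 2)), nrow = 2)
  denominator <- mean(vapply(seq_len(n_pairs), function(p) {
    sum(Z[, pairs[1, p]] != Z[, pairs[2, p]])
  }, numeric(1)))
  degenerate <- denominator == 0
  if (degenerate) warning("pairwise Hamming distance is zero; ratio undefined")
  list(ratio = if (degenerate) NA_real_ else numerator / denominator,
       numerator = numerator, denominator = denominator,
       hd_masked = hd_masked, degenerate = degenerate)
}

#' Mean memory-trace size
#'
#' Average number of memory neurons that fire during recall with the full
#' (unmasked) stored items.
#'
#' @param net a [btsp_network()].
#' @param ensemble the stored `pattern_ensemble`.
#' @param items optional subset of item indices.
#' @return Mean ones-count of the traces.
#' @export
trace_size <- function(net, ensemble, items = NULL) {
  if (is.null(items)) items <- seq_len(ensemble$M)
  Z <- recall_many(net, ensemble$items[items, , drop = FALSE])
  mean(colSums(Z))
}

#' Fraction of strong synaptic weights
#'
#' Fraction of existing connections whose binary weight is 1.
#'
#' @param net a [btsp_network()].
#' @return A fraction in \[0, 1\].
#' @export
strong_weight_fraction <- function(net) {
  sum(net$W) / sum(net$mask)
}

#' Overlap ratio of two memory traces
#'
#' Number of common 1's of the two traces divided by the average number
#' of 1's in a memory trace (the same normalisation that fMRI repulsion
#' studies apply to voxel patterns via correlation).
#'
#' @param z1,z2 binary traces.
#' @param mean_ones average ones-count per trace over the stored ensemble.
#' @return The overlap ratio; `NA` with a warning if `mean_ones` is 0.
#' @export
overlap_ratio <- function(z1, z2, mean_ones) {
  if (mean_ones <= 0) {
    warning("mean trace size is zero; overlap ratio undefined")
    return(NA_real_)
  }
  sum(z1 == 1 & z2 == 1) / mean_ones
}

#' Repulsion index
#'
#' Overlap ratio of the traces of a pair of unrelated memory items
#' divided by the overlap ratio for a pair of similar items (40% common
#' 1's in the standard protocol).  Values above 1 indicate repulsion:
#' similar items are mapped to traces that overlap *less* than those of
#' unrelated items.
#'
#' @param overlap_unrelated overlap ratio of the unrelated pair.
#' @param overlap_similar overlap ratio of the similar pair.
#' @return The index; `NA` with a warning when the similar-pair overlap
#'   is zero.
#' @export
repulsion_index <- function(overlap_unrelated, overlap_similar) {
  if (is.na(overlap_similar) || overlap_similar == 0) {
    warning("similar-pair overlap is zero; repulsion index undefined")
    return(NA_real_)
  }
  overlap_unrelated / overlap_similar
}

#' Weighted-sum distributions at a memory neuron
#'
#' For one memory neuron, the weighted input sums across all stored items
#' are split by whether the neuron received a plateau potential when the
#' item was learned.  After BTSP learning this distribution is bimodal -
#' plateau items produce markedly larger sums - which is what allows a
#' threshold separating the two clusters and hence masking-robust traces.
#'
#' @param net a [btsp_network()] carrying its `plateaus` schedule (as
#'   returned by [learn_sequence()]), or supply `plateaus` explicitly.
#' @param ensemble the stored `pattern_ensemble`.
#' @param neuron index of the memory neuron.
#' @param plateaus optional `plateau_schedule` overriding `net$plateaus`.
#' @return A list with numeric vectors `plateau` and `no_plateau` of
#'   weighted sums, and `separation` = (min of plateau sums) - (max of
#'   no-plateau sums); positive values mean the clusters are disjoint.
#' @export
weighted_sum_histogram <- function(net, ensemble, neuron, plateaus = NULL) {
  if (is.null(plateaus)) plateaus <- net$plateaus
  if (is.null(plateaus)) stop("no plateau schedule available")
  u <- as.numeric(ensemble$items %*% net$W[neuron, ])
  has_plateau <- plateaus$mask[, neuron]
  plate <- u[has_plateau]
  rest <- u[!has_plateau]
  sep <- if (length(plate) && length(rest)) min(plate) - max(rest) else NA_real_
  list(plateau = plate, no_plateau = rest, separation = sep)
}
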