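# The binary BTSP rule, its deterministic "core" variant, plateau
# generation, sequence learning, and the multi-release-site simulation.

#' Plasticity rule configuration
#'
#' The stochastic rule flips the binary weight of every synapse that (a)
#' receives input (`x_i = 1`), (b) sits on a neuron with a plateau
#' potential for the current item, and (c) exists in the connectivity
#' mask - but only when the item's arrival time falls into the plastic
#' part of the seconds-long window opened by the plateau.  That timing is
#' one random variable per (neuron, item), so the update decision is a
#' single Bernoulli(`p_update`) draw shared by all synapses of the neuron
#' for that item; the direction of each flip (LTP for weak synapses, LTD
#' for strong ones) is determined by the current weight.  The `core`
#' variant drops the timing draw (every plateau triggers the flips) and is
#' meant to be used with a halved plateau probability, which leaves the
#' effective learning rate unchanged.
#'
#' Setting `p_ltp`/`p_ltd` selects the asymmetric variant: two independent
#' per-(neuron, item) draws gate potentiation of weak synapses
#' (probability `p_ltp`) and depression of strong ones (`p_ltd`)
#' separately.
#'
#' @param rule `"eq1"` (stochastic, default) or `"core"` (deterministic
#'   flips).
#' @param p_update update probability of the stochastic rule (default 0.5).
#' @param p_ltp,p_ltd optional asymmetric LTP/LTD probabilities; both must
#'   be given together.
#' @return A list of class `plasticity_config`.
#' @export
plasticity_config <- function(rule = c("eq1", "core"), p_update = 0.5,
                              p_ltp = NULL, p_ltd = NULL) {
  rule <- match.arg(rule)
  check_prob(p_update, "p_update")
  asymmetric <- !is.null(p_ltp) || !is.null(p_ltd)
  if (asymmetric) {
    if (is.null(p_ltp) || is.null(p_ltd))
      stop("p_ltp and p_ltd must be supplied together")
    check_prob(p_ltp, "p_ltp"); check_prob(p_ltd, "p_ltd")
  }
  structure(list(rule = rule, p_update = p_update, p_ltp = p_ltp,
                 p_ltd = p_ltd, asymmetric = asymmetric),
            class = "plasticity_config")
}

#' Draw plateau-potential schedules
#'
#' During learning of each item, every memory neuron independently
#' receives a plateau potential with probability `f_q`.  The schedule is
#' an `M x n` logical matrix; row `k` is the plateau set Q(x_k).
#'
#' @param M number of memory items.
#' @param n number of memory neurons.
#' @param f_q plateau probability per neuron per item.
#' @param seed optional integer seed.
#' @return A list of class `plateau_schedule` with elements `mask`
#'   (`M x n` logical), `f_q` and `seed`.
#' @export
draw_plateaus <- function(M, n, f_q, seed = NULL) {
  check_count(M, "M", min = 0); check_count(n, "n"); check_prob(f_q, "f_q")
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(M * n) < f_q, nrow = M, ncol = n)
  structure(list(mask = mask, M = M, n = n, f_q = f_q,
                 seed = if (is.null(seed)) NA else seed),
            class = "plateau_schedule")
}

# Decide, per plateau neuron, which flip directions are gated on for this
# item.  Returns a list with logical vectors ltp / ltd over `Q`.
gate_draws <- function(nQ, cfg) {
  if (cfg$rule == "core") {
    list(ltp = rep(TRUE, nQ), ltd = rep(TRUE, nQ))
  } else if (cfg$asymmetric) {
    list(ltp = stats::runif(nQ) < cfg$p_ltp,
         ltd = stats::runif(nQ) < cfg$p_ltd)
  } else {
    g <- stats::runif(nQ) < cfg$p_update
    list(ltp = g, ltd = g)
  }
}

#' Apply one BTSP learning step
#'
#' Applies the binary BTSP rule for a single memory item: for every
#' neuron `j` in the plateau set `Q` whose update gate fires, each
#' connected synapse from an active input (`x_i = 1`) is flipped -
#' potentiated if currently 0, depressed if currently 1.  Weights outside
#' `Q`, outside the connectivity mask, or from silent inputs are
#' untouched.
#'
#' @param W binary `n x m` weight matrix (numeric 0/1).
#' @param mask logical `n x m` connectivity mask.
#' @param x binary input vector of length `m`.
#' @param Q integer indices of memory neurons with a plateau potential.
#' @param cfg a [plasticity_config()].
#' @param seed optional integer seed.
#' @return The updated weight matrix.
#' @export
btsp_step <- function(W, mask, x, Q, cfg = plasticity_config(), seed = NULL) {
  if (length(x) != ncol(W))
    stop("pattern length ", length(x), " does not match network input size ",
         ncol(W))
  if (!is.null(seed)) set.seed(seed)
  S <- which(x == 1)
  Q <- as.integer(Q)
  if (length(Q) == 0L || length(S) == 0L) return(W)
  g <- gate_draws(length(Q), cfg)
  sub <- W[Q, S, drop = FALSE]
  con <- mask[Q, S, drop = FALSE]
  flip <- con & ((sub == 0 & g$ltp) | (sub == 1 & g$ltd))
  sub[flip] <- 1 - sub[flip]
  W[Q, S] <- sub
  W
}

#' Apply one core-BTSP step (deterministic flips)
#'
#' Equivalent to [btsp_step()] with `rule = "core"`: every connected
#' synapse from an active input onto a plateau neuron is flipped with
#' certainty.  Intended for use with plateau schedules drawn at `f_q / 2`,
#' which makes the core rule equal in law to the stochastic rule at `f_q`.
#'
#' @inheritParams btsp_step
#' @export
core_btsp_step <- function(W, mask, x, Q) {
  btsp_step(W, mask, x, Q, cfg = plasticity_config(rule = "core"))
}

#' Learn a sequence of memory items with BTSP
#'
#' One-shot learning: weights start at zero and every item is presented
#' exactly once, in order.  Returns the resulting [btsp_network()];
#' with `keep_log = TRUE` the per-synapse update events are recorded so
#' the parity of logged events can be replayed against the final weights.
#'
#' @param patterns a `pattern_ensemble`.
#' @param plateaus a `plateau_schedule` with matching `M`.
#' @param mask logical `n x m` connectivity mask (see
#'   [build_connectivity()]).
#' @param cfg a [plasticity_config()].
#' @param v_th firing threshold stored on the returned network (can be set
#'   later; see [optimize_threshold()]).
#' @param seed optional integer seed governing the update gates.
#' @param keep_log record update events (`item`, `neuron`, `input`,
#'   `direction`)?  Memory-hungry; meant for small instances.
#' @return A [btsp_network()]; if `keep_log`, the event log is attached as
#'   `$update_log`.
#' @export
learn_sequence <- function(patterns, plateaus, mask, cfg = plasticity_config(),
                           v_th = 0L, seed = NULL, keep_log = FALSE) {
  stopifnot(inherits(patterns, "pattern_ensemble"),
            inherits(plateaus, "plateau_schedule"))
  if (patterns$M != plateaus$M)
    stop("patterns (M = ", patterns$M, ") and plateaus (M = ", plateaus$M,
         ") disagree")
  n <- plateaus$n; m <- patterns$m
  if (!all(dim(mask) == c(n, m)))
    stop("connectivity mask must be ", n, " x ", m)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, nrow = n, ncol = m)
  log_rows <- if (keep_log) vector("list", patterns$M) else NULL
  for (k in seq_len(patterns$M)) {
    S <- which(patterns$items[k, ] == 1L)
    Q <- which(plateaus$mask[k, ])
    if (length(Q) == 0L || length(S) == 0L) next
    g <- gate_draws(length(Q), cfg)
    sub <- W[Q, S, drop = FALSE]
    con <- mask[Q, S, drop = FALSE]
    flip <- con & ((sub == 0 & g$ltp) | (sub == 1 & g$ltd))
    if (keep_log && any(flip)) {
      idx <- which(flip, arr.ind = TRUE)
      log_rows[[k]] <- data.frame(
        item = k, neuron = Q[idx[, 1]], input = S[idx[, 2]],
        direction = ifelse(sub[flip] == 0, "ltp", "ltd"))
    }
    sub[flip] <- 1 - sub[flip]
    W[Q, S] <- sub
  }
  net <- btsp_network(W = W, mask = mask, v_th = v_th)
  net$plateaus <- plateaus
  net$cfg <- cfg
  if (keep_log)
    net$update_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                      logical(1))])
  net
}

#' Mean weight change at a multi-release-site connection
#'
#' Two neurons joined by `n_sites` release sites, each with an independent
#' binary weight, emulate a graded synapse.  Initial site weights are
#' i.i.d. Bernoulli(0.5); a single BTSP event (plateau present, input
#' present) is applied per trial.  The net change of the summed weight is
#' reported stratified by the initial sum: with flips gated at
#' probability `p`, its expectation is `p * (n_sites - 2 * k)` for initial
#' sum `k`, so weak connections potentiate and strong ones depress on
#' average - the signature of a graded rule recovered from binary parts.
#'
#' @param n_sites number of release sites (default 8).
#' @param n_trials number of simulated trials (default 10,000).
#' @param cfg a [plasticity_config()].
#' @param seed optional integer seed.
#' @return A data frame with columns `initial_sum`, `mean_change`,
#'   `expected_change` (closed form) and `n_trials`.
#' @export
multi_release_site_change <- function(n_sites = 8, n_trials = 10000,
                                      cfg = plasticity_config(),
                                      seed = NULL) {
  check_count(n_sites, "n_sites"); check_count(n_trials, "n_trials")
  if (!is.null(seed)) set.seed(seed)
  w0 <- matrix(stats::runif(n_trials * n_sites) < 0.5, nrow = n_trials)
  k0 <- rowSums(w0)
  g <- gate_draws(n_trials, cfg)
  # flipping all weak sites adds (n_sites - k0); flipping strong removes k0
  delta <- ifelse(g$ltp, n_sites - k0, 0) - ifelse(g$ltd, k0, 0)
  p_ltp <- if (cfg$rule == "core") 1 else if (cfg$asymmetric) cfg$p_ltp else cfg$p_update
  p_ltd <- if (cfg$rule == "core") 1 else if (cfg$asymmetric) cfg$p_ltd else cfg$p_update
  out <- data.frame(initial_sum = 0:n_sites)
  out$mean_change <- vapply(out$initial_sum, function(k) {
    sel <- k0 == k
    if (!any(sel)) NA_real_ else mean(delta[sel])
  }, numeric(1))
  out$expected_change <- p_ltp * (n_sites - out$initial_sum) -
    p_ltd * out$initial_sum
  out$n_trials <- vapply(out$initial_sum, function(k) sum(k0 == k), numeric(1))
  out
}
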