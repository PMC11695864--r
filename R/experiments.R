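# Figure-level experiment runners: masking sweeps with theory overlays,
# model comparison, overlapping items, completion, repulsion, release
# sites, and brain-scale theory evaluation.  All runners return tidy data
# frames keyed by parameters and seed.

#' Parameter presets
#'
#' `preset_reduced()` is the default testing scale: `m = 2500`,
#' `n = 3900`, `f_p = 0.02`, `f_q = 0.01`, `f_w = 0.6`, `M = 2000`.  It
#' keeps the expected ones-per-item (`m f_p = 50`), plateau neurons per
#' item (`n f_q = 39`) and fan-in proportionate to the biologically
#' motivated full scale, `preset_paper()` (`m = 25000`, `n = 39000`,
#' `f_p = f_q = 0.005`, `M = 30000`), so the closed-form theory remains a
#' valid oracle while runs complete in seconds on one CPU.
#'
#' @return Named list of parameters.
#' @export
preset_reduced <- function() {
  list(m = 2500, n = 3900, f_p = 0.02, f_q = 0.01, f_w = 0.6, M = 2000)
}

#' @rdname preset_reduced
#' @export
preset_paper <- function() {
  list(m = 25000, n = 39000, f_p = 0.005, f_q = 0.005, f_w = 0.6, M = 30000)
}

# learn one network from scratch under a preset-like parameter list
learn_network <- function(p, cfg = plasticity_config(), v_th, seed) {
  ens <- gen_random_patterns(p$M, p$m, p$f_p, seed = seed)
  pls <- draw_plateaus(p$M, p$n, p$f_q, seed = seed + 1L)
  mask <- build_connectivity(p$m, p$n, p$f_w, seed = seed + 2L)
  net <- learn_sequence(ens, pls, mask, cfg = cfg, v_th = v_th,
                        seed = seed + 3L)
  list(net = net, ensemble = ens, plateaus = pls, mask = mask)
}

#' Trace metrics under masking, simulation vs theory
#'
#' For each combination of `f_q` and `M`, learns a fresh network
#' (threshold from [optimize_threshold()] at the largest `M`), measures
#' mean trace size, strong-weight fraction and relative dissimilarity
#' under each masking fraction, and pairs every measurement with its
#' closed-form prediction.
#'
#' @param p parameter list (see [preset_reduced()]).
#' @param f_q_values plateau probabilities to sweep.
#' @param M_values memory loads to sweep.
#' @param f_d_values masking fractions to sweep.
#' @param replicates independent repetitions per point.
#' @param seed base seed; replicate `r` of a point uses `seed + r`.
#' @param items_probe number of items probed for dissimilarity.
#' @return Tidy data frame with columns `metric`, `simulated`,
#'   `predicted` and the sweep parameters.
#' @export
run_masking_experiment <- function(p = preset_reduced(),
                                   f_q_values = p$f_q,
                                   M_values = p$M,
                                   f_d_values = c(0.1, 0.2, 0.33, 0.5),
                                   replicates = 5, seed = 1,
                                   items_probe = 200) {
  out <- list()
  for (fq in f_q_values) for (M in M_values) {
    pp <- p; pp$f_q <- fq; pp$M <- M
    tp <- theory_params(p$m, p$n, M, p$f_p, fq, p$f_w)
    v_th <- optimize_threshold(tp, f_d = 0.33, v_max = 100)
    tp$v_th <- v_th
    pred_trace <- p$n * as.numeric(p_favg(tp))
    pred_strong <- 0.5 * (1 - pow1m(p$f_p * fq, M))
    pred_pairs <- expected_hd_pairs(tp)
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * r
      sim <- learn_network(pp, v_th = v_th, seed = s)
      probe <- seq_len(min(items_probe, M))
      rows <- list(
        data.frame(metric = "trace_size", f_d = NA,
                   simulated = trace_size(sim$net, sim$ensemble, probe),
                   predicted = pred_trace),
        data.frame(metric = "strong_weight_fraction", f_d = NA,
                   simulated = strong_weight_fraction(sim$net),
                   predicted = pred_strong))
      for (fd in f_d_values) {
        rd <- relative_dissimilarity(sim$net, sim$ensemble, f_d = fd,
                                     items = probe, n_pairs = 500)
        rows[[length(rows) + 1]] <-
          data.frame(metric = "relative_dissimilarity", f_d = fd,
                     simulated = rd$ratio,
                     predicted = expected_hd_masked(tp, f_d = fd) /
                       pred_pairs)
        rows[[length(rows) + 1]] <-
          data.frame(metric = "hd_masked", f_d = fd,
                     simulated = rd$numerator,
                     predicted = expected_hd_masked(tp, f_d = fd))
      }
      rows <- do.call(rbind, rows)
      rows$f_q <- fq; rows$M <- M; rows$v_th <- v_th
      rows$replicate <- r; rows$seed <- s
      out[[length(out) + 1]] <- rows
    }
  }
  do.call(rbind, out)
}

#' BTSP versus random projection (and optionally Hopfield)
#'
#' Learns a BTSP network, builds a density-matched random projection
#' with a grid-searched threshold, and compares relative dissimilarity
#' across masking fractions, the bimodality of the weighted-sum
#' distribution, and downstream readout robustness.
#'
#' @inheritParams run_masking_experiment
#' @param n_neurons_probe memory neurons sampled for the weighted-sum
#'   separation statistic.
#' @return List with data frames `dissimilarity`, `readout` and
#'   `separation`.
#' @export
run_model_comparison <- function(p = preset_reduced(),
                                 f_d_values = c(0.1, 0.2, 0.33, 0.5),
                                 replicates = 5, seed = 1,
                                 items_probe = 150, n_neurons_probe = 40) {
  dis <- list(); rob <- list(); sep <- list()
  tp <- theory_params(p$m, p$n, p$M, p$f_p, p$f_q, p$f_w)
  v_th <- optimize_threshold(tp, f_d = 0.33, v_max = 100)
  for (r in seq_len(replicates)) {
    s <- seed + 1000L * r
    sim <- learn_network(p, v_th = v_th, seed = s)
    dens <- strong_weight_fraction(sim$net) * p$f_w
    rp <- rp_build(dens, p$m, p$n, seed = s + 7L)
    probe <- seq_len(min(items_probe, p$M))
    rp <- rp_optimize_threshold(rp, sim$ensemble, f_d = 0.33,
                                items = probe, seed = s + 8L)
    for (fd in f_d_values) {
      rd_btsp <- relative_dissimilarity(sim$net, sim$ensemble, f_d = fd,
                                        items = probe, n_pairs = 500)
      X <- sim$ensemble$items[probe, , drop = FALSE]
      Zf <- (rp$R %*% t(X)) > rp$threshold
      Zm <- vapply(probe, function(k)
        as.numeric(rp$R %*% mask_pattern(sim$ensemble$items[k, ],
                                         fd)$vector) > rp$threshold,
        logical(p$n))
      num <- mean(colSums(Zf != Zm))
      pairs <- matrix(replicate(300, sample.int(length(probe), 2)), nrow = 2)
      den <- mean(vapply(seq_len(300), function(q)
        sum(Zf[, pairs[1, q]] != Zf[, pairs[2, q]]), numeric(1)))
      dis[[length(dis) + 1]] <- data.frame(
        f_d = fd, replicate = r,
        btsp = rd_btsp$ratio, rp = if (den > 0) num / den else NA)
      # readout robustness on full vs masked traces
      Zb_f <- recall_many(sim$net, X)
      Zb_m <- vapply(probe, function(k)
        recall(sim$net, mask_pattern(sim$ensemble$items[k, ], fd)$vector),
        integer(p$n))
      rob[[length(rob) + 1]] <- data.frame(
        f_d = fd, replicate = r,
        btsp = as.numeric(readout_robustness(Zb_f, Zb_m, seed = s + 9L)),
        rp = as.numeric(readout_robustness(Zf + 0L, Zm + 0L, seed = s + 9L)))
    }
    # weighted-sum separation, BTSP vs RP, over sampled neurons
    set.seed(s + 11L)
    neurons <- sample(p$n, n_neurons_probe)
    for (j in neurons) {
      h <- weighted_sum_histogram(sim$net, sim$ensemble, j)
      u_rp <- as.numeric(sim$ensemble$items %*% rp$R[j, ])
      sep[[length(sep) + 1]] <- data.frame(
        replicate = r, neuron = j,
        mean_plateau = mean(h$plateau), mean_no_plateau = mean(h$no_plateau),
        separation = h$separation,
        rp_sd_over_mean = stats::sd(u_rp) / max(mean(u_rp), 1e-12))
    }
  }
  list(dissimilarity = do.call(rbind, dis),
       readout = do.call(rbind, rob),
       separation = do.call(rbind, sep))
}

#' Overlapping-item experiment, simulation vs theory
#'
#' Sweeps the overlap fraction `f_c`, learning a network per replicate on
#' an ensemble with `c = floor(m f_c f_p)` common 1's, and compares the
#' simulated relative dissimilarity at 33% masking with the
#' overlapping-item predictions.
#'
#' @inheritParams run_masking_experiment
#' @param f_c_values overlap fractions to sweep.
#' @return Tidy data frame.
#' @export
run_overlap_experiment <- function(p = preset_reduced(),
                                   f_c_values = c(0, 0.1, 0.2, 0.3),
                                   f_d = 0.33, replicates = 5, seed = 1,
                                   items_probe = 150) {
  out <- list()
  for (fc in f_c_values) {
    c1 <- floor(p$m * fc * p$f_p)
    tp <- theory_params(p$m, p$n, p$M, p$f_p, p$f_q, p$f_w, f_d = f_d,
                        c = c1)
    v_th <- optimize_threshold(tp, f_d = f_d, v_max = 100)
    tp$v_th <- v_th
    pred <- overlapping_predictions(tp, f_d = f_d)
    pred_ratio <- pred$expected_hd_masked / pred$expected_hd_pairs
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * r
      ens <- gen_overlapping_patterns(p$M, p$m, p$f_p, fc, seed = s)
      pls <- draw_plateaus(p$M, p$n, p$f_q, seed = s + 1L)
      mask <- build_connectivity(p$m, p$n, p$f_w, seed = s + 2L)
      net <- learn_sequence(ens, pls, mask, v_th = v_th, seed = s + 3L)
      probe <- seq_len(min(items_probe, p$M))
      rd <- relative_dissimilarity(net, ens, f_d = f_d, items = probe,
                                   n_pairs = 500)
      out[[length(out) + 1]] <- data.frame(
        f_c = fc, c = c1, v_th = v_th, replicate = r, seed = s,
        simulated = rd$ratio, predicted = pred_ratio,
        simulated_hd = rd$numerator, predicted_hd = pred$expected_hd_masked)
    }
  }
  do.call(rbind, out)
}

#' Pattern-completion experiment
#'
#' Learns feedforward (BTSP) and feedback (saturating Hebb) weights with
#' the two-step protocol, fixes both layer thresholds, and measures the
#' scaled reconstruction error across masking fractions, plus the
#' first-100 versus last-100 item comparison that probes whether early
#' memories degrade as later ones are stored.
#'
#' @inheritParams run_masking_experiment
#' @param sample_fraction fraction of items used for the per-masking
#'   threshold scan.
#' @param scan_range integer range scanned for both layer thresholds.
#' @return List of data frames `errors` (per item), `summary`, and
#'   `thresholds` (the scanned optima per masking fraction).
#' @export
run_completion_experiment <- function(p = preset_reduced(),
                                      f_d_values = c(0.2, 0.33),
                                      replicates = 5, seed = 1,
                                      items_probe = 100,
                                      sample_fraction = 0.2,
                                      scan_range = c(1, 60)) {
  tp <- theory_params(p$m, p$n, p$M, p$f_p, p$f_q, p$f_w)
  v_th <- optimize_threshold(tp, f_d = 0.33, v_max = 100)
  errs <- list(); thr <- list()
  for (r in seq_len(replicates)) {
    s <- seed + 1000L * r
    ens <- gen_random_patterns(p$M, p$m, p$f_p, seed = s)
    pls <- draw_plateaus(p$M, p$n, p$f_q, seed = s + 1L)
    mask <- build_connectivity(p$m, p$n, p$f_w, seed = s + 2L)
    fb0 <- feedback_net(p$m, p$n, f_w = p$f_w, seed = s + 4L)
    trained <- learn_sequence_with_feedback(ens, pls, mask, fb0,
                                            v_th = v_th, seed = s + 3L)
    groups <- list(first = seq_len(items_probe),
                   last = seq(p$M - items_probe + 1, p$M))
    for (fd in f_d_values) {
      # both layer thresholds adapt to the cue sparsity, chosen per
      # masking fraction by a grid scan on a random sample of items
      set.seed(s + 5L)
      ks <- sample(ens$M, max(2, ceiling(sample_fraction *
                                           min(ens$M, 200))))
      sc <- scan_threshold_pair(trained$net, trained$fb, ens, fd, ks,
                                v_cand = seq(scan_range[1], scan_range[2]))
      net_fd <- trained$net; net_fd$v_th <- as.integer(sc$v_mem)
      thr[[length(thr) + 1]] <- data.frame(
        replicate = r, f_d = fd, v_mem = sc$v_mem, v_in = sc$v_in,
        ones_fraction = sc$ones_fraction, scan_hd = sc$hd)
      for (g in names(groups)) for (k in groups[[g]]) {
        x <- ens$items[k, ]
        cue <- mask_pattern(x, fd)
        z <- recall(net_fd, cue$vector)
        rec <- reconstruct(trained$fb, z, sc$v_in)
        errs[[length(errs) + 1]] <- data.frame(
          replicate = r, f_d = fd, group = g, item = k,
          scaled_error = scaled_reconstruction_error(x, cue, rec))
      }
    }
  }
  errs <- do.call(rbind, errs)
  summ <- stats::aggregate(scaled_error ~ f_d + group + replicate, errs, mean)
  list(errors = errs, summary = summ, thresholds = do.call(rbind, thr))
}

#' Repulsion-effect experiment
#'
#' The human-memory repulsion protocol: among `M` random items, one pair
#' has 40% common 1's and one pair is disjoint.  After learning all items
#' (BTSP with an elevated plateau probability, default `f_q = 0.02`), the
#' overlap ratio of the two traces is computed for both pairs; the
#' repulsion index divides the unrelated-pair overlap by the similar-pair
#' overlap.  The same items are pushed through a density-matched Top-K
#' random projection as the non-learned control.
#'
#' @inheritParams run_masking_experiment
#' @param f_q plateau probability for this protocol (default 0.02).
#' @param M number of items (default 1000).
#' @param overlap_fraction common-1's fraction of the similar pair.
#' @param trials number of independent trials (default 20).
#' @return Data frame with one row per trial and columns
#'   `btsp_overlap_similar`, `btsp_overlap_unrelated`, `btsp_index`,
#'   `rp_overlap_similar`, `rp_overlap_unrelated`, `rp_index`.
#' @export
run_repulsion_experiment <- function(p = preset_reduced(), f_q = 0.02,
                                     M = 1000, overlap_fraction = 0.4,
                                     trials = 20, seed = 1) {
  out <- list()
  tp <- theory_params(p$m, p$n, M, p$f_p, f_q, p$f_w)
  v_th <- optimize_threshold(tp, f_d = 0.33, v_max = 100)
  K <- max(1L, floor(p$n * f_q))
  for (t in seq_len(trials)) {
    s <- seed + 1000L * t
    set.seed(s)
    ens <- gen_random_patterns(M, p$m, p$f_p)
    # build the similar pair: item b shares `n_common` 1's with item a
    a <- which(rowSums(ens$items) > 0)[1]
    ones_a <- which(ens$items[a, ] == 1L)
    n_common <- round(overlap_fraction * length(ones_a))
    b <- if (a < M) a + 1L else a - 1L
    xb <- integer(p$m)
    keep <- sample(ones_a, n_common)
    xb[keep] <- 1L
    pool <- setdiff(seq_len(p$m), ones_a)
    xb[sample(pool, max(0, length(ones_a) - n_common))] <- 1L
    ens$items[b, ] <- xb
    # and a fully unrelated partner for the same item a
    u <- if (b < M) b + 1L else a - 2L
    xu <- integer(p$m)
    xu[sample(pool, length(ones_a))] <- 1L
    ens$items[u, ] <- xu
    ord <- sample(M)                     # pairs may appear anywhere
    ens$items <- ens$items[ord, , drop = FALSE]
    pos <- match(c(a, b, u), ord)
    pls <- draw_plateaus(M, p$n, f_q)
    mask <- build_connectivity(p$m, p$n, p$f_w)
    net <- learn_sequence(ens, pls, mask, v_th = v_th)
    probe <- seq_len(min(200, M))
    mean_ones <- trace_size(net, ens, probe)
    z <- lapply(pos, function(k) recall(net, ens$items[k, ]))
    ov_sim <- overlap_ratio(z[[1]], z[[2]], mean_ones)
    ov_unr <- overlap_ratio(z[[1]], z[[3]], mean_ones)
    # Top-K random projection control at matched density
    rp <- rp_build(strong_weight_fraction(net) * p$f_w, p$m, p$n)
    zr <- lapply(pos, function(k) rp_topk(rp, ens$items[k, ], K))
    mean_ones_rp <- mean(vapply(probe, function(k)
      sum(rp_topk(rp, ens$items[k, ], K)), numeric(1)))
    rp_sim <- overlap_ratio(zr[[1]], zr[[2]], mean_ones_rp)
    rp_unr <- overlap_ratio(zr[[1]], zr[[3]], mean_ones_rp)
    out[[length(out) + 1]] <- data.frame(
      trial = t, seed = s,
      btsp_overlap_similar = ov_sim, btsp_overlap_unrelated = ov_unr,
      btsp_index = repulsion_index(ov_unr, ov_sim),
      rp_overlap_similar = rp_sim, rp_overlap_unrelated = rp_unr,
      rp_index = repulsion_index(rp_unr, rp_sim))
  }
  do.call(rbind, out)
}

#' Release-site experiment
#'
#' Thin wrapper over [multi_release_site_change()] returning its
#' stratified mean weight changes.
#'
#' @inheritParams multi_release_site_change
#' @export
run_release_site_experiment <- function(n_sites = 8, n_trials = 10000,
                                        seed = 1) {
  multi_release_site_change(n_sites = n_sites, n_trials = n_trials,
                            seed = seed)
}

#' Brain-scale theory evaluation
#'
#' Evaluates the closed-form predictions at human-CA3 scale
#' (`m = 2.5e6`, `f_p = 5e-5`, up to 800,000 items).  Simulation at this
#' size is refused: only the theory is tractable.
#'
#' @param m,n,f_p,f_q,f_w scaled-up parameters.
#' @param M_values memory loads to evaluate.
#' @param f_d masking fraction (default 2/3).
#' @param simulate must stay `FALSE`; requesting simulation errors with
#'   guidance.
#' @return Data frame with `M`, `v_th`, `p_favg`, `expected_hd_masked`,
#'   `expected_hd_pairs`, `relative_dissimilarity`.
#' @export
run_scaleup_theory <- function(m = 2.5e6, n = 3.9e6, f_p = 5e-5,
                               f_q = 0.005, f_w = 0.6,
                               M_values = c(2e5, 4e5, 8e5), f_d = 2/3,
                               simulate = FALSE) {
  if (isTRUE(simulate))
    stop("simulation at brain scale is not supported; evaluate the ",
         "closed-form predictions (simulate = FALSE) or use ",
         "preset_reduced() for simulations")
  rows <- lapply(M_values, function(M) {
    tp <- theory_params(m, n, M, f_p, f_q, f_w, f_d = f_d)
    v_th <- optimize_threshold(tp, f_d = f_d, v_max = 120)
    tp$v_th <- v_th
    pf <- as.numeric(p_favg(tp))
    hdm <- expected_hd_masked(tp, f_d = f_d)
    hdp <- expected_hd_pairs(tp)
    data.frame(M = M, v_th = as.integer(v_th), p_favg = pf,
               expected_hd_masked = hdm, expected_hd_pairs = hdp,
               relative_dissimilarity = hdm / hdp)
  })
  do.call(rbind, rows)
}
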