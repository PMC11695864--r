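# Generators for synthetic memory items: sparse random patterns,
# controlled-overlap ensembles, masked / perturbed recall cues, and
# line-drawing images.

#' Construct a pattern ensemble
#'
#' Internal constructor for the `pattern_ensemble` class.  Items are stored
#' as the rows of an `M x m` integer matrix with entries in \{0, 1\}.
#'
#' @param items integer matrix, one memory item per row.
#' @param f_p nominal input density (expected fraction of 1-bits).
#' @param common integer vector of positions that are 1 in every item
#'   (empty for independent random items).
#' @param seed seed the ensemble was generated from (or `NA`).
#' @param meta optional list of extra metadata (e.g. line-segment tables).
#' @keywords internal
new_pattern_ensemble <- function(items, f_p, common = integer(0), seed = NA,
                                 meta = list()) {
  storage.mode(items) <- "integer"
  structure(
    list(items = items, M = nrow(items), m = ncol(items), f_p = f_p,
         c = length(common), common = as.integer(common), seed = seed,
         meta = meta),
    class = "pattern_ensemble")
}

#' @export
print.pattern_ensemble <- function(x, ...) {
  cat(sprintf("<pattern_ensemble> %d items of length %d (f_p = %g, c = %d)\n",
              x$M, x$m, x$f_p, x$c))
  cat(sprintf("  mean ones per item: %.2f\n", mean(rowSums(x$items))))
  invisible(x)
}

#' Generate independent sparse random memory items
#'
#' Each of the `M` items is a binary vector of length `m` whose bits are
#' i.i.d. Bernoulli(`f_p`).  This is the generic sparse coding regime of
#' hippocampal area CA3, where a fraction `f_p` of input neurons fires
#' during the presentation of a memory item.
#'
#' @param M number of memory items.
#' @param m number of input neurons (pattern length).
#' @param f_p input density: probability that a bit is 1.
#' @param seed integer seed for reproducibility (or `NULL` to use the
#'   current RNG state).
#' @return A [pattern_ensemble][new_pattern_ensemble] with `M` rows.
#' @examples
#' ens <- gen_random_patterns(M = 10, m = 200, f_p = 0.05, seed = 1)
#' rowSums(ens$items)
#' @export
gen_random_patterns <- function(M, m, f_p, seed = NULL) {
  check_count(M, "M"); check_count(m, "m"); check_prob(f_p, "f_p")
  if (!is.null(seed)) set.seed(seed)
  items <- matrix(as.integer(stats::runif(M * m) < f_p), nrow = M, ncol = m)
  new_pattern_ensemble(items, f_p = f_p, seed = if (is.null(seed)) NA else seed)
}

#' Generate overlapping memory items with a fixed set of common 1's
#'
#' All items share `c = floor(m * f_c * f_p)` fixed 1-positions; the
#' remaining `m - c` bits are i.i.d. Bernoulli with the adjusted density
#' `f_hat_p = (m * f_p - c) / (m - c)`, so the expected total number of
#' 1's per item stays at `m * f_p` regardless of the overlap fraction.
#'
#' @inheritParams gen_random_patterns
#' @param f_c overlap fraction in \[0, 1\]; the fraction of an item's
#'   expected 1's that is common to all items.
#' @return A [pattern_ensemble][new_pattern_ensemble]; `$common` holds the
#'   shared 1-positions.
#' @export
gen_overlapping_patterns <- function(M, m, f_p, f_c, seed = NULL) {
  check_count(M, "M"); check_count(m, "m")
  check_prob(f_p, "f_p"); check_prob(f_c, "f_c")
  c_common <- floor(m * f_c * f_p)
  f_hat_p <- if (c_common == m) 0 else (m * f_p - c_common) / (m - c_common)
  if (f_hat_p < 0 || f_hat_p > 1)
    stop("derived remaining-bit density f_hat_p = ", signif(f_hat_p, 4),
         " is outside [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  common <- if (c_common > 0) sort(sample.int(m, c_common)) else integer(0)
  items <- matrix(as.integer(stats::runif(M * m) < f_hat_p), nrow = M, ncol = m)
  items[, common] <- 1L
  ens <- new_pattern_ensemble(items, f_p = f_p, common = common,
                              seed = if (is.null(seed)) NA else seed)
  ens$f_hat_p <- f_hat_p
  ens
}

#' Mask a fraction of the 1's in a memory item
#'
#' Produces a one-sided recall cue: exactly `round(f_d * ones(x))` distinct
#' 1-positions, chosen uniformly without replacement, are set to 0 (R's
#' `round()` uses round-half-to-even).  No 0 is ever turned into a 1, so
#' the cue is elementwise less than or equal to the original item.
#'
#' @param x binary vector (a memory item).
#' @param f_d masking fraction in \[0, 1\].
#' @param seed optional integer seed.
#' @param source_index optional index of `x` in its ensemble, kept as
#'   metadata.
#' @return A list of class `cue` with elements `vector`, `f_d`, `mode`
#'   (`"masked"`), `removed` (positions zeroed) and `source_index`.
#' @export
mask_pattern <- function(x, f_d, seed = NULL, source_index = NA) {
  check_prob(f_d, "f_d")
  x <- as.integer(x)
  if (!is.null(seed)) set.seed(seed)
  ones <- which(x == 1L)
  k <- round(f_d * length(ones))
  removed <- if (k > 0) sort(sample(ones, k)) else integer(0)
  v <- x
  v[removed] <- 0L
  structure(list(vector = v, f_d = f_d, mode = "masked", removed = removed,
                 added = integer(0), source_index = source_index),
            class = "cue")
}

#' Perturb a memory item with two-sided errors
#'
#' Removes `k = round(f_d * ones(x))` 1's (as in [mask_pattern()]) and, to
#' keep the expected total number of 1's equal to that of the original
#' item, independently flips each 0-position to 1 with probability
#' `k / (m - ones(x))`.
#'
#' @inheritParams mask_pattern
#' @return A `cue` with `mode = "two_sided"`.
#' @export
perturb_pattern <- function(x, f_d, seed = NULL, source_index = NA) {
  check_prob(f_d, "f_d")
  x <- as.integer(x)
  if (!is.null(seed)) set.seed(seed)
  m <- length(x)
  ones <- which(x == 1L)
  k <- round(f_d * length(ones))
  removed <- if (k > 0) sort(sample(ones, k)) else integer(0)
  v <- x
  v[removed] <- 0L
  zeros <- which(x == 0L)
  if (length(zeros) == 0L) {
    if (k > 0)
      warning("pattern has no 0 positions; returning removals only")
    added <- integer(0)
  } else {
    p_add <- k / length(zeros)
    added <- zeros[stats::runif(length(zeros)) < p_add]
    v[added] <- 1L
  }
  structure(list(vector = v, f_d = f_d, mode = "two_sided", removed = removed,
                 added = added, source_index = source_index),
            class = "cue")
}

#' Generate binary line-drawing images
#'
#' Each image is a 50 x 50 binary canvas containing the union of five
#' axis-aligned line segments of 8 pixels each, in random positions and
#' random horizontal/vertical orientation.  One planted pair of images
#' (the last two) shares exactly three of its five segments, providing two
#' very similar memory items for completion experiments.  Images are
#' flattened row-major (rows top to bottom) into vectors of length 2,500.
#'
#' @param M number of images (at least 2).
#' @param seed optional integer seed.
#' @param side canvas side length (default 50).
#' @param n_segments segments per image (default 5).
#' @param seg_len segment length in pixels (default 8).
#' @return A [pattern_ensemble][new_pattern_ensemble] with
#'   `meta$segments`, a data frame (image, segment, orientation, row, col)
#'   describing every segment, and `meta$planted_pair`, the indices of the
#'   pair sharing three segments.
#' @export
gen_line_drawings <- function(M, seed = NULL, side = 50, n_segments = 5,
                              seg_len = 8) {
  if (M < 2) stop("M must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  rand_seg <- function() {
    horiz <- stats::runif(1) < 0.5
    if (horiz) c(orient = 1L, row = sample.int(side, 1),
                 col = sample.int(side - seg_len + 1, 1))
    else       c(orient = 0L, row = sample.int(side - seg_len + 1, 1),
                 col = sample.int(side, 1))
  }
  draw <- function(segs, img) {
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, ]
      if (s[["orient"]] == 1L)
        img[s[["row"]], s[["col"]]:(s[["col"]] + seg_len - 1)] <- 1L
      else
        img[s[["row"]]:(s[["row"]] + seg_len - 1), s[["col"]]] <- 1L
    }
    img
  }
  items <- matrix(0L, nrow = M, ncol = side * side)
  seg_tab <- vector("list", M)
  all_segs <- vector("list", M)
  for (k in seq_len(M - 1)) {
    segs <- do.call(rbind, replicate(n_segments, rand_seg(), simplify = FALSE))
    all_segs[[k]] <- segs
    items[k, ] <- as.integer(t(draw(segs, matrix(0L, side, side))))
  }
  # planted partner of item M-1: keep 3 segments, redraw 2 that differ from
  # ALL segments of the partner so the shared count is exactly 3
  partner <- all_segs[[M - 1]]
  keep <- partner[1:3, , drop = FALSE]
  fresh <- list()
  while (length(fresh) < n_segments - 3) {
    s <- rand_seg()
    clash <- any(apply(partner, 1, function(p) all(p == s)))
    if (!clash) fresh[[length(fresh) + 1]] <- s
  }
  segs_last <- rbind(keep, do.call(rbind, fresh))
  all_segs[[M]] <- segs_last
  items[M, ] <- as.integer(t(draw(segs_last, matrix(0L, side, side))))
  seg_df <- do.call(rbind, lapply(seq_len(M), function(k) {
    data.frame(image = k, segment = seq_len(n_segments),
               orientation = ifelse(all_segs[[k]][, "orient"] == 1L,
                                    "horizontal", "vertical"),
               row = all_segs[[k]][, "row"], col = all_segs[[k]][, "col"],
               row.names = NULL)
  }))
  new_pattern_ensemble(items, f_p = n_segments * seg_len / (side * side),
                       seed = if (is.null(seed)) NA else seed,
                       meta = list(segments = seg_df,
                                   planted_pair = c(M - 1L, M),
                                   side = side, seg_len = seg_len))
}

#' Mask the bottom rows of a flattened image
#'
#' Recall cues for line drawings are produced by zeroing the last rows of
#' the canvas (by default rows 31 to 50 of a 50-row image).
#'
#' @param x flattened row-major image vector.
#' @param rows integer vector of row indices to zero.
#' @param side canvas side length.
#' @return The masked flattened image.
#' @export
mask_image_rows <- function(x, rows = 31:50, side = 50) {
  x <- as.integer(x)
  idx <- as.vector(outer(seq_len(side), (rows - 1) * side, `+`))
  x[idx] <- 0L
  x
}

# -- argument checks ---------------------------------------------------------

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop(name, " must be a probability in [0, 1]")
  invisible(p)
}

check_count <- function(n, name, min = 1) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < min ||
      n != floor(n))
    stop(name, " must be an integer >= ", min)
  invisible(n)
}
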