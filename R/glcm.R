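#' Quantize a grayscale image to N gray levels
#'
#' Equal-width binning of `[lo, hi]` into `n_levels` bins:
#' `v -> min(floor((v - lo) * N / (hi - lo + 1)), N - 1) + 1`, so levels run
#' from 1 to N. Values outside the limits are clamped first. Sixteen levels
#' is the conventional reduction for co-occurrence texture analysis.
#'
#' @param img a [gray_image] (or integer matrix).
#' @param n_levels number of output levels N (>= 2).
#' @param gray_limits numeric `c(lo, hi)` intensity range mapped onto the
#'   levels.
#' @return An integer matrix of levels in `[1, n_levels]` with attribute
#'   `n_levels`, class `quantized_image`.
#' @export
quantize <- function(img, n_levels = 16, gray_limits = c(0, 255)) {
  lo <- gray_limits[1]; hi <- gray_limits[2]
  if (!(lo < hi)) stop("gray_limits must satisfy lo < hi")
  if (n_levels < 2) stop("n_levels must be >= 2")
  n_levels <- as.integer(n_levels)
  v <- pmin(pmax(as.numeric(img), lo), hi)
  q <- pmin(floor((v - lo) * n_levels / (hi - lo + 1)), n_levels - 1) + 1
  structure(matrix(as.integer(q), nrow(img), ncol(img)),
            n_levels = n_levels, class = c("quantized_image", "matrix"))
}

# (row, col) offset of the neighbour pixel for each standard orientation
glcm_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("theta must be one of 0, 45, 90, 135 (degrees)"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of quantized levels `(i, j)` for pixels separated by
#' the offset of orientation `theta` at distance `d` (single-offset,
#' non-symmetric counting unless `symmetric = TRUE`), then normalizes the
#' counts to probabilities summing to 1.
#'
#' @param q a [quantize]d image.
#' @param d pair distance in pixels (>= 1).
#' @param theta orientation in degrees: 0, 45, 90 or 135.
#' @param symmetric if `TRUE`, also count each pair in the reversed order
#'   (transpose-symmetric matrix).
#' @return An object of class `cooc_matrix`: list with `probabilities`
#'   (N x N), `counts`, `distance`, `orientation`, `pair_count`, `n_levels`.
#' @export
cooccurrence <- function(q, d = 1, theta = 0, symmetric = FALSE) {
  n <- attr(q, "n_levels")
  if (is.null(n)) n <- max(q)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  off <- glcm_offset(theta, d)
  h <- nrow(q); w <- ncol(q)
  rows <- seq_len(h)[seq_len(h) + off[1] >= 1L & seq_len(h) + off[1] <= h]
  cols <- seq_len(w)[seq_len(w) + off[2] >= 1L & seq_len(w) + off[2] <= w]
  if (length(rows) == 0L || length(cols) == 0L)
    stop("image smaller than the requested offset")
  a <- q[rows, cols, drop = FALSE]
  b <- q[rows + off[1], cols + off[2], drop = FALSE]
  counts <- matrix(tabulate(a + n * (b - 1L), n * n), n, n)
  if (symmetric) counts <- counts + t(counts)
  pair_count <- sum(counts)
  structure(list(probabilities = counts / pair_count, counts = counts,
                 distance = d, orientation = theta,
                 pair_count = pair_count, n_levels = n),
            class = "cooc_matrix")
}

haralick_names <- c("energy", "contrast", "correlation", "variance",
                    "sum_average", "sum_variance", "sum_entropy", "entropy")

#' Haralick texture features of a co-occurrence matrix
#'
#' Computes the eight classic features from a normalized GLCM `P(i, j)`:
#' energy (angular second moment) `sum P^2`; contrast `sum (i-j)^2 P`;
#' correlation `sum ((i-mu_x)/sigma_x)((j-mu_y)/sigma_y) P`; variance
#' `sum (i-mu)^2 P` with `mu = mu_x`; sum average `sum k P_{x+y}(k)`; sum
#' variance `sum (k-mu_{x+y})^2 P_{x+y}(k)`; sum entropy
#' `-sum P_{x+y} log P_{x+y}`; entropy `-sum P log P`. Marginals `P_x`, `P_y`
#' are row/column sums; `P_{x+y}(k) = sum_{i+j=k} P(i, j)`, `k = 2..2N`.
#' Logarithms are base 2 by default (entropy in bits, maximum
#' `log2(N)` per marginal direction); `0 log 0 = 0`; correlation is defined
#' as 0 (with a warning) when `sigma_x sigma_y = 0`.
#'
#' @param P a [cooccurrence()] result or a normalized N x N matrix.
#' @param log_base base of the entropy logarithms (2 or `exp(1)`).
#' @return Named numeric vector of the eight features.
#' @export
haralick_features <- function(P, log_base = 2) {
  if (inherits(P, "cooc_matrix")) P <- P$probabilities
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("P must be square")
  if (any(P < 0) || abs(sum(P) - 1) > 1e-6)
    stop("P must be a normalized co-occurrence matrix (entries >= 0, sum 1)")
  n <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lv <- seq_len(n)
  mu_x <- sum(lv * px); mu_y <- sum(lv * py)
  sig_x <- sqrt(sum((lv - mu_x)^2 * px))
  sig_y <- sqrt(sum((lv - mu_y)^2 * py))
  lg <- function(x) ifelse(x > 0, log(x, base = log_base), 0)

  ks <- 2:(2 * n)
  pxy <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  mu_xy <- sum(ks * pxy)

  corr <- if (sig_x * sig_y == 0) {
    warning("degenerate marginals (sigma_x * sigma_y = 0): correlation set to 0")
    0
  } else {
    sum(((i - mu_x) / sig_x) * ((j - mu_y) / sig_y) * P)
  }

  c(energy = sum(P^2),
    contrast = sum((i - j)^2 * P),
    correlation = corr,
    variance = sum((i - mu_x)^2 * P),
    sum_average = mu_xy,
    sum_variance = sum((ks - mu_xy)^2 * pxy),
    sum_entropy = -sum(pxy * lg(pxy)),
    entropy = -sum(P * lg(P)))
}

#' Average Haralick features over the four standard orientations
#'
#' @param vectors list of exactly four feature vectors (0, 45, 90, 135
#'   degrees) as returned by [haralick_features()].
#' @return Feature-wise arithmetic mean, a named numeric vector.
#' @export
directional_average <- function(vectors) {
  if (length(vectors) != 4L) stop("exactly 4 orientation vectors are required")
  Reduce(`+`, vectors) / 4
}

#' Haralick texture profile of the segmented vasculature
#'
#' The texture pipeline applied to one image: grayscale conversion, masking
#' (non-vessel pixels set to 0), quantization to `n_levels` gray levels,
#' co-occurrence matrices at distance `d` for the four standard orientations
#' over the full raster, per-orientation Haralick features, and the
#' directional average.
#'
#' @param img a [fundus_image].
#' @param mask a [vessel_mask] of matching dimensions (typically from
#'   [segment_vessels()] or a ground-truth annotation).
#' @param n_levels,gray_limits quantization, see [quantize()].
#' @param d pair distance in pixels.
#' @param log_base entropy logarithm base, see [haralick_features()].
#' @param symmetric GLCM symmetry flag, see [cooccurrence()].
#' @return Named numeric vector of the eight direction-averaged features.
#'   An empty mask produces a degenerate all-background raster (energy 1,
#'   contrast 0) with a warning.
#' @export
vessel_texture_profile <- function(img, mask, n_levels = 16, d = 1,
                                   log_base = 2, gray_limits = c(0, 255),
                                   symmetric = FALSE) {
  if (!identical(dim(img)[1:2], dim(mask)[1:2]))
    stop("mask dimensions must match the image")
  if (!any(mask == 1L))
    warning("empty vessel mask: texture computed on an all-background raster")
  g <- to_grayscale(img)
  gm <- matrix(as.integer(g), nrow(g), ncol(g))
  gm[mask == 0L] <- 0L
  q <- quantize(gray_image(gm), n_levels = n_levels, gray_limits = gray_limits)
  feats <- lapply(c(0, 45, 90, 135), function(th)
    haralick_features(cooccurrence(q, d = d, theta = th, symmetric = symmetric),
                      log_base = log_base))
  directional_average(feats)
}
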