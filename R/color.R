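channel_index <- function(channel) {
  ch <- match(toupper(channel), c("R", "G", "B"))
  if (is.na(ch)) stop("channel must be one of R, G, B")
  ch
}

#' 256-bin intensity histogram of one color channel
#'
#' Exact integer counts `n_i = |{(x, y) : I(x, y) = i}|`, `i = 0..255`; the
#' counts always sum to the number of pixels considered.
#'
#' @param img a [fundus_image].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @param fov_only if `TRUE`, count only pixels inside the field of view;
#'   by default the full fundus area (the whole raster) is analyzed.
#' @return An object of class `channel_histogram`: list with `counts`
#'   (length-256 integer vector, bin i holds intensity i-1), `channel`,
#'   `n_pixels`.
#' @export
channel_histogram <- function(img, channel, fov_only = FALSE) {
  ch <- channel_index(channel)
  v <- img[, , ch]
  if (fov_only) v <- v[image_fov(img)]
  counts <- tabulate(as.integer(v) + 1L, 256L)
  structure(list(counts = counts, channel = toupper(channel),
                 n_pixels = length(v)),
            class = "channel_histogram")
}

#' Per-group set of RGB channel histograms
#'
#' Computes the three channel histograms for every image of a group and
#' their frequency (sum-to-1) normalizations, the unit on which group
#' averages and Mahalanobis separability are defined.
#'
#' @param images list of [fundus_image]s belonging to one group.
#' @param group group label; defaults to the first image's label.
#' @param fov_only see [channel_histogram()].
#' @return An object of class `group_histogram_set`: list with `group`,
#'   `per_image` (per image, named list of the three `channel_histogram`s)
#'   and `frequencies` (per image, named list of length-256 frequency
#'   vectors).
#' @export
group_histogram_set <- function(images, group = NULL, fov_only = FALSE) {
  if (length(images) < 1L) stop("at least one image is required")
  if (is.null(group)) group <- attr(images[[1]], "group")
  per_image <- lapply(images, function(im)
    sapply(c("R", "G", "B"), function(ch)
      channel_histogram(im, ch, fov_only = fov_only),
      simplify = FALSE))
  frequencies <- lapply(per_image, function(hs)
    lapply(hs, function(h) h$counts / h$n_pixels))
  structure(list(group = group, per_image = per_image,
                 frequencies = frequencies),
            class = "group_histogram_set")
}

#' Group-average channel histogram
#'
#' Bin-wise arithmetic mean of the per-image frequency histograms of one
#' channel.
#'
#' @param set a [group_histogram_set].
#' @param channel `"R"`, `"G"` or `"B"`.
#' @return Length-256 numeric frequency vector (sums to 1).
#' @export
average_histogram <- function(set, channel) {
  ch <- toupper(channel)
  channel_index(ch)
  rowMeans(vapply(set$frequencies, function(f) f[[ch]], numeric(256)))
}

# rows = per-image concatenated frequency vectors of the selected channels
histogram_feature_matrix <- function(set, channels) {
  t(vapply(set$frequencies,
           function(f) unlist(f[channels], use.names = FALSE),
           numeric(256 * length(channels))))
}

#' Mahalanobis separability of two groups in histogram space
#'
#' Treats each image as a point in `256 * |channels|`-dimensional space (its
#' concatenated channel frequency histograms) and returns the Mahalanobis
#' distance between the two group means,
#' `D = sqrt((mu_A - mu_B)' Sigma^+ (mu_A - mu_B))`, where `Sigma` is the
#' pooled within-group covariance. With ~15 images in 256+ dimensions
#' `Sigma` is rank-deficient, so the inverse is regularized (see
#' `covariance`).
#'
#' @param set_a,set_b [group_histogram_set]s with >= 2 images each.
#' @param channels subset of `c("R", "G", "B")`; several channels are
#'   combined by concatenation.
#' @param covariance `"pseudoinverse"` (Moore-Penrose after truncating
#'   eigenvalues below `tol` times the largest), `"shrinkage"`
#'   (`(1 - lambda) Sigma + lambda diag(Sigma)`, then inverted by the same
#'   pseudo-inverse), or `"identity"` (Euclidean distance of the means,
#'   mainly for tests).
#' @param lambda shrinkage weight in `[0, 1]`.
#' @param tol relative eigenvalue truncation threshold.
#' @return Non-negative Mahalanobis distance.
#' @export
mahalanobis_separation <- function(set_a, set_b, channels = c("R", "G", "B"),
                                   covariance = c("pseudoinverse", "shrinkage",
                                                  "identity"),
                                   lambda = 0.1, tol = 1e-10) {
  covariance <- match.arg(covariance)
  channels <- toupper(channels)
  xa <- histogram_feature_matrix(set_a, channels)
  xb <- histogram_feature_matrix(set_b, channels)
  mahalanobis_distance(xa, xb, covariance = covariance, lambda = lambda,
                       tol = tol)
}

#' Mahalanobis distance between two sample means (regularized)
#'
#' The linear-algebra core of [mahalanobis_separation()], exposed for direct
#' use on arbitrary feature matrices (rows = observations).
#'
#' @param xa,xb numeric matrices with >= 2 rows each and equal column count.
#' @param covariance,lambda,tol see [mahalanobis_separation()].
#' @return Non-negative distance between the row means.
#' @export
mahalanobis_distance <- function(xa, xb,
                                 covariance = c("pseudoinverse", "shrinkage",
                                                "identity"),
                                 lambda = 0.1, tol = 1e-10) {
  covariance <- match.arg(covariance)
  xa <- as.matrix(xa); xb <- as.matrix(xb)
  if (nrow(xa) < 2L || nrow(xb) < 2L)
    stop("each group needs >= 2 observations (covariance undefined)")
  if (ncol(xa) != ncol(xb)) stop("feature dimensions differ")
  d <- colMeans(xa) - colMeans(xb)
  if (covariance == "identity") return(sqrt(sum(d^2)))
  na <- nrow(xa); nb <- nrow(xb)
  sigma <- ((na - 1) * stats::cov(xa) + (nb - 1) * stats::cov(xb)) / (na + nb - 2)
  if (covariance == "shrinkage")
    sigma <- (1 - lambda) * sigma + lambda * diag(diag(sigma))
  e <- eigen(sigma, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(0)
  z <- crossprod(e$vectors[, keep, drop = FALSE], d)
  sqrt(max(0, sum(z^2 / e$values[keep])))
}

#' Bivariate (joint) histogram of a channel pair
#'
#' Exact 256 x 256 joint counts of the ordered value pairs of two color
#' channels over the pixels of one image; visualizes the co-distribution of
#' the channels. Row sums reproduce the first channel's histogram and column
#' sums the second's.
#'
#' @param img a [fundus_image].
#' @param pair `"RG"`, `"RB"` or `"GB"` (rows = first channel).
#' @param fov_only see [channel_histogram()].
#' @return An object of class `bivariate_histogram`: list with `counts`
#'   (256 x 256 integer matrix, entry `[i, j]` counts pixels with first
#'   channel `i - 1` and second channel `j - 1`), `pair`, `n_pixels`.
#' @export
bivariate_histogram <- function(img, pair = c("RG", "RB", "GB"),
                                fov_only = FALSE) {
  pair <- match.arg(toupper(pair[1]), c("RG", "RB", "GB"))
  chs <- strsplit(pair, "")[[1]]
  v1 <- img[, , channel_index(chs[1])]
  v2 <- img[, , channel_index(chs[2])]
  if (fov_only) {
    fov <- image_fov(img)
    v1 <- v1[fov]; v2 <- v2[fov]
  }
  idx <- as.integer(v1) + 256L * as.integer(v2) + 1L
  counts <- matrix(tabulate(idx, 256L * 256L), 256L, 256L)
  structure(list(counts = counts, pair = pair, n_pixels = length(v1)),
            class = "bivariate_histogram")
}
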