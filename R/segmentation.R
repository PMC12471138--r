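#' Matched filter parameters
#'
#' Classic oriented matched filter for retinal vessels: a zero-mean kernel
#' whose cross-section is an inverted Gaussian of standard deviation `sigma`
#' (truncated at `3 sigma`), extended over `length` pixels along the vessel
#' direction, evaluated at `n_orientations` angles spaced `180 / n` degrees.
#'
#' @param sigma Gaussian cross-profile standard deviation in pixels.
#' @param length kernel extent along the vessel direction, in pixels (>= 3).
#' @param n_orientations number of filter orientations (>= 4).
#' @return An object of class `matched_filter_params`.
#' @export
matched_filter_params <- function(sigma = 2, length = 9, n_orientations = 12) {
  if (sigma <= 0) stop("sigma must be positive")
  if (length < 3) stop("length must be >= 3")
  if (n_orientations < 4) stop("n_orientations must be >= 4")
  structure(list(sigma = sigma, length = length,
                 n_orientations = as.integer(n_orientations)),
            class = "matched_filter_params")
}

#' Matched filter kernel for one orientation
#'
#' Cross-section `-exp(-u^2 / (2 sigma^2))` perpendicular to the vessel
#' direction, support `|u| <= 3 sigma` and `|t| <= length / 2` along it,
#' mean-subtracted over the support so the kernel annihilates constants.
#' A dark (low-intensity) line along `theta` therefore yields a positive
#' response.
#'
#' @param sigma,length as in [matched_filter_params()].
#' @param theta vessel direction in radians (0 = horizontal).
#' @return A square numeric matrix (odd side), zero outside the support.
#' @export
matched_filter_kernel <- function(sigma, length, theta) {
  half <- ceiling(max(length / 2, 3 * sigma))
  off <- seq(-half, half)
  dx <- matrix(off, 2 * half + 1, 2 * half + 1, byrow = TRUE)  # col offset
  dy <- matrix(off, 2 * half + 1, 2 * half + 1)                # row offset
  along <- dx * cos(theta) + dy * sin(theta)
  cross <- -dx * sin(theta) + dy * cos(theta)
  sup <- abs(along) <= length / 2 & abs(cross) <= 3 * sigma
  k <- matrix(0, 2 * half + 1, 2 * half + 1)
  k[sup] <- -exp(-cross[sup]^2 / (2 * sigma^2))
  k[sup] <- k[sup] - mean(k[sup])
  k
}

#' Oriented matched-filter response
#'
#' Convolves the image with the matched-filter kernel at each orientation
#' (reflective borders) and takes the pixel-wise maximum across orientations;
#' the combined response is then linearly rescaled to `[0, 255]`. Because the
#' kernels are zero-mean the response is invariant to adding a constant to
#' the input, and a constant image maps to an all-zero response.
#'
#' @param img a [gray_image].
#' @param params a [matched_filter_params].
#' @param reduce if `FALSE`, return the list of raw (unscaled)
#'   per-orientation response matrices instead.
#' @return Numeric response matrix in `[0, 255]`, or a list when
#'   `reduce = FALSE`.
#' @export
matched_filter_response <- function(img, params = matched_filter_params(),
                                    reduce = TRUE) {
  stopifnot(inherits(params, "matched_filter_params"))
  m <- matrix(as.numeric(img), nrow(img), ncol(img))
  thetas <- (seq_len(params$n_orientations) - 1) * pi / params$n_orientations
  resps <- lapply(thetas, function(th)
    cpp_conv2_reflect(m, matched_filter_kernel(params$sigma, params$length, th)))
  if (!reduce) {
    names(resps) <- sprintf("%g", thetas * 180 / pi)
    return(resps)
  }
  r <- Reduce(pmax, resps)
  lo <- min(r); hi <- max(r)
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1)) {
    return(matrix(0, nrow(r), ncol(r)))
  }
  (r - lo) / (hi - lo) * 255
}

#' Isodata (iterative intermeans) threshold
#'
#' Starting from the global mean, repeatedly sets the threshold to the
#' average of the foreground and background class means until the update
#' changes by less than `tol` (or `max_iter` iterations).
#'
#' @param values non-empty numeric vector of intensities.
#' @param tol convergence tolerance in gray levels.
#' @param max_iter iteration cap.
#' @return A list with elements `threshold`, `degenerate` (`TRUE` when all
#'   values are identical, in which case the threshold is that value), and
#'   `iterations`.
#' @export
isodata_threshold <- function(values, tol = 0.5, max_iter = 100) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("values must be non-empty")
  if (max(values) - min(values) == 0) {
    return(list(threshold = values[1], degenerate = TRUE, iterations = 0L))
  }
  t_cur <- mean(values)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    hi <- values > t_cur
    if (!any(hi) || all(hi)) break   # one class empty: converged at boundary
    t_new <- (mean(values[hi]) + mean(values[!hi])) / 2
    done <- abs(t_new - t_cur) < tol
    t_cur <- t_new
    if (done || iter >= max_iter) break
  }
  list(threshold = t_cur, degenerate = FALSE, iterations = iter)
}

# drop connected components (8-connectivity) smaller than min_px
filter_small_components <- function(bin, min_px) {
  if (min_px <= 1 || !any(bin == 1L)) return(bin)
  lab <- cpp_label_components(bin, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(as.integer(lab %in% keep & lab > 0L), nrow(bin), ncol(bin))
}

# default speckle-removal size: 50 px at HRF scale (3504 x 2336), scaled by
# image area for smaller rasters
default_min_component <- function(h, w) max(1L, as.integer(round(50 * (h * w) / (3504 * 2336))))

#' Segment the retinal vasculature
#'
#' Full segmentation pipeline: green channel, CLAHE, median filtering,
#' oriented matched filtering, isodata thresholding of the in-FOV response,
#' and removal of connected components smaller than `min_component_px`.
#'
#' @param img a [fundus_image].
#' @param params a [matched_filter_params].
#' @param min_component_px minimum connected-component size kept, in pixels;
#'   default 50 at HRF scale (3504 x 2336), scaled by image area.
#' @param fov optional logical FOV matrix; defaults to the image's stored or
#'   estimated field of view.
#' @param tiles,clip_limit CLAHE parameters, see [clahe()].
#' @param median_k median filter window, see [median_filter()].
#' @return A [vessel_mask] restricted to the FOV, with attributes
#'   `threshold` (the isodata threshold on the response) and `degenerate`
#'   (`TRUE` when the response had no contrast and the mask is empty).
#' @export
segment_vessels <- function(img, params = matched_filter_params(),
                            min_component_px = NULL, fov = NULL,
                            tiles = c(8, 8), clip_limit = 0.01, median_k = 3) {
  if (is.null(fov)) fov <- image_fov(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (is.null(min_component_px)) min_component_px <- default_min_component(h, w)

  green <- gray_image(img[, , 2])
  pre <- median_filter(clahe(green, tiles = tiles, clip_limit = clip_limit),
                       k = median_k)
  resp <- matched_filter_response(pre, params)

  vals <- resp[fov]
  if (length(vals) == 0L) vals <- as.numeric(resp)
  th <- isodata_threshold(vals)
  if (th$degenerate) {
    warning("degenerate threshold: response has no contrast; returning empty mask")
    out <- vessel_mask(matrix(0L, h, w))
    attr(out, "threshold") <- th$threshold
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  bin <- matrix(as.integer(resp > th$threshold & fov), h, w)
  bin <- filter_small_components(bin, min_component_px)
  out <- vessel_mask(bin)
  attr(out, "threshold") <- th$threshold
  attr(out, "degenerate") <- FALSE
  out
}

#' Dice similarity coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [vessel_mask] objects (or 0/1 matrices) of equal dimensions.
#' @return Similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask dimensions differ")
  na <- sum(a == 1L); nb <- sum(b == 1L)
  if (na + nb == 0L) return(1)
  2 * sum(a == 1L & b == 1L) / (na + nb)
}
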