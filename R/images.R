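#' @useDynLib fundustex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var pnorm
#' @importFrom utils read.csv write.csv
NULL

#' Construct an 8-bit RGB fundus image
#'
#' The basic raster container of the package: an integer `height x width x 3`
#' array with values in `[0, 255]`, carrying an image id, a group label and an
#' optional field-of-view (FOV) mask of the circular imaged retinal region.
#'
#' @param pixels numeric or integer array `h x w x 3`, values in `[0, 255]`.
#' @param id character image identifier.
#' @param group character group label (e.g. `"healthy"`, `"glaucoma"`).
#' @param fov optional logical matrix `h x w`, `TRUE` inside the circular
#'   field of view. When `NULL` it is estimated on demand.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, id = "img", group = NA_character_, fov = NULL) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an h x w x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (!is.null(fov)) {
    fov <- as.matrix(fov)
    if (!identical(dim(fov), dim(pixels)[1:2]))
      stop("fov dimensions must match the image")
    storage.mode(fov) <- "logical"
  }
  structure(pixels, id = id, group = group, fov = fov,
            class = c("fundus_image", "array"))
}

#' Construct an 8-bit grayscale image
#'
#' @param pixels numeric matrix with values in `[0, 255]`.
#' @return An object of class `gray_image` (an integer matrix).
#' @export
gray_image <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("gray values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("gray_image", "matrix"))
}

#' Construct a binary vessel mask
#'
#' @param pixels matrix of 0/1 (or logical) values, vessel = 1.
#' @return An object of class `vessel_mask` (an integer 0/1 matrix).
#' @export
vessel_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("vessel_mask", "matrix"))
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<fundus_image %s> %d x %d px, group = %s, fov = %s\n",
              attr(x, "id"), d[1], d[2], attr(x, "group"),
              if (is.null(attr(x, "fov"))) "none" else "present"))
  invisible(x)
}

#' Circular field-of-view mask
#'
#' Fundus photographs image a circular retinal field on a black surround.
#' This returns the idealized FOV used by the synthetic generator: a centred
#' disc of radius `radius_frac * min(h, w)`.
#'
#' @param h,w image height and width in pixels.
#' @param radius_frac disc radius as a fraction of the shorter side.
#' @return Logical `h x w` matrix, `TRUE` inside the field.
#' @export
circular_fov <- function(h, w, radius_frac = 0.48) {
  r <- radius_frac * min(h, w)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  dy <- (seq_len(h) - cy)^2
  dx <- (seq_len(w) - cx)^2
  outer(dy, dx, "+") <= r^2
}

#' Estimate the field of view of a fundus photograph
#'
#' Thresholds the red channel (`> threshold`) and keeps the largest connected
#' component, the standard heuristic for the black surround of HRF-style
#' images. Used when no explicit FOV mask accompanies an image.
#'
#' @param img a [fundus_image].
#' @param threshold 8-bit red-channel threshold separating field from
#'   surround.
#' @return Logical matrix, `TRUE` inside the estimated field.
#' @export
estimate_fov <- function(img, threshold = 20) {
  red <- img[, , 1]
  cand <- matrix(as.integer(red > threshold), nrow(red), ncol(red))
  if (!any(cand == 1L)) return(cand == 1L)
  lab <- cpp_label_components(cand, 8L)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# FOV accessor: stored mask if present, else estimate.
image_fov <- function(img) {
  fov <- attr(img, "fov")
  if (is.null(fov)) fov <- estimate_fov(img)
  fov
}

#' Read a fundus image from a PNG file
#'
#' @param path PNG file path (8-bit RGB or gray; gray is replicated to RGB).
#' @param id,group metadata attached to the returned image; `id` defaults to
#'   the file name without extension.
#' @param fov optional logical FOV matrix.
#' @return A [fundus_image].
#' @export
read_fundus_png <- function(path, id = NULL, group = NA_character_, fov = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  fundus_image(floor(px * 255 + 0.5), id = id, group = group, fov = fov)
}

#' Write a fundus image to a PNG file
#'
#' @param img a [fundus_image].
#' @param path output path.
#' @export
write_fundus_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' Read a binary vessel mask from a PNG file
#'
#' Any strictly positive pixel counts as vessel (masks are conventionally
#' stored as 0/255).
#'
#' @param path PNG file path.
#' @return A [vessel_mask].
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  vessel_mask(px > 0)
}

#' Write a binary vessel mask to a PNG file (0/255 convention)
#'
#' @param mask a [vessel_mask].
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
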