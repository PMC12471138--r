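#' Convert an RGB fundus image to 8-bit grayscale
#'
#' Uses the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B` (the
#' rgb2gray convention), rounded half-up and clipped to `[0, 255]`.
#'
#' @param img a [fundus_image].
#' @return A [gray_image] of the same dimensions.
#' @export
to_grayscale <- function(img) {
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  gray_image(pmin(pmax(floor(y + 0.5), 0), 255))
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Standard CLAHE: the image is divided into a grid of tiles, each tile's
#' 256-bin histogram is clipped at `clip_limit` times the tile pixel count
#' (excess redistributed uniformly), the clipped cumulative histogram defines
#' a per-tile intensity mapping, and per-pixel output is the bilinear
#' interpolation of the four surrounding tile mappings.
#'
#' @param img a [gray_image].
#' @param tiles integer vector `c(rows, cols)` of the tile grid, both >= 2.
#' @param clip_limit histogram clip limit as a fraction of the tile pixel
#'   count, in `(0, 1]`.
#' @return A [gray_image] with enhanced local contrast.
#' @export
clahe <- function(img, tiles = c(8, 8), clip_limit = 0.01) {
  if (length(tiles) != 2L || any(tiles < 2)) stop("tiles must be (rows, cols) >= 2")
  if (clip_limit <= 0 || clip_limit > 1) stop("clip_limit must be in (0, 1]")
  h <- nrow(img); w <- ncol(img)
  tr <- as.integer(tiles[1]); tc <- as.integer(tiles[2])
  if (h < tr || w < tc) stop("image smaller than the tile grid")

  row_tile <- pmin(tr, (seq_len(h) - 1L) %/% ceiling(h / tr) + 1L)
  col_tile <- pmin(tc, (seq_len(w) - 1L) %/% ceiling(w / tc) + 1L)

  # per-tile clipped-histogram lookup tables, lut[tile_r, tile_c, value+1]
  lut <- array(0, c(tr, tc, 256L))
  centers_r <- numeric(tr); centers_c <- numeric(tc)
  for (a in seq_len(tr)) centers_r[a] <- mean(which(row_tile == a))
  for (b in seq_len(tc)) centers_c[b] <- mean(which(col_tile == b))
  for (a in seq_len(tr)) {
    for (b in seq_len(tc)) {
      px <- img[row_tile == a, col_tile == b]
      n <- length(px)
      hist <- tabulate(px + 1L, 256L)
      if (sum(hist > 0) <= 1L) {
        # zero-contrast tile: equalization is arbitrary, keep the identity
        # mapping (makes constant images fixed points)
        lut[a, b, ] <- 0:255
        next
      }
      clip <- max(1, clip_limit * n)
      excess <- sum(pmax(hist - clip, 0))
      hist <- pmin(hist, clip) + excess / 256
      lut[a, b, ] <- floor(cumsum(hist) / n * 255 + 0.5)
    }
  }

  # bilinear interpolation between the four nearest tile mappings
  idx_lo <- function(pos, centers) pmax(1L, pmin(length(centers) - 1L,
                                                 findInterval(pos, centers)))
  r1 <- idx_lo(seq_len(h), centers_r); r2 <- r1 + 1L
  c1 <- idx_lo(seq_len(w), centers_c); c2 <- c1 + 1L
  wr <- pmin(1, pmax(0, (seq_len(h) - centers_r[r1]) /
                       (centers_r[r2] - centers_r[r1])))
  wc <- pmin(1, pmax(0, (seq_len(w) - centers_c[c1]) /
                       (centers_c[c2] - centers_c[c1])))

  v <- as.integer(img)                       # column-major h*w vector
  R1 <- rep(r1, w); R2 <- rep(r2, w)
  C1 <- rep(c1, each = h); C2 <- rep(c2, each = h)
  WR <- rep(wr, w); WC <- rep(wc, each = h)
  at <- function(ri, ci) lut[cbind(ri, ci, v + 1L)]
  out <- (1 - WR) * (1 - WC) * at(R1, C1) + (1 - WR) * WC * at(R1, C2) +
         WR * (1 - WC) * at(R2, C1) + WR * WC * at(R2, C2)
  gray_image(matrix(pmin(pmax(floor(out + 0.5), 0), 255), h, w))
}

#' Median filtering
#'
#' Each output pixel is the median of its `k x k` neighbourhood; image
#' borders are handled by reflection padding. Suppresses background noise
#' while preserving vessel edges.
#'
#' @param img a [gray_image].
#' @param k odd window size, `k >= 3`.
#' @return A [gray_image].
#' @export
median_filter <- function(img, k = 3) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 3L) stop("k must be odd and >= 3")
  out <- cpp_median_filter(matrix(as.numeric(img), nrow(img), ncol(img)), k)
  gray_image(out)
}
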