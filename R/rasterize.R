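# Polygon rasterization: scanline even-odd fill of a closed polygon into
# a binary pixel mask at a stated pixels-per-mm calibration. Used by the
# synthetic generator to emit masks through the same reader path real
# images take.

#' Rasterize a closed polygon into a binary mask
#'
#' Pixel centers inside the polygon (even-odd rule) become foreground.
#' The mask frame is the polygon bounding box plus a `pad`-pixel
#' background ring, with the usual image convention (row 1 = top).
#'
#' @param poly n x 2 vertex matrix in mm (mathematical axes).
#' @param pixels_per_mm raster calibration (> 0).
#' @param pad background ring width in pixels.
#' @return a [binary_mask()] with an extra `origin_px` element, the
#'   (x, y) offset such that a point at `p` mm appears at pixel-frame
#'   coordinates `p * pixels_per_mm - origin_px + 1`.
#' @export
rasterize_polygon <- function(poly, pixels_per_mm, pad = 2L) {
  validate_polygon(poly, require_ccw = FALSE)
  if (pixels_per_mm <= 0) stop("pixels_per_mm must be positive")
  v <- poly * pixels_per_mm
  pad <- as.integer(pad)
  x0 <- floor(min(v[, 1L])) - pad
  y0 <- floor(min(v[, 2L])) - pad
  w <- ceiling(max(v[, 1L])) - x0 + pad + 1L
  h <- ceiling(max(v[, 2L])) - y0 + pad + 1L
  xs <- x0 + seq_len(w) - 1L           # pixel-center x coordinates
  ys <- y0 + seq_len(h) - 1L           # pixel-center y coordinates
  n <- nrow(v)
  j <- c(2:n, 1L)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- v[j, 1L]; by <- v[j, 2L]
  m <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    yc <- ys[r]
    crosses <- (ay <= yc & by > yc) | (by <= yc & ay > yc)
    if (!any(crosses)) next
    xi <- ax[crosses] + (yc - ay[crosses]) / (by[crosses] - ay[crosses]) *
      (bx[crosses] - ax[crosses])
    xi <- sort(xi)
    inside <- rep(FALSE, w)
    for (s in seq(1L, length(xi) - 1L, by = 2L))
      inside <- inside | (xs > xi[s] & xs < xi[s + 1L])
    # image row 1 is the top: flip y
    m[h - r + 1L, inside] <- 1L
  }
  out <- binary_mask(m)
  out$origin_px <- c(x0, y0)
  out
}
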