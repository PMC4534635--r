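## Preparation of tumor-core images for crowd scoring: color negation, an
## HSL saturation/hue transform, and 4x4 tiling with corner removal. Images
## are plain H x W x 3 arrays of 8-bit channel values (0-255).

check_core_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_invalid("image must be an H x W x 3 array")
  if (dim(img)[1] < 4L || dim(img)[2] < 4L)
    stop_invalid("image must be at least 4 x 4 pixels")
  if (min(img) < 0 || max(img) > 255)
    stop_invalid("channel values must lie in [0, 255]")
  invisible(img)
}

#' Color negation
#'
#' Replaces each pixel by its complementary color (`255 - c` per channel),
#' the first step in making faint nuclear staining visible to untrained
#' scorers. An involution: negating twice restores the image.
#'
#' @param img H x W x 3 array, values 0-255.
#' @return array of the same shape.
#' @export
negate <- function(img) {
  check_core_image(img)
  255 - img
}

## RGB (0-1) <-> HSL, vectorized over pixels. H in degrees [0, 360).
rgb_to_hsl <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- numeric(length(r))
  i <- d > 0 & mx == r
  h[i] <- 60 * (((g[i] - b[i]) / d[i]) %% 6)
  i <- d > 0 & mx == g & mx != r
  h[i] <- 60 * ((b[i] - r[i]) / d[i] + 2)
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * ((r[i] - g[i]) / d[i] + 4)
  list(h = h %% 360, s = s, l = l)
}

hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  hp <- (h %% 360) / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  r <- g <- b <- numeric(length(h))
  i <- hp < 1;            r[i] <- c_[i]; g[i] <- x[i]
  i <- hp >= 1 & hp < 2;  r[i] <- x[i];  g[i] <- c_[i]
  i <- hp >= 2 & hp < 3;  g[i] <- c_[i]; b[i] <- x[i]
  i <- hp >= 3 & hp < 4;  g[i] <- x[i];  b[i] <- c_[i]
  i <- hp >= 4 & hp < 5;  r[i] <- x[i];  b[i] <- c_[i]
  i <- hp >= 5;           r[i] <- c_[i]; b[i] <- x[i]
  m <- l - c_ / 2
  list(r = r + m, g = g + m, b = b + m)
}

#' Saturation and hue transform (modulate semantics)
#'
#' Converts to HSL, multiplies saturation by `saturation_pct / 100`
#' (clipped to 1) and rotates the hue by `(hue_pct - 100) / 100 * 180`
#' degrees, then converts back. These are the semantics of ImageMagick's
#' `-modulate` operator, under which the default settings (saturation 300,
#' hue 18) mean a threefold saturation boost and a rotation of -147.6
#' degrees. Grays (zero chroma) are unchanged by any saturation scaling.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param saturation_pct saturation percentage (default 300).
#' @param hue_pct hue percentage (default 18; 100 = no rotation).
#' @return transformed array, values 0-255.
#' @export
saturate_hue <- function(img, saturation_pct = 300, hue_pct = 18) {
  check_core_image(img)
  if (saturation_pct < 0 || hue_pct < 0)
    stop_invalid("percentages must be non-negative")
  d <- dim(img)
  hsl <- rgb_to_hsl(as.vector(img[, , 1]) / 255,
                    as.vector(img[, , 2]) / 255,
                    as.vector(img[, , 3]) / 255)
  h <- (hsl$h + (hue_pct - 100) / 100 * 180) %% 360
  s <- clip(hsl$s * saturation_pct / 100, 0, 1)
  rgb <- hsl_to_rgb(h, s, hsl$l)
  out <- array(0, d)
  out[, , 1] <- clip(rgb$r, 0, 1) * 255
  out[, , 2] <- clip(rgb$g, 0, 1) * 255
  out[, , 3] <- clip(rgb$b, 0, 1) * 255
  out
}

resize_bilinear <- function(img, out_h, out_w) {
  eb <- EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  rs <- EBImage::resize(eb, w = out_w, h = out_h, filter = "bilinear")
  aperm(EBImage::imageData(rs), c(2, 1, 3)) * 255
}

#' Tile a core image and drop the corners
#'
#' Splits the image into a `grid[1] x grid[2]` (default 4 x 4) array of
#' tiles -- remainder pixels are absorbed by the last row and column -- then
#' drops the four corner tiles (which rarely contain tumor material) and
#' resizes the remaining tiles to `out_size` by bilinear interpolation.
#' Tiles are returned in row-major order.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param grid tiling grid, rows x columns.
#' @param out_size output tile size `c(height, width)` in pixels (default
#'   496 x 495).
#' @param drop_corners drop the four corner tiles (default `TRUE`).
#' @return list of tile arrays (12 for a 4 x 4 grid with corners dropped).
#' @export
tile_and_trim <- function(img, grid = c(4L, 4L), out_size = c(496L, 495L),
                          drop_corners = TRUE) {
  check_core_image(img)
  gr <- as.integer(grid)
  if (dim(img)[1] < gr[1] || dim(img)[2] < gr[2])
    stop_invalid("image smaller than the tiling grid")
  h <- dim(img)[1]; w <- dim(img)[2]
  rb <- floor(h / gr[1]); cb <- floor(w / gr[2])
  row_breaks <- c(seq(0, by = rb, length.out = gr[1]), h)
  col_breaks <- c(seq(0, by = cb, length.out = gr[2]), w)
  tiles <- list()
  for (i in seq_len(gr[1])) {
    for (j in seq_len(gr[2])) {
      corner <- (i %in% c(1L, gr[1])) && (j %in% c(1L, gr[2]))
      if (drop_corners && corner) next
      tile <- img[(row_breaks[i] + 1):row_breaks[i + 1],
                  (col_breaks[j] + 1):col_breaks[j + 1], , drop = FALSE]
      tiles[[length(tiles) + 1L]] <-
        resize_bilinear(tile, out_size[1], out_size[2])
    }
  }
  tiles
}

#' Read / write a core image as PNG
#'
#' @param path PNG file path.
#' @return `read_core_image`: H x W x 3 array with values 0-255 (an alpha
#'   channel, if present, is dropped; grayscale is replicated to 3
#'   channels).
#' @export
read_core_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' @rdname read_core_image
#' @param img H x W x 3 array, values 0-255.
#' @export
write_core_image <- function(img, path) {
  check_core_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Full image preparation pipeline
#'
#' Negation, saturation/hue transform, tiling with corner removal --- the
#' steps applied to every core image before it is shown to the crowd.
#'
#' @inheritParams saturate_hue
#' @inheritParams tile_and_trim
#' @return list of prepared sub-image tiles.
#' @export
prepare_core_image <- function(img, saturation_pct = 300, hue_pct = 18,
                               grid = c(4L, 4L), out_size = c(496L, 495L)) {
  tile_and_trim(saturate_hue(negate(img), saturation_pct, hue_pct),
                grid = grid, out_size = out_size)
}
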