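## Attention heatmaps: per-tile attention weights mapped back to their
## spatial coordinates and blended over the (downsampled) slide.

#' Render an attention heatmap
#'
#' Rescales the attention weights to [0, 1] by per-slide min-max (a
#' constant vector maps to 0.5), colours each kept tile's footprint with
#' a perceptually uniform ramp and alpha-blends it over the downsampled
#' slide (or a white canvas). Pixels outside every tile footprint are
#' left untouched.
#'
#' @param alpha attention weights, one per kept tile.
#' @param coords matching level-0 tile coordinates (columns x, y).
#' @param slideDim c(height, width) of the slide at level 0.
#' @param tileSize tile side at level 0.
#' @param downsample rendering downsample factor.
#' @param colormap palette name for [grDevices::hcl.colors()].
#' @param blend overlay opacity in [0, 1].
#' @param background optional [SlideImage] to render over.
#' @param path optional PNG output path.
#' @return invisible h x w x 3 array in [0, 1].
#' @export
renderHeatmap <- function(alpha, coords, slideDim, tileSize = 256L,
                          downsample = 8L, colormap = "viridis",
                          blend = 0.6, background = NULL, path = NULL) {
  coords <- rbind(coords)
  if (length(alpha) != nrow(coords))
    stop("alpha and coords must have the same length")
  H <- slideDim[1]; W <- slideDim[2]
  if (any(coords[, 1] < 0 | coords[, 1] + tileSize > W |
          coords[, 2] < 0 | coords[, 2] + tileSize > H))
    stop("tile coordinate outside slide bounds")
  h <- ceiling(H / downsample); w <- ceiling(W / downsample)
  canvas <- if (is.null(background)) {
    array(1, dim = c(h, w, 3L))
  } else {
    px <- background@pixels[seq(1L, H, by = downsample),
                            seq(1L, W, by = downsample), , drop = FALSE] / 255
    px[seq_len(h), seq_len(w), , drop = FALSE]
  }
  rng <- range(alpha)
  norm <- if (rng[2] > rng[1]) (alpha - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, length(alpha))
  ramp <- grDevices::col2rgb(grDevices::hcl.colors(256L, colormap)) / 255
  for (i in seq_along(alpha)) {
    rows <- (floor(coords[i, 2] / downsample) + 1):
      min(ceiling((coords[i, 2] + tileSize) / downsample), h)
    cols <- (floor(coords[i, 1] / downsample) + 1):
      min(ceiling((coords[i, 1] + tileSize) / downsample), w)
    col <- ramp[, 1L + round(norm[i] * 255)]
    for (ch in 1:3)
      canvas[rows, cols, ch] <-
        (1 - blend) * canvas[rows, cols, ch] + blend * col[ch]
  }
  if (!is.null(path)) png::writePNG(canvas, path)
  invisible(canvas)
}

#' Write a tissue-mask preview overlay
#'
#' Downsampled slide with the tissue mask tinted green, for quick visual
#' checks of segmentation parameters.
#'
#' @param slide a [SlideImage].
#' @param mask its [TissueMask].
#' @param path PNG output path.
#' @param blend overlay opacity.
#' @return invisible path.
#' @export
writeMaskPreview <- function(slide, mask, path, blend = 0.4) {
  ds <- mask@downsample
  d <- dim(slide@pixels)
  px <- slide@pixels[seq(1L, d[1], by = ds), seq(1L, d[2], by = ds), ,
                     drop = FALSE] / 255
  mm <- mask@mask[seq_len(dim(px)[1]), seq_len(dim(px)[2])]
  g <- px[, , 2]
  px[, , 2] <- (1 - blend * mm) * g + blend * mm
  px[, , 1] <- (1 - blend * mm) * px[, , 1]
  px[, , 3] <- (1 - blend * mm) * px[, , 3]
  png::writePNG(px, path)
  invisible(path)
}
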