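## Whole-slide tiling: HSV-saturation tissue segmentation, the
## four-point tile-validity rule over a non-overlapping level-0 grid,
## and tile preprocessing (bicubic resize + encoder-space
## normalisation).

#' Segmentation parameters
#'
#' @param medianKernel odd median-filter kernel size (default 7).
#' @param satThreshold fixed saturation threshold on the 0-255 scale
#'   (default 8); ignored when \code{useOtsu}.
#' @param useOtsu use Otsu's adaptive threshold instead of the fixed one.
#' @param closeKernel side of the square structuring element for
#'   morphological closing (default 4).
#' @param whiteSatMax background (white-area) exclusion: pixels with
#'   saturation below this and brightness at least
#'   \code{whiteBrightMin} are removed from the mask.
#' @param whiteBrightMin brightness floor of the white filter (0-255).
#' @param blackRgbMeanMin over-stain (black-area) exclusion: pixels with
#'   mean RGB below this are removed.
#' @return list of parameters.
#' @export
segParams <- function(medianKernel = 7L, satThreshold = 8L,
                      useOtsu = FALSE, closeKernel = 4L,
                      whiteSatMax = 15L, whiteBrightMin = 200L,
                      blackRgbMeanMin = 50L) {
  stopifnot(medianKernel >= 1L, medianKernel %% 2L == 1L,
            satThreshold >= 0L, satThreshold <= 255L,
            closeKernel >= 1L,
            whiteSatMax >= 0L, whiteSatMax <= 255L,
            blackRgbMeanMin >= 0L, blackRgbMeanMin <= 255L)
  list(medianKernel = as.integer(medianKernel),
       satThreshold = as.integer(satThreshold),
       useOtsu = isTRUE(useOtsu), closeKernel = as.integer(closeKernel),
       whiteSatMax = as.integer(whiteSatMax),
       whiteBrightMin = as.integer(whiteBrightMin),
       blackRgbMeanMin = as.integer(blackRgbMeanMin))
}

#' Tile grid specification
#'
#' @param tileSize tile side in level-0 pixels (default 256).
#' @param stride grid stride (default 256: no overlap).
#' @param level pyramid level to read tiles from (only level 0 is
#'   supported for flat images).
#' @param validityRule \code{"four_pt_any"} (keep a tile if at least one
#'   of the four probe points falls in tissue; permissive default) or
#'   \code{"four_pt_all"} (all four).
#' @param outputSize side of the resized tile fed to the encoder
#'   (default 224).
#' @return list of parameters.
#' @export
tileSpec <- function(tileSize = 256L, stride = 256L, level = 0L,
                     validityRule = c("four_pt_any", "four_pt_all"),
                     outputSize = 224L) {
  validityRule <- match.arg(validityRule)
  stopifnot(tileSize > 0L, stride > 0L, outputSize > 0L, level >= 0L)
  list(tileSize = as.integer(tileSize), stride = as.integer(stride),
       level = as.integer(level), validityRule = validityRule,
       outputSize = as.integer(outputSize))
}

#' Normalisation parameters for tile preprocessing
#'
#' Defaults are the ImageNet channel statistics, used when no
#' encoder-specific values are supplied (the appropriate statistics are
#' those of the pretrained encoder in use).
#'
#' @param mean,std per-channel mean and standard deviation on the [0, 1]
#'   scale; all std components must be positive.
#' @return list of parameters.
#' @export
normParams <- function(mean = c(0.485, 0.456, 0.406),
                       std = c(0.229, 0.224, 0.225)) {
  stopifnot(length(mean) == 3L, length(std) == 3L, all(std > 0))
  list(mean = mean, std = std, interpolation = "bicubic")
}

#' Segment tissue from an RGB slide image
#'
#' HSV-saturation pipeline: convert to HSV and take the saturation
#' channel; median-filter it; binarise at the fixed saturation threshold
#' (or Otsu); morphologically close with a square structuring element;
#' then remove white background (low saturation at high brightness) and
#' over-stained black regions (low mean RGB). The mask is computed at
#' the coarsest working downsample whose longest side is at most 4096
#' px.
#'
#' @param slide a [SlideImage].
#' @param params a [segParams()] list.
#' @return a [TissueMask].
#' @export
segmentTissue <- function(slide, params = segParams()) {
  px <- slide@pixels
  d <- dim(px)
  if (length(d) != 3L || d[3] != 3L)
    stop("segmentTissue expects an RGB (H x W x 3) image")
  ds <- 1L
  while (max(d[1:2]) / ds > 4096) ds <- ds * 2L
  if (ds > 1L)
    px <- px[seq(1L, d[1], by = ds), seq(1L, d[2], by = ds), , drop = FALSE]
  if (params$medianKernel > min(dim(px)[1:2]))
    stop("median kernel larger than the working image")

  R <- px[, , 1] / 255; G <- px[, , 2] / 255; B <- px[, , 3] / 255
  mx <- pmax(R, G, B); mn <- pmin(R, G, B)
  S <- ifelse(mx > 0, (mx - mn) / mx, 0)   # HSV saturation
  V <- mx                                  # HSV value / brightness

  med <- if (params$medianKernel > 1L) {
    EBImage::medianFilter(S, (params$medianKernel - 1L) %/% 2L)
  } else S
  thr <- if (params$useOtsu) EBImage::otsu(med, range = c(0, 1))
         else params$satThreshold / 255
  bin <- (med > thr) * 1
  if (params$closeKernel > 1L && any(bin == 1)) {
    kern <- matrix(1, params$closeKernel, params$closeKernel)
    bin <- EBImage::closing(bin, kern)
  }
  white <- (S * 255 < params$whiteSatMax) & (V * 255 >= params$whiteBrightMin)
  black <- (R + G + B) / 3 * 255 < params$blackRgbMeanMin
  bin[white | black] <- 0
  new("TissueMask", mask = matrix(as.numeric(bin), nrow(bin), ncol(bin)),
      downsample = as.numeric(ds))
}

#' Extract the filtered level-0 tile grid
#'
#' Enumerates the non-overlapping (or strided) grid of fully-contained
#' tiles in row-major order (y outer, x inner) and keeps each candidate
#' according to the four-point rule: the four probe points at
#' (cx +- tileSize/4, cy +- tileSize/4) around the tile centre are
#' looked up in the tissue mask, and the tile survives if at least one
#' (\code{four_pt_any}) or all four (\code{four_pt_all}) fall in tissue.
#' Coordinates are 0-based top-left corners at level 0, half-open
#' \code{[x, x + tileSize)}.
#'
#' @param slide a [SlideImage].
#' @param mask a [TissueMask] for that slide.
#' @param spec a [tileSpec()] list.
#' @return integer matrix with columns \code{x}, \code{y} (possibly 0
#'   rows), with the spec recorded in attributes.
#' @export
extractTileGrid <- function(slide, mask, spec = tileSpec()) {
  d <- dim(slide@pixels)
  if (spec$level >= length(slide@levelDownsamples))
    stop("requested pyramid level does not exist")
  if (spec$level != 0L)
    stop("only level-0 extraction is supported for flat images")
  H <- d[1]; W <- d[2]; ts <- spec$tileSize
  mm <- mask@mask; ds <- mask@downsample
  keepEmpty <- matrix(integer(0), 0L, 2L,
                      dimnames = list(NULL, c("x", "y")))
  if (W < ts || H < ts) return(.gridAttr(keepEmpty, spec, ds))
  xs <- seq(0L, W - ts, by = spec$stride)
  ys <- seq(0L, H - ts, by = spec$stride)
  cand <- cbind(x = rep(xs, times = length(ys)),
                y = rep(ys, each = length(xs)))
  probe <- function(px, py) {
    col <- pmin(pmax(floor(px / ds) + 1, 1), ncol(mm))
    row <- pmin(pmax(floor(py / ds) + 1, 1), nrow(mm))
    mm[cbind(row, col)] == 1
  }
  cx <- cand[, "x"] + ts / 2; cy <- cand[, "y"] + ts / 2
  off <- ts / 4
  hits <- cbind(probe(cx - off, cy - off), probe(cx + off, cy - off),
                probe(cx - off, cy + off), probe(cx + off, cy + off))
  keep <- if (spec$validityRule == "four_pt_any") rowSums(hits) >= 1L
          else rowSums(hits) == 4L
  .gridAttr(cand[keep, , drop = FALSE], spec, ds)
}

.gridAttr <- function(coords, spec, downsample) {
  storage.mode(coords) <- "integer"
  attr(coords, "tileSize") <- spec$tileSize
  attr(coords, "stride") <- spec$stride
  attr(coords, "level") <- spec$level
  attr(coords, "downsample") <- downsample
  coords
}

#' Cut tile pixel arrays out of a slide
#'
#' @param slide a [SlideImage].
#' @param coords coordinate matrix from [extractTileGrid()].
#' @param spec the matching [tileSpec()].
#' @return list of tileSize x tileSize x 3 arrays (0-255).
#' @export
extractTiles <- function(slide, coords, spec = tileSpec()) {
  ts <- spec$tileSize
  lapply(seq_len(nrow(coords)), function(i) {
    x <- coords[i, "x"]; y <- coords[i, "y"]
    slide@pixels[(y + 1):(y + ts), (x + 1):(x + ts), , drop = FALSE]
  })
}

#' Preprocess one tile for the encoder
#'
#' Resize to \code{outputSize} with bicubic interpolation, scale from
#' [0, 255] to [0, 1], then standardise each channel with the encoder's
#' mean and standard deviation -- in that order.
#'
#' @param tile tileSize x tileSize x 3 array with 8-bit values.
#' @param norm a [normParams()] list.
#' @param spec a [tileSpec()] list (supplies the output size).
#' @return outputSize x outputSize x 3 numeric array.
#' @export
preprocessTile <- function(tile, norm = normParams(), spec = tileSpec()) {
  d <- dim(tile)
  if (length(d) != 3L || d[3] != 3L || d[1] != spec$tileSize ||
      d[2] != spec$tileSize)
    stop(sprintf("tile must be %d x %d x 3", spec$tileSize, spec$tileSize))
  if (any(tile < 0 | tile > 255)) stop("tile values must be 8-bit (0-255)")
  n <- spec$outputSize
  Wy <- .bicubicWeights(d[1], n)
  Wx <- .bicubicWeights(d[2], n)
  out <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) {
    resized <- Wy %*% tile[, , ch] %*% t(Wx)
    out[, , ch] <- (resized / 255 - norm$mean[ch]) / norm$std[ch]
  }
  out
}

## Dense separable bicubic resampling weights (Catmull-Rom kernel,
## a = -0.5), pixel-centre aligned, edge-clamped. Row o holds the
## weights of output sample o over the input samples.
.bicubicWeights <- function(nIn, nOut) {
  a <- -0.5
  kern <- function(d) {
    d <- abs(d)
    ifelse(d <= 1, (a + 2) * d^3 - (a + 3) * d^2 + 1,
           ifelse(d < 2, a * d^3 - 5 * a * d^2 + 8 * a * d - 4 * a, 0))
  }
  scale <- nIn / nOut
  W <- matrix(0, nOut, nIn)
  for (o in seq_len(nOut)) {
    src <- (o - 0.5) * scale - 0.5          # 0-based input position
    k <- floor(src)
    for (tap in (k - 1):(k + 2)) {
      w <- kern(src - tap)
      idx <- min(max(tap, 0), nIn - 1) + 1  # clamp to the border
      W[o, idx] <- W[o, idx] + w
    }
  }
  W
}

#' Read a flat RGB image file as a SlideImage
#'
#' PNG and TIFF are supported; an alpha channel is dropped; non-RGB
#' images are rejected.
#'
#' @param path image file.
#' @param micronsPerPixel physical resolution to record (default 0.25).
#' @return a [SlideImage].
#' @export
readSlideImage <- function(path, micronsPerPixel = 0.25) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) != 3L) stop("image is not RGB")
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L) stop("image is not RGB")
  new("SlideImage", pixels = img * 255,
      micronsPerPixel = micronsPerPixel, levelDownsamples = 1)
}

#' Physical tile size
#'
#' Side length of a tile in micrometres: tileSize x micronsPerPixel
#' (64 um for 256 px at 0.25 um/px).
#'
#' @param slide a [SlideImage].
#' @param spec a [tileSpec()] list.
#' @return size in micrometres.
#' @export
tileMicrons <- function(slide, spec = tileSpec()) {
  spec$tileSize * slide@micronsPerPixel
}
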