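## Encoder contract and feature-bag construction. Pretrained foundation
## encoders plug in through the same contract; the package ships a
## deterministic synthetic encoder for testing, not any weights.

#' Deterministic synthetic tile encoder
#'
#' Computes, per tile, a 12-vector of per-channel summary statistics
#' (mean, sd, min, max for each of R, G, B) and maps it through a fixed
#' seeded random linear projection to D dimensions, so distinct tile
#' appearances yield distinct, bit-reproducible feature vectors. Useful
#' for exercising the full pipeline without pretrained weights.
#'
#' @param seed projection seed.
#' @param dim output dimensionality D.
#' @return an encoder contract: list with \code{name}, \code{dim} and
#'   \code{encode(tiles)} mapping a list of H x W x 3 arrays to an
#'   N x D matrix.
#' @export
syntheticEncoder <- function(seed = 7L, dim = 64L) {
  stopifnot(dim >= 1L)
  P <- .withSeed(seed, matrix(rnorm(dim * 12L), dim, 12L))
  stats1 <- function(tile) {
    unlist(lapply(1:3, function(ch) {
      v <- as.numeric(tile[, , ch])
      c(mean(v), if (length(v) > 1L) sd(v) else 0, min(v), max(v))
    }))
  }
  structure(list(
    name = sprintf("synthetic-%d-d%d", seed, dim),
    dim = as.integer(dim),
    encode = function(tiles) {
      if (is.array(tiles)) tiles <- list(tiles)
      t(vapply(tiles, function(tl) drop(P %*% stats1(tl)), numeric(dim)))
    }
  ), class = "milEncoder")
}

#' Encode a slide's tiles into a feature bag
#'
#' @param tiles list of preprocessed tile arrays (length N >= 1).
#' @param coords N x 2 integer coordinate matrix aligned with
#'   \code{tiles}.
#' @param encoder an encoder contract (see [syntheticEncoder()]).
#' @param slideId,patientId identifiers.
#' @param site \code{"primary"} or \code{"metastatic"}.
#' @return a [FeatureBag] with row i = encoder(tiles[[i]]).
#' @export
encodeSlide <- function(tiles, coords, encoder, slideId,
                        patientId = "unknown", site = "primary") {
  if (!length(tiles)) stop("empty bag: no tiles to encode")
  coords <- rbind(coords)
  if (nrow(coords) != length(tiles))
    stop("tiles and coords must have the same length")
  feats <- encoder$encode(tiles)
  if (ncol(feats) != encoder$dim)
    stop("encoder contract violated: wrong output dimensionality")
  cc <- coords[, 1:2, drop = FALSE]
  colnames(cc) <- c("x", "y")
  storage.mode(cc) <- "integer"
  new("FeatureBag", features = feats, coords = cc,
      slideId = as.character(slideId), patientId = as.character(patientId),
      site = site, encoderName = encoder$name)
}

#' Save / load a feature bag container
#'
#' One container file per slide holding the feature matrix, the aligned
#' coordinates and the identifying attributes; the round trip is
#' lossless (features bit-exact). Files with mismatched feature/coord
#' lengths or missing fields are rejected at load.
#'
#' @param bag a [FeatureBag].
#' @param path container file path (\code{.rds}).
#' @return \code{loadBag} returns the [FeatureBag].
#' @export
saveBag <- function(bag, path) {
  saveRDS(list(features = bag@features, coords = bag@coords,
               slide_id = bag@slideId, patient_id = bag@patientId,
               site = bag@site, encoder_name = bag@encoderName), path)
  invisible(path)
}

#' @rdname saveBag
#' @export
loadBag <- function(path) {
  x <- readRDS(path)
  need <- c("features", "coords", "slide_id", "patient_id", "site",
            "encoder_name")
  if (!is.list(x) || !all(need %in% names(x)))
    stop("bag container format error: missing fields in ", path)
  if (nrow(x$features) != nrow(x$coords))
    stop("bag container format error: features/coords length mismatch")
  new("FeatureBag", features = x$features, coords = x$coords,
      slideId = x$slide_id, patientId = x$patient_id, site = x$site,
      encoderName = x$encoder_name)
}
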