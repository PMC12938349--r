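#' @import methods
#' @importFrom stats rnorm runif rbinom rexp quantile median sd
#'   chisq.test kruskal.test plogis uniroot setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

#' FeatureBag: a slide-level bag of tile features
#'
#' The multiple-instance-learning "bag" for one whole-slide image: an
#' \eqn{N \times D} matrix of tile feature vectors \eqn{h_i} with the
#' level-0 tile coordinates aligned row for row, plus slide/patient
#' identifiers, the lesion site, and the name of the encoder that
#' produced the features.
#'
#' @slot features numeric matrix, one row per tile (\eqn{N \ge 1}), all
#'   values finite.
#' @slot coords integer matrix with columns \code{x}, \code{y}: 0-based
#'   top-left tile corners at pyramid level 0, one row per feature row.
#' @slot slideId,patientId character identifiers.
#' @slot site \code{"primary"} or \code{"metastatic"}.
#' @slot encoderName name of the tile encoder.
#'
#' @seealso [encodeSlide()], [saveBag()], [loadBag()]
#' @export
setClass("FeatureBag",
  representation(
    features = "matrix",
    coords = "matrix",
    slideId = "character",
    patientId = "character",
    site = "character",
    encoderName = "character"
  )
)

setValidity("FeatureBag", function(object) {
  msg <- character()
  if (nrow(object@features) < 1L)
    msg <- c(msg, "a bag must contain at least one instance")
  if (!all(is.finite(object@features)))
    msg <- c(msg, "features contain non-finite values")
  if (nrow(object@coords) != nrow(object@features))
    msg <- c(msg, "coords and features must have the same number of rows")
  if (ncol(object@coords) != 2L)
    msg <- c(msg, "coords must have two columns (x, y)")
  if (!object@site %in% c("primary", "metastatic"))
    msg <- c(msg, "site must be 'primary' or 'metastatic'")
  if (length(msg)) msg else TRUE
})

#' SlideImage: an RGB whole-slide-style image
#'
#' A flat 8-bit RGB image together with its (possibly notional) pyramid
#' downsample factors and physical resolution. Level 0 is the native
#' resolution; scanners at a 40x objective give roughly 0.25 um/pixel.
#'
#' @slot pixels numeric array H x W x 3 with values in [0, 255].
#' @slot microsPerPixel physical resolution at level 0 (micrometres).
#' @slot levelDownsamples per-level scale factors; the first must be 1.
#' @export
setClass("SlideImage",
  representation(
    pixels = "array",
    micronsPerPixel = "numeric",
    levelDownsamples = "numeric"
  ),
  prototype(micronsPerPixel = 0.25, levelDownsamples = 1)
)

setValidity("SlideImage", function(object) {
  d <- dim(object@pixels)
  msg <- character()
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be an H x W x 3 array")
  else if (d[1] < 1L || d[2] < 1L)
    msg <- c(msg, "image must be at least 1 x 1")
  if (any(object@pixels < 0 | object@pixels > 255))
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (length(object@levelDownsamples) < 1L ||
      object@levelDownsamples[1] != 1)
    msg <- c(msg, "level 0 downsample must be 1")
  if (length(msg)) msg else TRUE
})

#' TissueMask: binary tissue mask at a working downsample
#'
#' @slot mask numeric 0/1 matrix indexed [row = y, column = x].
#' @slot downsample scale factor from mask space back to level 0.
#' @export
setClass("TissueMask",
  representation(mask = "matrix", downsample = "numeric")
)

setValidity("TissueMask", function(object) {
  msg <- character()
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask values must be 0 or 1")
  if (object@downsample < 1)
    msg <- c(msg, "downsample must be >= 1")
  if (length(msg)) msg else TRUE
})

#' MILCohort: a multimodal slide cohort
#'
#' Container tying together per-slide feature bags, per-patient encoded
#' clinical covariates, the slide-level manifest (identifiers, lesion
#' site, surgery route, response label, survival outcome, split), and --
#' for synthetic cohorts -- the generator's ground truth.
#'
#' @slot bags named list of [FeatureBag] objects, keyed by slide id.
#' @slot clinical numeric matrix of encoded covariates, one row per
#'   patient (rownames are patient ids).
#' @slot manifest data.frame with one row per slide: \code{patient_id},
#'   \code{slide_id}, \code{site}, \code{surgery_type}, \code{label},
#'   \code{time}, \code{event}, \code{split}.
#' @slot schema data.frame describing the clinical encoding (column
#'   name, type, source variable).
#' @slot groundTruth list of generator internals (empty for real data).
#' @export
setClass("MILCohort",
  representation(
    bags = "list",
    clinical = "matrix",
    manifest = "data.frame",
    schema = "data.frame",
    groundTruth = "list"
  ),
  prototype(groundTruth = list())
)

setValidity("MILCohort", function(object) {
  msg <- character()
  m <- object@manifest
  need <- c("patient_id", "slide_id", "site", "surgery_type",
            "label", "time", "event", "split")
  miss <- setdiff(need, names(m))
  if (length(miss))
    msg <- c(msg, paste("manifest lacks columns:", paste(miss, collapse = ", ")))
  if (length(object@bags) && !identical(sort(names(object@bags)),
                                        sort(as.character(m$slide_id))))
    msg <- c(msg, "bag names and manifest slide ids differ")
  if (!all(unique(m$patient_id) %in% rownames(object@clinical)))
    msg <- c(msg, "clinical matrix lacks rows for some patients")
  if ("surgery_type" %in% names(m) &&
      !all(m$surgery_type %in% c("PDS", "IDS")))
    msg <- c(msg, "surgery_type must be PDS or IDS")
  if ("site" %in% names(m) && !all(m$site %in% c("primary", "metastatic")))
    msg <- c(msg, "site must be primary or metastatic")
  ## patient-level consistency: label/survival/split shared across a
  ## patient's slides
  if (all(need %in% names(m)) && nrow(m)) {
    for (col in c("label", "time", "event", "split")) {
      nun <- tapply(m[[col]], m$patient_id, function(x) length(unique(x)))
      bad <- names(nun)[nun > 1L]
      if (length(bad))
        msg <- c(msg, sprintf("patient %s has inconsistent '%s' across slides",
                              bad[1], col))
    }
  }
  if (length(msg)) msg else TRUE
})

#' MILModel: a fitted (or freshly initialised) gated-attention model
#'
#' Holds the network configuration, the named parameter arrays of the
#' dual-route gated-attention network with clinical gated fusion, the
#' task head in use, and the training history.
#'
#' @slot config list created by [milConfig()].
#' @slot params named list of parameter matrices/vectors.
#' @slot task \code{"classification"} or \code{"survival"}.
#' @slot history data.frame of per-epoch training loss and validation
#'   metric (empty before training).
#' @export
setClass("MILModel",
  representation(
    config = "list",
    params = "list",
    task = "character",
    history = "data.frame"
  ),
  prototype(history = data.frame())
)

setValidity("MILModel", function(object) {
  if (!object@task %in% c("classification", "survival"))
    return("task must be 'classification' or 'survival'")
  TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FeatureBag", function(object) {
  cat(sprintf("FeatureBag '%s' (patient %s, %s site)\n",
              object@slideId, object@patientId, object@site))
  cat(sprintf("  %d instances x %d features [%s]\n",
              nrow(object@features), ncol(object@features),
              object@encoderName))
})

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage %d x %d px, %.3g um/px, %d level(s)\n",
              d[1], d[2], object@micronsPerPixel,
              length(object@levelDownsamples)))
})

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask %d x %d at downsample %g (%.1f%% tissue)\n",
              nrow(object@mask), ncol(object@mask), object@downsample,
              100 * mean(object@mask)))
})

setMethod("show", "MILCohort", function(object) {
  m <- object@manifest
  cat(sprintf("MILCohort: %d patients, %d slides (%d primary / %d metastatic)\n",
              length(unique(m$patient_id)), nrow(m),
              sum(m$site == "primary"), sum(m$site == "metastatic")))
  if (!all(is.na(m$split))) {
    sp <- table(m$split[!duplicated(m$patient_id)])
    cat("  split (patients):",
        paste(names(sp), as.integer(sp), sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  clinical covariates: %d; ground truth: %s\n",
              ncol(object@clinical),
              if (length(object@groundTruth)) "yes" else "no"))
})

setMethod("show", "MILModel", function(object) {
  cfg <- object@config
  cat(sprintf("MILModel (%s head)\n", object@task))
  cat(sprintf("  input %d -> attention %d (dual %s routes) -> fusion %d\n",
              cfg$inputDim, cfg$attentionHidden,
              paste(c("PDS", "IDS"), collapse = "/"), cfg$fusionDim))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); best validation metric %.4f\n",
                nrow(object@history), max(object@history$valMetric)))
})

## ---- accessors ----------------------------------------------------------

#' @describeIn FeatureBag the N x D feature matrix
#' @param bag a \code{FeatureBag}
#' @export
bagFeatures <- function(bag) bag@features

#' @describeIn FeatureBag tile coordinates aligned with the feature rows
#' @export
bagCoords <- function(bag) bag@coords

#' @describeIn FeatureBag number of instances N
#' @export
nInstances <- function(bag) nrow(bag@features)

#' Cohort accessors
#'
#' @param cohort a [MILCohort]
#' @return \code{cohortManifest}: the slide-level manifest data.frame;
#'   \code{cohortBags}: the named list of bags; \code{cohortClinical}:
#'   the encoded patient-by-covariate matrix; \code{cohortPatients}:
#'   patient-level data.frame (one row per patient with label, survival
#'   and split).
#' @export
cohortManifest <- function(cohort) cohort@manifest

#' @rdname cohortManifest
#' @export
cohortBags <- function(cohort) cohort@bags

#' @rdname cohortManifest
#' @export
cohortClinical <- function(cohort) cohort@clinical

#' @rdname cohortManifest
#' @export
cohortPatients <- function(cohort) {
  m <- cohort@manifest
  p <- m[!duplicated(m$patient_id),
         c("patient_id", "surgery_type", "label", "time", "event", "split")]
  rownames(p) <- NULL
  p
}

#' @describeIn MILModel per-epoch training history
#' @param model a \code{MILModel}
#' @export
trainingHistory <- function(model) model@history

#' @describeIn MILModel the model configuration list
#' @export
modelConfig <- function(model) model@config
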