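## Cohort manifest I/O and on-disk cohort layout.

.manifestCols <- c("patient_id", "slide_id", "site", "surgery_type",
                   "label", "time", "event", "split")

#' Read and validate a cohort manifest
#'
#' A manifest has one row per slide with the columns \code{patient_id},
#' \code{slide_id}, \code{site} (primary/metastatic),
#' \code{surgery_type} (PDS/IDS), \code{label} (0 = resistant,
#' 1 = sensitive), \code{time} (months), \code{event} (0/1) and
#' \code{split} (train/val/test or empty). Every invariant is enforced
#' at load: enums must be valid, and a patient's slides must agree on
#' label, survival and split (no patient may straddle splits).
#'
#' @param path CSV file.
#' @return validated manifest data.frame.
#' @export
readManifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.manifestCols, names(m))
  if (length(miss))
    stop("manifest lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$slide_id))
    stop("duplicate slide ids in manifest")
  if (!all(m$site %in% c("primary", "metastatic")))
    stop("unknown site value (must be primary/metastatic)")
  if (!all(m$surgery_type %in% c("PDS", "IDS")))
    stop("unknown surgery_type value (must be PDS/IDS)")
  if (!all(m$label %in% c(0L, 1L)))
    stop("label must be 0 (resistant) or 1 (sensitive)")
  if (!all(m$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (any(!is.na(m$time) & m$time <= 0)) stop("time must be positive")
  m$split[is.na(m$split) | m$split == ""] <- NA_character_
  if (!all(is.na(m$split) | m$split %in% c("train", "val", "test")))
    stop("split must be train/val/test")
  for (col in c("label", "time", "event", "split")) {
    nun <- tapply(m[[col]], m$patient_id,
                  function(x) length(unique(x[!is.na(x)])) +
                    (any(is.na(x)) && any(!is.na(x))))
    bad <- names(nun)[nun > 1L]
    if (length(bad))
      stop(sprintf("patient %s has inconsistent '%s' across slides",
                   bad[1], col))
  }
  m
}

#' @rdname readManifest
#' @param manifest manifest data.frame.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a cohort directory
#'
#' On-disk layout: \code{manifest.csv} (with a \code{bag_path} column),
#' one bag container per slide under \code{bags/}, the encoded clinical
#' matrix as \code{clinical.csv}, the schema as \code{schema.csv}, and
#' -- for synthetic cohorts -- the generator ground truth as
#' \code{ground_truth.json}.
#'
#' @param cohort a [MILCohort].
#' @param dir target directory (created if needed).
#' @return \code{readCohort} returns the [MILCohort].
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "bags"), recursive = TRUE, showWarnings = FALSE)
  m <- cohort@manifest
  m$bag_path <- file.path("bags", paste0(m$slide_id, ".rds"))
  for (i in seq_len(nrow(m)))
    saveBag(cohort@bags[[m$slide_id[i]]], file.path(dir, m$bag_path[i]))
  writeManifest(m, file.path(dir, "manifest.csv"))
  cl <- data.frame(patient_id = rownames(cohort@clinical),
                   cohort@clinical, check.names = FALSE)
  write.csv(cl, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort@schema, file.path(dir, "schema.csv"), row.names = FALSE)
  gt <- cohort@groundTruth
  if (length(gt)) {
    gt$clinicalRaw <- NULL
    gt$settings <- NULL
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  m <- readManifest(file.path(dir, "manifest.csv"))
  bags <- setNames(lapply(file.path(dir, m$bag_path), loadBag), m$slide_id)
  cl <- read.csv(file.path(dir, "clinical.csv"), check.names = FALSE)
  clinical <- as.matrix(cl[, -1, drop = FALSE])
  rownames(clinical) <- cl$patient_id
  schema <- read.csv(file.path(dir, "schema.csv"), stringsAsFactors = FALSE)
  gtPath <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtPath)) {
    g <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    g$planted <- lapply(g$planted, as.logical)
    g
  } else list()
  new("MILCohort", bags = bags, clinical = clinical,
      manifest = m[, .manifestCols], schema = schema, groundTruth = gt)
}
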