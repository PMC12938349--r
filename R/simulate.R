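## Synthetic data: (a) seeded multimodal cohorts -- feature bags with a
## planted fraction of signal instances, encoded clinical covariates,
## Bernoulli response labels and exponential survival with independent
## censoring -- with full ground truth; (b) tissue-like images for the
## tiling stage.

#' Synthetic cohort settings
#'
#' Defaults mirror the cohort structure the package targets: ~300
#' patients each contributing two primary-lesion slides and one
#' metastatic slide, bags of 50-200 tiles in a 64-dimensional feature
#' space, a planted signal fraction of 0.2 with instance mean shift 2.0
#' along a fixed direction, 38% high-risk (platinum-resistant-like)
#' patients, 35% primary-debulking surgery, and ~30% independent
#' censoring.
#'
#' @param nPatients number of patients.
#' @param slidesPerPatient named vector: primary and metastatic slides
#'   per patient.
#' @param bagSizeRange min/max tiles per slide.
#' @param dim feature dimensionality D.
#' @param signalFraction planted fraction pi of instances in high-risk
#'   slides.
#' @param effectSize mean shift mu added along the signal direction.
#' @param metastaticBoost multiplier on pi for metastatic slides of
#'   high-risk patients (capped at 1).
#' @param highRiskRate prevalence of the high-risk latent type.
#' @param latentCoef coefficient a on the realized planted fraction in
#'   the latent score.
#' @param clinicalEffect named coefficients on the encoded (centred)
#'   clinical covariates.
#' @param latentNoise sd of the latent-score noise.
#' @param labelSlope logistic slope b of the response-label model.
#' @param baselineHazard exponential baseline rate lambda0 (1/months).
#' @param survivalEffect proportional-hazards coefficient beta_s on the
#'   latent score.
#' @param censoringRate target censoring fraction (0 disables).
#' @param surgeryMix probability of the PDS route.
#' @param seed master seed; per-patient draws use counter-based
#'   sub-seeds so growing the cohort never perturbs earlier patients.
#' @return list of settings.
#' @export
simSettings <- function(nPatients = 300L,
                        slidesPerPatient = c(primary = 2L, metastatic = 1L),
                        bagSizeRange = c(50L, 200L), dim = 64L,
                        signalFraction = 0.2, effectSize = 2.0,
                        metastaticBoost = 1.25, highRiskRate = 0.38,
                        latentCoef = 25, clinicalEffect = NULL,
                        latentNoise = 0.4, labelSlope = 3,
                        baselineHazard = 0.05, survivalEffect = 1,
                        censoringRate = 0.3, surgeryMix = 0.35,
                        seed = 0L) {
  if (is.null(clinicalEffect))
    clinicalEffect <- c(stage_iv = 1.25, suboptimal = 0.75,
                        z_log_ca125 = 0.75,
                        crs_1 = -0.6, crs_2 = 0, crs_3 = 0.6)
  stopifnot(signalFraction >= 0, signalFraction <= 1,
            bagSizeRange[1] >= 1L, bagSizeRange[1] <= bagSizeRange[2],
            censoringRate >= 0, censoringRate < 1,
            length(clinicalEffect) == 6L)
  list(nPatients = as.integer(nPatients),
       slidesPerPatient = slidesPerPatient,
       bagSizeRange = as.integer(bagSizeRange), dim = as.integer(dim),
       signalFraction = signalFraction, effectSize = effectSize,
       metastaticBoost = metastaticBoost, highRiskRate = highRiskRate,
       latentCoef = latentCoef, clinicalEffect = clinicalEffect,
       latentNoise = latentNoise, labelSlope = labelSlope,
       baselineHazard = baselineHazard, survivalEffect = survivalEffect,
       censoringRate = censoringRate, surgeryMix = surgeryMix,
       seed = as.integer(seed))
}

## Counter-based sub-seed: a fixed integer hash of (seed, counter), so
## each patient owns an independent reproducible RNG block.
.subSeed <- function(seed, counter) {
  as.integer((as.double(seed) * 2654435761 + as.double(counter) * 97003 +
                12345) %% 2147483647)
}

## Fixed encoding constants of the simulated clinical schema: one
## stage-like binary, one cytoreduction-like binary, one log-normal
## marker (z-scored with fixed constants), one 3-level categorical.
.simSchema <- function() {
  data.frame(
    name = c("stage_iv", "suboptimal", "z_log_ca125",
             "crs_1", "crs_2", "crs_3"),
    type = c("binary", "binary", "continuous",
             "onehot", "onehot", "onehot"),
    source = c("stage", "cytoreduction", "ca125", "crs", "crs", "crs"),
    stringsAsFactors = FALSE)
}

.simClinicalMeans <- function() c(0.17, 0.70, 0, 1 / 3, 1 / 3, 1 / 3)

## Draw one patient's encoded clinical row (assumes the caller set the
## RNG state).
.drawClinical <- function() {
  stage <- rbinom(1L, 1L, 0.17)
  subopt <- rbinom(1L, 1L, 0.70)
  zca <- rnorm(1L)                     # z-scored log CA-125
  crs <- sample.int(3L, 1L)
  c(stage_iv = stage, suboptimal = subopt, z_log_ca125 = zca,
    crs_1 = as.integer(crs == 1L), crs_2 = as.integer(crs == 2L),
    crs_3 = as.integer(crs == 3L))
}

## Expected latent score under the settings (clinical effects are
## centred and the noise has mean zero, so only the planted-fraction
## term contributes). Used to centre the label and hazard models, which
## keeps the null generator (zero effects) balanced at 50/50.
.latentCenter <- function(cfg) {
  nPrim <- cfg$slidesPerPatient[["primary"]]
  nMet <- cfg$slidesPerPatient[["metastatic"]]
  meanFrac <- (nPrim * cfg$signalFraction +
                 nMet * min(cfg$metastaticBoost * cfg$signalFraction, 1)) /
    (nPrim + nMet)
  cfg$latentCoef * cfg$highRiskRate * meanFrac
}

## Censoring rate lambda_c solving E[lc / (lc + hazard)] = target over
## the settings-level latent-score distribution (fixed internal Monte
## Carlo, independent of nPatients and of the master seed).
.censoringRate <- function(cfg) {
  if (cfg$censoringRate <= 0) return(0)
  haz <- .withSeed(990017L, {
    n <- 20000L
    z <- rbinom(n, 1L, cfg$highRiskRate)
    C <- t(replicate(n, .drawClinical()))
    s <- cfg$latentCoef * cfg$signalFraction * z +
      drop((C - matrix(.simClinicalMeans(), n, 6L, byrow = TRUE)) %*%
             cfg$clinicalEffect) +
      rnorm(n, sd = cfg$latentNoise)
    cfg$baselineHazard * exp(cfg$survivalEffect * (s - .latentCenter(cfg)))
  })
  f <- function(lg) mean(exp(lg) / (exp(lg) + haz)) - cfg$censoringRate
  exp(uniroot(f, c(-20, 10))$root)
}

#' Simulate a multimodal cohort with known ground truth
#'
#' Each patient carries a latent high-risk type z (aggressive-morphology
#' instances are planted only in the slides of high-risk patients, at
#' fraction \code{round(pi * N) / N}, with a boosted fraction on the
#' metastatic slide). Background instances are standard normal in D
#' dimensions; planted instances are shifted by \code{effectSize} along
#' a fixed seeded unit direction. The latent score is
#' \eqn{s = a f_{planted} + \gamma^T (C - E C) + \epsilon}; the response
#' label (1 = treatment-sensitive) follows
#' \eqn{Bern(\sigma(-b (s - s_0)))} so that high-risk patients are
#' mostly resistant; survival times are exponential with hazard
#' \eqn{\lambda_0 \exp(\beta_s (s - s_0))} under independent exponential
#' censoring tuned to the target censoring fraction.
#'
#' @param cfg a [simSettings()] list.
#' @return a [MILCohort]; the \code{groundTruth} slot holds the signal
#'   direction, latent scores, per-slide planted flags, hazards, label
#'   probabilities and the raw clinical table.
#' @export
simulateCohort <- function(cfg = simSettings()) {
  D <- cfg$dim
  u <- .withSeed(.subSeed(cfg$seed, 0L), {
    v <- rnorm(D); v / sqrt(sum(v^2))
  })
  lambdaC <- .censoringRate(cfg)
  s0 <- .latentCenter(cfg)
  EC <- .simClinicalMeans()

  nP <- cfg$nPatients
  bags <- list(); manifest <- list()
  clinical <- matrix(0, nP, 6L)
  raw <- list()
  z <- integer(nP); s <- numeric(nP); labelProb <- numeric(nP)
  hazard <- numeric(nP); planted <- list(); frac <- numeric(nP)
  pid <- sprintf("P%04d", seq_len(nP))

  for (i in seq_len(nP)) {
    res <- .withSeed(.subSeed(cfg$seed, i), {
      zi <- rbinom(1L, 1L, cfg$highRiskRate)
      Ci <- .drawClinical()
      eps <- rnorm(1L, sd = cfg$latentNoise)
      surgery <- if (runif(1L) < cfg$surgeryMix) "PDS" else "IDS"
      nPrim <- cfg$slidesPerPatient[["primary"]]
      nMet <- cfg$slidesPerPatient[["metastatic"]]
      sites <- c(rep("primary", nPrim), rep("metastatic", nMet))
      slideBags <- list(); fl <- list(); fr <- numeric(length(sites))
      for (k in seq_along(sites)) {
        N <- sample(seq(cfg$bagSizeRange[1], cfg$bagSizeRange[2]), 1L)
        pi_k <- if (zi == 1L) {
          if (sites[k] == "metastatic")
            min(cfg$metastaticBoost * cfg$signalFraction, 1)
          else cfg$signalFraction
        } else 0
        nSig <- round(pi_k * N)
        H <- matrix(rnorm(N * D), N, D)
        flags <- rep(FALSE, N)
        if (nSig > 0L) {
          idx <- sample.int(N, nSig)
          H[idx, ] <- H[idx, ] + rep(cfg$effectSize * u, each = nSig)
          flags[idx] <- TRUE
        }
        slideBags[[k]] <- H; fl[[k]] <- flags; fr[k] <- nSig / N
      }
      fpl <- mean(fr)
      si <- cfg$latentCoef * fpl + sum(cfg$clinicalEffect * (Ci - EC)) + eps
      pSens <- plogis(-cfg$labelSlope * (si - s0))
      yi <- rbinom(1L, 1L, pSens)
      hi <- cfg$baselineHazard * exp(cfg$survivalEffect * (si - s0))
      tEvent <- rexp(1L, hi)
      tCens <- if (lambdaC > 0) rexp(1L, lambdaC) else Inf
      list(z = zi, C = Ci, surgery = surgery, sites = sites,
           bags = slideBags, flags = fl, frac = fpl, s = si,
           pSens = pSens, label = yi, hazard = hi,
           time = min(tEvent, tCens),
           event = as.integer(tEvent <= tCens))
    })
    z[i] <- res$z; s[i] <- res$s; labelProb[i] <- res$pSens
    hazard[i] <- res$hazard; frac[i] <- res$frac
    clinical[i, ] <- res$C
    raw[[i]] <- data.frame(patient_id = pid[i],
                           stage = res$C[["stage_iv"]],
                           cytoreduction = res$C[["suboptimal"]],
                           z_log_ca125 = res$C[["z_log_ca125"]],
                           crs = which(res$C[4:6] == 1L))
    for (k in seq_along(res$sites)) {
      sid <- sprintf("%s_S%d", pid[i], k)
      bags[[sid]] <- new("FeatureBag",
        features = res$bags[[k]],
        coords = cbind(x = rep(0L, nrow(res$bags[[k]])),
                       y = seq_len(nrow(res$bags[[k]])) - 1L),
        slideId = sid, patientId = pid[i], site = res$sites[k],
        encoderName = "simulated")
      planted[[sid]] <- res$flags[[k]]
      manifest[[length(manifest) + 1L]] <- data.frame(
        patient_id = pid[i], slide_id = sid, site = res$sites[k],
        surgery_type = res$surgery, label = res$label,
        time = res$time, event = res$event, split = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  rownames(clinical) <- pid
  colnames(clinical) <- .simSchema()$name
  gt <- list(u = u, z = setNames(z, pid), s = setNames(s, pid),
             labelProb = setNames(labelProb, pid),
             hazard = setNames(hazard, pid),
             plantedFraction = setNames(frac, pid),
             planted = planted, censoringHazard = lambdaC,
             clinicalRaw = do.call(rbind, raw), settings = cfg)
  new("MILCohort", bags = bags, clinical = clinical,
      manifest = do.call(rbind, manifest), schema = .simSchema(),
      groundTruth = gt)
}

#' Generator oracle score
#'
#' The projection of each slide's mean feature vector onto the planted
#' signal direction, aggregated per patient -- the generator's own view
#' of how separable the cohort is, independent of any trained model.
#'
#' @param cohort a synthetic [MILCohort] (must carry ground truth).
#' @param aggregate \code{"mean"} or \code{"median"} across a patient's
#'   slides.
#' @return data.frame with \code{patient_id}, \code{score},
#'   \code{label}, \code{time}, \code{event}, \code{split}.
#' @export
oracleScore <- function(cohort, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  gt <- cohort@groundTruth
  if (!length(gt)) stop("cohort has no ground truth")
  m <- cohort@manifest
  slideScore <- vapply(m$slide_id, function(sid)
    sum(colMeans(cohort@bags[[sid]]@features) * gt$u), numeric(1))
  pats <- unique(m$patient_id)
  out <- do.call(rbind, lapply(pats, function(p) {
    sl <- which(m$patient_id == p)
    data.frame(patient_id = p,
               score = aggregatePatient(slideScore[sl], aggregate)$aggregate,
               label = m$label[sl[1]], time = m$time[sl[1]],
               event = m$event[sl[1]], split = m$split[sl[1]])
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a tissue-like slide image with known mask
#'
#' White background with saturated elliptical "tissue" blobs (random
#' hue, high saturation) and optional pure-black artifact patches;
#' returns the image together with the exact ground-truth tissue mask
#' (blobs minus artifact patches) at level 0.
#'
#' @param width,height canvas size in pixels (at least 256 each).
#' @param nBlobs number of elliptical tissue regions.
#' @param seed RNG seed.
#' @param blackPatches number of 48-px square black artifact patches.
#' @return list with \code{slide} (a [SlideImage]) and \code{mask}
#'   (H x W 0/1 matrix).
#' @export
simulateTissueImage <- function(width = 768L, height = 768L, nBlobs = 3L,
                                seed = 0L, blackPatches = 0L) {
  if (width < 256L || height < 256L)
    stop("canvas must be at least 256 x 256")
  maxAxis <- floor(min(width, height) / 4)
  if (maxAxis < 48L) stop("canvas too small for tissue blobs")
  .withSeed(seed, {
    px <- array(255, dim = c(height, width, 3L))
    mask <- matrix(0, height, width)
    xs <- matrix(seq_len(width), height, width, byrow = TRUE)
    ys <- matrix(seq_len(height), height, width)
    for (b in seq_len(nBlobs)) {
      a <- runif(1L, 48, maxAxis); bb <- runif(1L, 48, maxAxis)
      th <- runif(1L, 0, pi)
      cx <- runif(1L, a + 1, width - a - 1)
      cy <- runif(1L, bb + 1, height - bb - 1)
      col <- grDevices::col2rgb(grDevices::hsv(runif(1L), 0.85, 0.9))
      dx <- xs - cx; dy <- ys - cy
      rx <- cos(th) * dx + sin(th) * dy
      ry <- -sin(th) * dx + cos(th) * dy
      inside <- (rx / a)^2 + (ry / bb)^2 <= 1
      for (ch in 1:3) {
        pl <- px[, , ch]; pl[inside] <- col[ch]; px[, , ch] <- pl
      }
      mask[inside] <- 1
    }
    if (blackPatches > 0L) {
      for (b in seq_len(blackPatches)) {
        sz <- 48L
        x0 <- sample.int(width - sz, 1L); y0 <- sample.int(height - sz, 1L)
        px[y0:(y0 + sz - 1L), x0:(x0 + sz - 1L), ] <- 0
        mask[y0:(y0 + sz - 1L), x0:(x0 + sz - 1L)] <- 0
      }
    }
    list(slide = new("SlideImage", pixels = px, micronsPerPixel = 0.25,
                     levelDownsamples = 1),
         mask = mask)
  })
}
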