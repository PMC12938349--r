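## Training: per-slide Adam optimisation with the combined
## classification objective, minibatch Cox partial-likelihood training
## for the survival head, early stopping on a validation metric, and
## patient-level aggregation at evaluation time.

#' Training configuration with the per-task default hyperparameters
#'
#' Classification: Adam, learning rate 5e-5, weight decay 1e-4, dropout
#' 0.5, combined loss weight lambda = 0.9, one optimisation example per
#' slide. Survival: Adam, learning rate 2e-4, weight decay 1e-5, dropout
#' 0.25, minibatch Cox risk sets (16 slides per batch) and a step
#' learning-rate scheduler (halved every 10 epochs). Both tasks: at most
#' 50 epochs, early stopping with patience 5 on the validation metric
#' (patient-level AUC or C-index), and a floor of 10 epochs before
#' stopping is allowed.
#'
#' @param task \code{"classification"} or \code{"survival"}.
#' @param ... named overrides of any field.
#' @return list of training settings.
#' @export
trainSettings <- function(task = c("classification", "survival"), ...) {
  task <- match.arg(task)
  base <- if (task == "classification") {
    list(task = task, learningRate = 5e-5, weightDecay = 1e-4,
         maxEpochs = 50L, patience = 5L, minEpochs = 10L,
         lambdaInst = 0.9, dropout = 0.5, batchSize = 1L,
         scheduler = NULL, aggregate = "mean",
         splitFractions = c(train = 0.65, val = 0.20, test = 0.15))
  } else {
    list(task = task, learningRate = 2e-4, weightDecay = 1e-5,
         maxEpochs = 50L, patience = 5L, minEpochs = 10L,
         lambdaInst = 0, dropout = 0.25, batchSize = 16L,
         scheduler = list(stepSize = 10L, gamma = 0.5),
         aggregate = "mean",
         splitFractions = c(train = 0.65, val = 0.20, test = 0.15))
  }
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(base)))
  out <- modifyList(base, ov)
  stopifnot(out$patience <= out$maxEpochs,
            abs(sum(out$splitFractions) - 1) < 1e-8)
  out
}

#' Patient-level random split
#'
#' Randomly allocates patients (never slides) to train/validation/test
#' in the given proportions; all of a patient's slides share the split.
#' Optional stratification by the response label keeps class balance.
#'
#' @param cohort a [MILCohort].
#' @param fractions length-3 proportions summing to 1.
#' @param seed RNG seed.
#' @param stratify stratify by label (default FALSE: simple random).
#' @return the cohort with \code{split} filled in.
#' @export
splitCohort <- function(cohort, fractions = c(0.65, 0.20, 0.15),
                        seed = 0L, stratify = FALSE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3L)
  m <- cohort@manifest
  pats <- unique(m$patient_id)
  assign1 <- function(ids) {
    n <- length(ids)
    ids <- sample(ids)
    nTrain <- round(fractions[1] * n)
    nVal <- round(fractions[2] * n)
    sp <- rep("test", n)
    sp[seq_len(nTrain)] <- "train"
    if (nVal > 0) sp[nTrain + seq_len(min(nVal, n - nTrain))] <- "val"
    setNames(sp, ids)
  }
  spl <- .withSeed(seed, {
    if (stratify) {
      lab <- m$label[match(pats, m$patient_id)]
      do.call(c, unname(lapply(split(pats, lab), assign1)))
    } else assign1(pats)
  })
  m$split <- unname(spl[as.character(m$patient_id)])
  cohort@manifest <- m
  validObject(cohort)
  cohort
}

## ---- Adam ---------------------------------------------------------------

.adamInit <- function() list(m = list(), v = list(), t = list())

## One Adam step over the parameters named in `grads`; untouched
## parameters (the unused surgery route) are not updated or decayed.
.adamStep <- function(params, grads, state, lr, wd,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gr <- grads[[nm]] + wd * params[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- gr * 0
      state$v[[nm]] <- gr * 0
      state$t[[nm]] <- 0L
    }
    state$t[[nm]] <- state$t[[nm]] + 1L
    t <- state$t[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.addGrads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

## ---- training -----------------------------------------------------------

## Gather per-slide tensors for a set of slide ids.
.slideData <- function(cohort, slideIds) {
  m <- cohort@manifest
  rows <- match(slideIds, m$slide_id)
  list(
    H = lapply(cohort@bags[slideIds], function(b) b@features),
    route = m$surgery_type[rows],
    patient = as.character(m$patient_id[rows]),
    label = as.integer(m$label[rows]),
    time = m$time[rows],
    event = as.integer(m$event[rows]),
    C = cohort@clinical[as.character(m$patient_id[rows]), , drop = FALSE]
  )
}

.dropMasks <- function(n, L, Fd, p) {
  if (p <= 0) return(list(hp = NULL, mf = NULL))
  list(hp = (matrix(runif(n * L), n, L) >= p) / (1 - p),
       mf = (runif(Fd) >= p) / (1 - p))
}

#' Train the gated-attention model on a split cohort
#'
#' Slide-level training (each slide is an optimisation example carrying
#' its patient's label), Adam with the task's default hyperparameters,
#' early stopping on the patient-level validation metric (AUC for
#' classification, Harrell C for survival), and -- for the survival task
#' -- minibatch Cox risk sets with a step learning-rate scheduler.
#' Patient-level aggregation is applied only when evaluating, never
#' inside the training loss.
#'
#' @param cohort a [MILCohort] with \code{split} assigned (see
#'   [splitCohort()]).
#' @param task \code{"classification"} or \code{"survival"}.
#' @param settings a [trainSettings()] list.
#' @param config optional [milConfig()]; defaults are derived from the
#'   cohort dimensions.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @param verbose print per-epoch progress.
#' @return a fitted [MILModel]; \code{trainingHistory()} gives per-epoch
#'   training loss and validation metric, and
#'   \code{attr(history, "bestEpoch")} the early-stopping optimum.
#' @export
trainModel <- function(cohort, task = c("classification", "survival"),
                       settings = NULL, config = NULL, seed = 0L,
                       verbose = FALSE) {
  task <- match.arg(task)
  if (is.null(settings)) settings <- trainSettings(task)
  stopifnot(settings$task == task)
  m <- cohort@manifest
  if (all(is.na(m$split))) stop("cohort has no split: call splitCohort() first")
  trainIds <- m$slide_id[m$split == "train"]
  valIds <- m$slide_id[m$split == "val"]
  if (!length(trainIds) || !length(valIds))
    stop("empty train or validation split")
  tr <- .slideData(cohort, trainIds)
  va <- .slideData(cohort, valIds)
  D <- ncol(tr$H[[1]])
  if (is.null(config))
    config <- milConfig(D, ncol(cohort@clinical), task)
  stopifnot(config$task == task)
  lambda <- if (task == "classification") settings$lambdaInst else 0

  res <- .withSeed(seed, {
    params <- .initParams(config)
    state <- .adamInit()
    best <- -Inf; bestParams <- params; bestEpoch <- 0L; since <- 0L
    hist <- data.frame()
    nTrain <- length(tr$H)
    for (epoch in seq_len(settings$maxEpochs)) {
      lrE <- settings$learningRate
      if (!is.null(settings$scheduler))
        lrE <- lrE * settings$scheduler$gamma ^
          ((epoch - 1L) %/% settings$scheduler$stepSize)
      ord <- sample.int(nTrain)
      epochLoss <- 0; nLoss <- 0L
      if (task == "classification") {
        for (i in ord) {
          H <- tr$H[[i]]
          dm <- .dropMasks(nrow(H), config$attentionHidden,
                           config$fusionDim, settings$dropout)
          fw <- .milForward(params, config, H, tr$C[i, ], tr$route[i],
                            dropHp = dm$hp, dropMf = dm$mf)
          y <- tr$label[i]
          onehot <- c(0, 0); onehot[y + 1L] <- 1
          lb <- -log(max(fw$probs[y + 1L], 1e-12))
          sel <- .instanceSelect(fw$alpha, y, config$kInstances)
          P <- .softmaxRows(fw$Si[sel$idx, , drop = FALSE])
          li <- -mean(log(pmax(P[cbind(seq_along(sel$idx),
                                       sel$pseudo + 1L)], 1e-12)))
          dSi <- matrix(0, nrow(H), 2L)
          tgt <- matrix(0, length(sel$idx), 2L)
          tgt[cbind(seq_along(sel$idx), sel$pseudo + 1L)] <- 1
          dSi[sel$idx, ] <- lambda * (P - tgt) / length(sel$idx)
          grads <- .milBackward(params, config, fw, H, tr$C[i, ],
                                tr$route[i], dlogits = fw$probs - onehot,
                                dSi = dSi)
          upd <- .adamStep(params, grads, state, lrE, settings$weightDecay)
          params <- upd$params; state <- upd$state
          epochLoss <- epochLoss + lb + lambda * li; nLoss <- nLoss + 1L
        }
      } else {
        batches <- split(ord, ceiling(seq_along(ord) / settings$batchSize))
        for (bidx in batches) {
          if (!any(tr$event[bidx] == 1L)) next
          fws <- vector("list", length(bidx))
          risks <- numeric(length(bidx))
          dms <- vector("list", length(bidx))
          for (j in seq_along(bidx)) {
            i <- bidx[j]
            dms[[j]] <- .dropMasks(nrow(tr$H[[i]]), config$attentionHidden,
                                   config$fusionDim, settings$dropout)
            fws[[j]] <- .milForward(params, config, tr$H[[i]], tr$C[i, ],
                                    tr$route[i], dropHp = dms[[j]]$hp,
                                    dropMf = dms[[j]]$mf)
            risks[j] <- fws[[j]]$logits[1]
          }
          loss <- coxLoss(risks, tr$time[bidx], tr$event[bidx])
          dr <- .coxLossGrad(risks, tr$time[bidx], tr$event[bidx])
          grads <- list()
          for (j in seq_along(bidx)) {
            i <- bidx[j]
            gj <- .milBackward(params, config, fws[[j]], tr$H[[i]],
                               tr$C[i, ], tr$route[i], dlogits = dr[j])
            grads <- .addGrads(grads, gj)
          }
          upd <- .adamStep(params, grads, state, lrE, settings$weightDecay)
          params <- upd$params; state <- upd$state
          epochLoss <- epochLoss + loss; nLoss <- nLoss + 1L
        }
      }
      trainLoss <- if (nLoss) epochLoss / nLoss else NA_real_
      if (!is.finite(trainLoss))
        stop(sprintf("non-finite training loss at epoch %d", epoch))
      valMetric <- .valMetric(params, config, va, task, settings$aggregate)
      improved <- isTRUE(valMetric > best + 1e-8)
      if (improved) {
        best <- valMetric; bestParams <- params
        bestEpoch <- epoch; since <- 0L
      } else since <- min(since + 1L, settings$patience)
      hist <- rbind(hist, data.frame(
        epoch = epoch, trainLoss = trainLoss, valMetric = valMetric,
        lr = lrE, epochsSinceImprovement = since))
      if (verbose)
        message(sprintf("epoch %d  loss %.4f  val %.4f%s", epoch,
                        trainLoss, valMetric, if (improved) " *" else ""))
      if (since >= settings$patience && epoch >= settings$minEpochs) break
    }
    list(params = bestParams, hist = hist, bestEpoch = bestEpoch)
  })
  attr(res$hist, "bestEpoch") <- res$bestEpoch
  cfg <- config
  cfg$trainSettings <- settings
  new("MILModel", config = cfg, params = res$params, task = task,
      history = res$hist)
}

## Patient-level validation metric from slide-level scores.
.valMetric <- function(params, config, sd, task, aggregate) {
  scores <- vapply(seq_along(sd$H), function(i) {
    fw <- .milForward(params, config, sd$H[[i]], sd$C[i, ], sd$route[i])
    if (task == "classification") fw$probs[2] else fw$logits[1]
  }, numeric(1))
  agg <- tapply(scores, sd$patient, function(x)
    if (aggregate == "median") median(x) else mean(x))
  pats <- names(agg)
  first <- match(pats, sd$patient)
  if (task == "classification") {
    lab <- sd$label[first]
    if (length(unique(lab)) < 2L) return(NA_real_)
    .aucFast(as.numeric(agg), lab)
  } else {
    .cindexFast(as.numeric(agg), sd$time[first], sd$event[first])
  }
}

#' Patient-level aggregation of slide scores
#'
#' Consolidates per-slide prediction scores (class probabilities or risk
#' scores) into a single patient-level value by mean or median (the
#' median of an even count is the midpoint of the two central values).
#'
#' @param slideScores numeric vector of slide-level scores (at least 1).
#' @param method \code{"mean"} or \code{"median"}.
#' @return list with \code{slideScores}, \code{aggregate}, \code{method}.
#' @export
aggregatePatient <- function(slideScores, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!length(slideScores)) stop("no slide scores to aggregate")
  agg <- if (method == "mean") mean(slideScores) else median(slideScores)
  list(slideScores = slideScores, aggregate = agg, method = method)
}

#' Patient-level predictions for a cohort
#'
#' Runs the fitted model over every slide of the requested split and
#' aggregates slide scores per patient.
#'
#' @param model a fitted [MILModel].
#' @param cohort a [MILCohort].
#' @param split restrict to one split (\code{"train"}, \code{"val"},
#'   \code{"test"}); NULL = all slides.
#' @param aggregate \code{"mean"} or \code{"median"}.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{score}, \code{nSlides}, \code{label}, \code{time},
#'   \code{event}, \code{split}.
#' @export
predictCohort <- function(model, cohort, split = NULL,
                          aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  m <- cohort@manifest
  ids <- if (is.null(split)) m$slide_id else m$slide_id[m$split %in% split]
  if (!length(ids)) stop("no slides in the requested split")
  sd <- .slideData(cohort, ids)
  scores <- vapply(seq_along(sd$H), function(i) {
    fw <- .milForward(model@params, model@config, sd$H[[i]], sd$C[i, ],
                      sd$route[i])
    if (model@task == "classification") fw$probs[2] else fw$logits[1]
  }, numeric(1))
  pats <- unique(sd$patient)
  out <- do.call(rbind, lapply(pats, function(p) {
    sl <- which(sd$patient == p)
    data.frame(patient_id = p,
               score = aggregatePatient(scores[sl], aggregate)$aggregate,
               nSlides = length(sl),
               label = sd$label[sl[1]], time = sd$time[sl[1]],
               event = sd$event[sl[1]],
               split = m$split[match(p, m$patient_id)])
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate a fitted model on one split
#'
#' Classification: patient-level ROC-AUC plus confusion-matrix metrics
#' at the given threshold. Survival: Harrell C-index plus IPCW
#' time-dependent AUC at the requested horizons.
#'
#' @inheritParams predictCohort
#' @param threshold classification decision threshold.
#' @param horizons time horizons (months) for the time-dependent AUC.
#' @param nBoot bootstrap resamples for CIs (0 = none).
#' @param seed bootstrap seed.
#' @return named list of metrics.
#' @export
evaluateCohort <- function(model, cohort, split = "test",
                           aggregate = c("mean", "median"),
                           threshold = 0.5, horizons = NULL,
                           nBoot = 0L, seed = 1L) {
  aggregate <- match.arg(aggregate)
  pred <- predictCohort(model, cohort, split = split, aggregate = aggregate)
  if (model@task == "classification") {
    auc <- tryCatch(rocAUC(pred$score, pred$label, nBoot = nBoot,
                           seed = seed),
                    error = function(e)
                      list(point = NA_real_, ciLow = NA_real_,
                           ciHigh = NA_real_))
    c(list(auc = auc$point, aucCiLow = auc$ciLow, aucCiHigh = auc$ciHigh,
           n = nrow(pred)),
      thresholdMetrics(pred$score, pred$label, threshold))
  } else {
    cc <- harrellC(pred$score, pred$time, pred$event, nBoot = nBoot,
                   seed = seed)
    out <- list(cindex = cc$point, cindexCiLow = cc$ciLow,
                cindexCiHigh = cc$ciHigh, n = nrow(pred))
    for (h in horizons)
      out[[sprintf("tdAUC_%g", h)]] <- tryCatch(
        timeDependentAUC(pred$score, pred$time, pred$event, h)$point,
        error = function(e) NA_real_)
    out
  }
}

#' Repeated training trials over seeds
#'
#' Runs [trainModel()] once per seed and summarises the evaluation
#' metric across trials as mean with a normal-approximation 95% CI.
#'
#' @inheritParams trainModel
#' @param seeds integer seeds, one trial each (default 0:9).
#' @param evalSplit split on which the metric is computed.
#' @param aggregate patient-level aggregation method.
#' @return list with \code{values} (per-seed metric) and \code{summary}
#'   (from [trialsSummary()]).
#' @export
runTrials <- function(cohort, task = c("classification", "survival"),
                      seeds = 0:9, settings = NULL, config = NULL,
                      evalSplit = "test", aggregate = "mean") {
  task <- match.arg(task)
  values <- vapply(seeds, function(s) {
    fit <- trainModel(cohort, task, settings = settings, config = config,
                      seed = s)
    ev <- evaluateCohort(fit, cohort, split = evalSplit,
                         aggregate = aggregate)
    if (task == "classification") ev$auc else ev$cindex
  }, numeric(1))
  list(values = setNames(values, seeds), summary = trialsSummary(values))
}
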