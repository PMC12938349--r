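## Evaluation statistics: discrimination metrics, survival estimates,
## risk stratification, baseline-table tests and multi-trial summaries.

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, with score ties counted 1/2
#' (equivalent to the trapezoidal ROC area). An optional bootstrap
#' resamples subjects with replacement for a percentile 95% CI.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 class labels; both classes must be present.
#' @param nBoot bootstrap resamples for the CI (0 = point estimate only).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{point}, \code{ciLow}, \code{ciHigh}, \code{n}.
#' @export
rocAUC <- function(scores, labels, nBoot = 0L, seed = 1L) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC is undefined: only one class present")
  point <- .aucFast(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    ci <- .withSeed(seed, {
      n <- length(scores)
      v <- vapply(seq_len(nBoot), function(b) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (length(unique(labels[idx])) == 2L)
            return(.aucFast(scores[idx], labels[idx]))
        }
      }, numeric(1))
      unname(quantile(v, c(0.025, 0.975), type = 7))
    })
  }
  list(point = point, ciLow = ci[1], ciHigh = ci[2], n = length(scores))
}

## Wilcoxon-statistic AUC; midranks give the 1/2-tie convention exactly.
.aucFast <- function(scores, labels) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Evaluate an expression under a temporary RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Subjects with \code{scores > threshold} are called positive (class 1).
#'
#' @inheritParams rocAUC
#' @param threshold decision threshold in (0, 1); default 0.5.
#' @return list with \code{precision}, \code{recall}, \code{f1},
#'   \code{specificity}.
#' @export
thresholdMetrics <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("no predictions supplied")
  stopifnot(threshold > 0, threshold < 1)
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(precision + recall > 0)) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  list(precision = precision, recall = recall, f1 = f1,
       specificity = specificity)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted risks order
#' concordantly with their outcomes. A pair is comparable when the
#' subject with the shorter time had an event, or when the times are
#' tied and exactly one subject had an event (the censored subject is
#' known to outlive the other). Risk ties score 1/2.
#'
#' @param risks numeric risk scores (higher = worse prognosis).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param nBoot,seed optional bootstrap 95% CI as in [rocAUC()].
#' @return list with \code{point}, \code{ciLow}, \code{ciHigh}, \code{n}.
#' @export
harrellC <- function(risks, time, event, nBoot = 0L, seed = 1L) {
  stopifnot(length(risks) == length(time), length(time) == length(event),
            all(time > 0))
  point <- .cindexFast(risks, time, as.integer(event))
  if (is.na(point)) stop("C-index is undefined: no comparable pairs")
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0L) {
    ci <- .withSeed(seed, {
      n <- length(risks)
      v <- vapply(seq_len(nBoot), function(b) {
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          ci <- .cindexFast(risks[idx], time[idx], as.integer(event[idx]))
          if (!is.na(ci)) return(ci)
        }
      }, numeric(1))
      unname(quantile(v, c(0.025, 0.975), type = 7))
    })
  }
  list(point = point, ciLow = ci[1], ciHigh = ci[2], n = length(risks))
}

## Vectorised pairwise concordance (O(n^2) memory; cohorts here are small).
.cindexFast <- function(risks, time, event) {
  dt <- outer(time, time, "<")           # [i,j]: t_i < t_j
  ev <- matrix(event == 1L, length(time), length(time))
  tie <- outer(time, time, "==")
  ## i earlier with event, or tied time with i the (sole) event subject
  usable <- (dt & ev) | (tie & ev & !t(ev))
  diag(usable) <- FALSE
  if (!any(usable)) return(NA_real_)
  dr <- outer(risks, risks, "-")
  conc <- sum(usable & dr > 0) + 0.5 * sum(usable & dr == 0)
  conc / sum(usable)
}

#' IPCW time-dependent AUC (cumulative/dynamic)
#'
#' Discrimination at horizon \code{tau} between subjects with an event
#' by \code{tau} (cases) and subjects still at risk beyond \code{tau}
#' (controls), reweighted by the inverse probability of censoring
#' estimated from the Kaplan-Meier curve of the censoring distribution.
#' With no censoring the weights collapse to 1 and the estimate equals
#' the plain ROC-AUC of risk against the event-by-tau indicator.
#'
#' @inheritParams harrellC
#' @param tau evaluation horizon (same units as \code{time}).
#' @return list with \code{point}, \code{n} (cases + controls used).
#' @export
timeDependentAUC <- function(risks, time, event, tau) {
  stopifnot(length(risks) == length(time), length(time) == length(event))
  event <- as.integer(event)
  cases <- which(time <= tau & event == 1L)
  controls <- which(time > tau)
  if (!length(cases)) stop("time-dependent AUC undefined: no events by tau")
  if (!length(controls)) stop("time-dependent AUC undefined: no one at risk past tau")
  G <- .censoringKM(time, event)
  wi <- 1 / vapply(time[cases], function(t) G(t, left = TRUE), numeric(1))
  wj <- rep(1 / G(tau, left = FALSE), length(controls))
  dr <- outer(risks[cases], risks[controls], "-")
  W <- outer(wi, wj)
  num <- sum(W * ((dr > 0) + 0.5 * (dr == 0)))
  list(point = num / sum(W), n = length(cases) + length(controls))
}

## KM estimator of the censoring survival function G(t); returns an
## evaluator with optional left limit G(t-).
.censoringKM <- function(time, event) {
  cens <- 1L - event
  ot <- sort(unique(time[cens == 1L]))
  if (!length(ot)) return(function(t, left = FALSE) 1)
  atRisk <- vapply(ot, function(u) sum(time >= u), numeric(1))
  d <- vapply(ot, function(u) sum(time == u & cens == 1L), numeric(1))
  surv <- cumprod(1 - d / atRisk)
  function(t, left = FALSE) {
    idx <- if (left) which(ot < t) else which(ot <= t)
    if (!length(idx)) 1 else surv[max(idx)]
  }
}

#' Kaplan-Meier estimate with median and fixed-horizon survival
#'
#' Product-limit estimator via [survival::survfit()] with Greenwood
#' variance and log-log confidence bands. The median is the earliest
#' time with \eqn{\hat S(t) \le 0.5} (NA, "not reached", if the curve
#' never drops that far); its CI inverts the log-log band in the same
#' way.
#'
#' @inheritParams harrellC
#' @param horizons optional times at which to report survival rates.
#' @return list with \code{curve} (data.frame: time, nRisk, nEvent,
#'   nCensor, surv, lower, upper), \code{median}, \code{medianCI}, and
#'   \code{horizons} (data.frame with survival and CI per horizon).
#' @export
kmEstimate <- function(time, event, horizons = NULL) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  curve <- data.frame(
    time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
    nCensor = fit$n.censor, surv = fit$surv,
    lower = ifelse(is.na(fit$lower), NA_real_, fit$lower),
    upper = ifelse(is.na(fit$upper), NA_real_, fit$upper)
  )
  firstBelow <- function(s) {
    i <- which(!is.na(s) & s <= 0.5)
    if (length(i)) curve$time[min(i)] else NA_real_
  }
  med <- firstBelow(curve$surv)
  medCI <- c(firstBelow(curve$upper), firstBelow(curve$lower))
  hz <- NULL
  if (!is.null(horizons)) {
    sm <- summary(fit, times = horizons, extend = TRUE)
    hz <- data.frame(time = sm$time, surv = sm$surv,
                     lower = sm$lower, upper = sm$upper)
  }
  list(curve = curve, median = med, medianCI = medCI, horizons = hz)
}

#' Tertile risk stratification
#'
#' \code{tertileStratify} computes the 1/3 and 2/3 empirical quantiles
#' (linear interpolation, quantile type 7) of the training risk scores;
#' the thresholds are then frozen and applied unchanged to any other
#' scores with \code{assignRiskGroup}: score \eqn{\le q_1} is low risk,
#' \eqn{q_1 <} score \eqn{\le q_2} intermediate, above \eqn{q_2} high.
#'
#' @param trainScores numeric training-set risk scores (at least 3
#'   distinct values).
#' @return list with \code{q1}, \code{q2}.
#' @export
tertileStratify <- function(trainScores) {
  if (length(unique(trainScores)) < 3L)
    stop("degenerate stratification: fewer than 3 distinct training scores")
  q <- unname(quantile(trainScores, c(1 / 3, 2 / 3), type = 7))
  list(q1 = q[1], q2 = q[2])
}

#' @rdname tertileStratify
#' @param scores scores to assign.
#' @param thresholds result of \code{tertileStratify}.
#' @return \code{assignRiskGroup}: factor with levels low, intermediate,
#'   high.
#' @export
assignRiskGroup <- function(scores, thresholds) {
  g <- ifelse(scores <= thresholds$q1, "low",
              ifelse(scores <= thresholds$q2, "intermediate", "high"))
  factor(g, levels = c("low", "intermediate", "high"))
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square on an r x c contingency table, no continuity
#' correction; expected counts from the margins; p from the upper tail
#' of the chi-square distribution with (r-1)(c-1) df.
#'
#' @param counts non-negative integer matrix, at least 2 x 2.
#' @return list with \code{statistic}, \code{df}, \code{p}.
#' @export
chiSquareIndependence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with a positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("table has an all-zero margin")
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with p from the chi-square distribution on
#' k - 1 df. If every value is identical the test is vacuous and (H = 0,
#' p = 1) is returned with a warning.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!lengths(groups))) stop("all groups must be non-empty")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L) {
    warning("all values identical: zero-variance Kruskal-Wallis test")
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  ht <- kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bootstrap comparison of two models' metrics on the same patients
#'
#' Patient-level resampling with replacement; on each resample the
#' metric is computed for both prediction sets and the difference
#' recorded. Reports the observed difference, the percentile 95% CI of
#' the bootstrap differences, and the two-sided bootstrap p-value
#' \eqn{2 \min(P(\Delta^* \le 0), P(\Delta^* \ge 0))} capped at 1.
#' Resamples on which the metric is undefined (e.g. one class only) are
#' redrawn, up to 10% of \code{nBoot}.
#'
#' @param metric \code{"auc"} or \code{"cindex"}.
#' @param scoresA,scoresB paired predictions for the same subjects.
#' @param labels 0/1 labels (for \code{"auc"}).
#' @param time,event survival outcome (for \code{"cindex"}).
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return list with \code{delta}, \code{ciLow}, \code{ciHigh}, \code{p},
#'   \code{nBoot}, \code{nRedraws}.
#' @export
bootstrapCompare <- function(metric = c("auc", "cindex"), scoresA, scoresB,
                             labels = NULL, time = NULL, event = NULL,
                             nBoot = 1000L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(scoresA) == length(scoresB))
  eval1 <- function(scores, idx) {
    if (metric == "auc") {
      if (length(unique(labels[idx])) < 2L) return(NA_real_)
      .aucFast(scores[idx], as.integer(labels[idx]))
    } else {
      .cindexFast(scores[idx], time[idx], as.integer(event[idx]))
    }
  }
  n <- length(scoresA)
  full <- seq_len(n)
  delta <- eval1(scoresA, full) - eval1(scoresB, full)
  maxRedraw <- ceiling(0.1 * nBoot)
  res <- .withSeed(seed, {
    redraws <- 0L
    d <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        a <- eval1(scoresA, idx); bb <- eval1(scoresB, idx)
        if (!is.na(a) && !is.na(bb)) { d[b] <- a - bb; break }
        redraws <- redraws + 1L
        if (redraws > maxRedraw)
          stop("metric undefined on too many bootstrap resamples")
      }
    }
    list(d = d, redraws = redraws)
  })
  ci <- unname(quantile(res$d, c(0.025, 0.975), type = 7))
  p <- min(1, 2 * min(mean(res$d <= 0), mean(res$d >= 0)))
  list(delta = delta, ciLow = ci[1], ciHigh = ci[2], p = p,
       nBoot = nBoot, nRedraws = res$redraws)
}

#' Summary of a metric over repeated training trials
#'
#' Mean with normal-approximation 95% CI
#' (\eqn{\bar x \pm 1.96\, s/\sqrt n}) across independently seeded
#' training runs.
#'
#' @param values metric values, one per trial (at least 2).
#' @return list with \code{point}, \code{ciLow}, \code{ciHigh}, \code{n}.
#' @export
trialsSummary <- function(values) {
  if (length(values) < 2L) stop("at least two trials are required")
  m <- mean(values)
  hw <- 1.96 * sd(values) / sqrt(length(values))
  list(point = m, ciLow = m - hw, ciHigh = m + hw, n = length(values))
}

#' Baseline characteristics table with per-variable tests
#'
#' Builds a cohort-characteristics table across splits: categorical
#' variables are summarised as counts (%) and compared with the Pearson
#' chi-square test; continuous variables as median [IQR] with the
#' Kruskal-Wallis test.
#'
#' @param data patient-level data.frame.
#' @param splitCol name of the split column.
#' @param categorical,continuous character vectors of variable names.
#' @return data.frame with one row per variable: name, type, per-split
#'   summary, test name, p-value.
#' @export
baselineTable <- function(data, splitCol = "split",
                          categorical = character(),
                          continuous = character()) {
  stopifnot(splitCol %in% names(data))
  sp <- factor(data[[splitCol]])
  rows <- list()
  for (v in categorical) {
    tab <- table(data[[v]], sp)
    ct <- chiSquareIndependence(as.matrix(tab))
    summ <- paste(vapply(levels(sp), function(s) {
      cnt <- tab[, s]
      paste0(s, ": ", paste(sprintf("%s=%d", rownames(tab), cnt),
                            collapse = "/"))
    }, character(1)), collapse = "; ")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "categorical", summary = summ,
      test = "chi-square", p = ct$p)
  }
  for (v in continuous) {
    groups <- split(data[[v]], sp)
    kt <- kruskalWallis(groups)
    summ <- paste(vapply(levels(sp), function(s) {
      x <- groups[[s]]
      sprintf("%s: %.3g [%.3g; %.3g]", s, median(x),
              quantile(x, 0.25), quantile(x, 0.75))
    }, character(1)), collapse = "; ")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, type = "continuous", summary = summ,
      test = "kruskal-wallis", p = kt$p)
  }
  do.call(rbind, rows)
}
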