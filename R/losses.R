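## Loss functions: bag cross-entropy, instance clustering loss, combined
## classification objective, and the Cox partial-likelihood survival loss.

#' Bag-level cross-entropy loss
#'
#' Negative log-probability of the true slide label under the predicted
#' class distribution. Probabilities are clamped at 1e-12 (with a
#' warning) to keep the loss finite.
#'
#' @param classProbs length-2 probability vector (sums to 1).
#' @param label true class, 0 or 1.
#' @return scalar loss.
#' @export
bagLoss <- function(classProbs, label) {
  stopifnot(length(classProbs) == 2L, label %in% c(0, 1))
  p <- classProbs[label + 1L]
  if (p < 1e-12) {
    warning("true-class probability clamped at 1e-12")
    p <- 1e-12
  }
  -log(p)
}

#' Instance-level clustering loss
#'
#' Attention-guided pseudo-labelling in the CLAM style: instances are
#' ranked by attention weight; the top-k inherit the bag label as a
#' pseudo-label and the bottom-k the complementary label; the loss is
#' the mean cross-entropy of the instance scores against those
#' pseudo-labels over the 2k selected instances. When N < 2k, k is
#' reduced to floor(N/2) (minimum 1); a single-instance bag uses that
#' instance with the bag label only.
#'
#' @param alpha attention weights (length N, non-negative, sums to 1).
#' @param instScores N x 2 matrix of instance class scores (logits).
#' @param bagLabel bag label, 0 or 1.
#' @param k instances selected per side.
#' @return scalar loss.
#' @export
instanceLoss <- function(alpha, instScores, bagLabel, k = 8L) {
  instScores <- rbind(instScores)
  n <- length(alpha)
  stopifnot(nrow(instScores) == n, ncol(instScores) == 2L,
            bagLabel %in% c(0, 1), k >= 1L)
  sel <- .instanceSelect(alpha, bagLabel, k)
  ce <- -.logSoftmax(instScores[sel$idx, , drop = FALSE])
  mean(ce[cbind(seq_along(sel$idx), sel$pseudo + 1L)])
}

## Shared selection rule so the training gradient and the public loss
## agree exactly. Returns selected row indices and pseudo-labels.
.instanceSelect <- function(alpha, bagLabel, k) {
  n <- length(alpha)
  if (n == 1L) return(list(idx = 1L, pseudo = as.integer(bagLabel)))
  k <- max(1L, min(as.integer(k), n %/% 2L))
  ord <- order(alpha, decreasing = TRUE)
  top <- ord[seq_len(k)]
  bottom <- rev(ord)[seq_len(k)]
  list(idx = c(top, bottom),
       pseudo = c(rep(as.integer(bagLabel), k),
                  rep(1L - as.integer(bagLabel), k)))
}

.logSoftmax <- function(x) {
  x <- rbind(x)
  m <- apply(x, 1L, max)
  x - m - log(rowSums(exp(x - m)))
}

.softmaxRows <- function(x) exp(.logSoftmax(x))

#' Combined classification objective
#'
#' \eqn{L_{total} = L_{bag} + \lambda L_{inst}} with \eqn{\lambda = 0.9}
#' by default.
#'
#' @param bagLossValue,instanceLossValue scalar component losses.
#' @param lambda weight on the instance clustering loss (>= 0).
#' @return scalar loss.
#' @export
totalClassificationLoss <- function(bagLossValue, instanceLossValue,
                                    lambda = 0.9) {
  stopifnot(lambda >= 0)
  bagLossValue + lambda * instanceLossValue
}

#' Cox partial-likelihood loss
#'
#' Negative mean partial log-likelihood over a batch of B subjects,
#' \deqn{L = -\frac{1}{B}\sum_i \delta_i \Big[\hat r_i -
#'   \log \sum_{j: t_j \ge t_i} \exp(\hat r_j)\Big],}
#' with risk sets formed within the batch and subjects tied on time
#' included in each other's risk sets (the Breslow convention implied by
#' \eqn{t_j \ge t_i}). With no events in the batch the empty sum gives 0
#' (reported with a warning).
#'
#' @param risks predicted risk scores over the batch.
#' @param time positive survival times.
#' @param event 0/1 event indicators.
#' @return scalar loss.
#' @export
coxLoss <- function(risks, time, event) {
  stopifnot(length(risks) >= 1L, length(risks) == length(time),
            length(time) == length(event), all(time > 0))
  event <- as.integer(event)
  if (!any(event == 1L)) {
    warning("no events in batch: Cox loss is 0")
    return(0)
  }
  B <- length(risks)
  m <- max(risks)
  ll <- 0
  for (i in which(event == 1L)) {
    rs <- risks[time >= time[i]]
    ll <- ll + risks[i] - (m + log(sum(exp(rs - m))))
  }
  -ll / B
}

## Gradient of coxLoss w.r.t. each risk:
## dL/dr_j = -(1/B) [ delta_j - exp(r_j) * sum_{i events: t_j >= t_i}
##                    1 / sum_{l: t_l >= t_i} exp(r_l) ]
.coxLossGrad <- function(risks, time, event) {
  event <- as.integer(event)
  B <- length(risks)
  g <- numeric(B)
  if (!any(event == 1L)) return(g)
  m <- max(risks)
  er <- exp(risks - m)
  for (i in which(event == 1L)) {
    inset <- time >= time[i]
    denom <- sum(er[inset])
    g[inset] <- g[inset] + er[inset] / denom
    g[i] <- g[i] - 1
  }
  g / B
}
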