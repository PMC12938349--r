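## Independent brute-force oracles used across the suite. Each one is
## deliberately written as plain enumeration, not sharing code with the
## implementation it checks.

## AUC as the explicit pairwise probability over all positive-negative
## pairs, ties counted 1/2.
oracleAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## Harrell C by explicit double loop over ordered pairs.
oracleCindex <- function(risks, time, event) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (risks[i] > risks[j]) num <- num + 1
    else if (risks[i] == risks[j]) num <- num + 0.5
  }
  if (den == 0) NA_real_ else num / den
}

## Negative mean Cox partial log-likelihood by direct risk-set
## enumeration (no max-shift, explicit which()).
oracleCoxLoss <- function(risks, time, event) {
  B <- length(risks)
  total <- 0
  for (i in seq_len(B)) {
    if (event[i] != 1) next
    rs <- which(time >= time[i])
    total <- total + risks[i] - log(sum(exp(risks[rs])))
  }
  -total / B
}

## Tiny deterministic bag for model tests.
makeBag <- function(n = 10L, d = 8L, seed = 1L) {
  set.seed(seed)
  new("FeatureBag",
      features = matrix(rnorm(n * d), n, d),
      coords = cbind(x = seq_len(n) - 1L, y = rep(0L, n)),
      slideId = "S1", patientId = "P1", site = "primary",
      encoderName = "test")
}

## Small synthetic cohort for training smoke tests (fast settings).
smallCohort <- function(seed = 0L, nPatients = 30L) {
  splitCohort(simulateCohort(simSettings(
    nPatients = nPatients, dim = 16L, bagSizeRange = c(10L, 25L),
    seed = seed)), seed = seed)
}

fastSettings <- function(task, ...) {
  trainSettings(task, maxEpochs = 6L, minEpochs = 2L, patience = 2L, ...)
}
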