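test_that("rocAUC matches the pairwise-probability definition", {
  expect_equal(rocAUC(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$point, 0.75)
  expect_equal(rocAUC(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$point, 1.0)
  expect_equal(rocAUC(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$point, 0.5)
  expect_error(rocAUC(1:3, c(1, 1, 1)), "one class")
  set.seed(11)
  for (rep in 1:150) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(rocAUC(scores, labels)$point, oracleAUC(scores, labels))
  }
})

test_that("rocAUC bootstrap CI brackets the point estimate and is seeded", {
  set.seed(3)
  sc <- runif(60); lab <- rbinom(60, 1, 0.5 + 0.3 * (sc > 0.5))
  a1 <- rocAUC(sc, lab, nBoot = 200, seed = 5)
  a2 <- rocAUC(sc, lab, nBoot = 200, seed = 5)
  expect_identical(a1, a2)
  expect_lte(a1$ciLow, a1$point)
  expect_gte(a1$ciHigh, a1$point)
})

test_that("threshold metrics are the standard confusion-matrix ratios", {
  ## fixture with TP=3, FP=1, FN=1, TN=5 at threshold 0.5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.2, 0.1, 0.1)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- thresholdMetrics(scores, labels, 0.5)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$specificity, 5 / 6)
  ## everyone called positive at prevalence 0.6
  m2 <- thresholdMetrics(rep(0.9, 10), c(rep(1, 6), rep(0, 4)), 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$specificity, 0)
  expect_equal(m2$precision, 0.6)
  ## perfect classifier
  m3 <- thresholdMetrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(m3), c(precision = 1, recall = 1, f1 = 1,
                             specificity = 1))
})

test_that("harrellC equals the O(n^2) pairwise oracle on censored data", {
  expect_equal(harrellC(c(5, 4, 3, 2, 1), 1:5, rep(1, 5))$point, 1.0)
  expect_equal(harrellC(rep(2, 5), 1:5, rep(1, 5))$point, 0.5)
  set.seed(22)
  for (rep in 1:150) {
    n <- sample(4:40, 1)
    risks <- sample(seq(-2, 2, by = 0.25), n, replace = TRUE)
    time <- sample(1:15, n, replace = TRUE)
    event <- c(1, rbinom(n - 1, 1, 0.6))
    ref <- oracleCindex(risks, time, event)
    if (is.na(ref)) {
      expect_error(harrellC(risks, time, event), "no comparable pairs")
    } else {
      expect_equal(harrellC(risks, time, event)$point, ref)
    }
  }
})

test_that("harrellC agrees with survival::concordance and is antisymmetric", {
  set.seed(9)
  for (rep in 1:20) {
    n <- 40
    risks <- rnorm(n)
    time <- sample(seq_len(1000), n)        # tie-free times
    event <- c(1, rbinom(n - 1, 1, 0.6))
    mine <- harrellC(risks, time, event)$point
    ref <- survival::concordance(
      survival::Surv(time, event) ~ risks, reverse = TRUE)$concordance
    expect_equal(mine, unname(ref), tolerance = 1e-12)
    expect_equal(harrellC(-risks, time, event)$point, 1 - mine,
                 tolerance = 1e-12)
  }
})

test_that("time-dependent AUC handles censoring weights correctly", {
  ## perfect inverse ordering, no censoring
  time <- 1:20
  expect_equal(timeDependentAUC(-(1:20), time, rep(1, 20), 10.5)$point, 1.0)
  ## no censoring: collapses to the plain ROC-AUC of the event indicator
  set.seed(4)
  n <- 60
  risks <- rnorm(n); tm <- rexp(n, 0.1)
  tau <- median(tm)
  expect_equal(timeDependentAUC(risks, tm, rep(1, n), tau)$point,
               rocAUC(risks, as.integer(tm <= tau))$point)
  ## uninformative risks: near 0.5 at large n (averaged over replicates
  ## to keep the Monte Carlo error well below the tolerance)
  set.seed(5)
  a <- mean(replicate(4, {
    n <- 2000
    tm <- rexp(n, 0.08); cs <- rexp(n, 0.03)
    time2 <- pmin(tm, cs); ev <- as.integer(tm <= cs)
    timeDependentAUC(rnorm(n), time2, ev, 12)$point
  }))
  expect_lt(abs(a - 0.5), 0.03)
  expect_error(timeDependentAUC(1:3, c(5, 6, 7), c(0, 1, 1), 2),
               "no events")
})

test_that("Kaplan-Meier estimate matches hand-computed product limits", {
  ## no censoring: empirical survival, median at the first S <= 0.5
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  ## all censored: flat at 1, median not reached
  km2 <- kmEstimate(c(3, 5, 8), c(0, 0, 0))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))
  ## textbook 6-subject fixture with interleaved censoring:
  ## times 6, 7+, 10, 15, 19+, 25 -> S = 5/6, 5/6*3/4, * 2/3, * 1
  km3 <- kmEstimate(c(6, 7, 10, 15, 19, 25), c(1, 0, 1, 1, 0, 1))
  ev <- km3$curve[km3$curve$nEvent > 0, ]
  expect_equal(ev$surv,
               c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0))
  ## horizon survival at t = 12 equals the current step value
  km4 <- kmEstimate(c(6, 7, 10, 15, 19, 25), c(1, 0, 1, 1, 0, 1),
                    horizons = 12)
  expect_equal(km4$horizons$surv, 5 / 6 * 3 / 4)
  ## property: no censoring => empirical survival at every event time
  set.seed(6)
  tm <- sample(1:30, 15, replace = TRUE)
  km5 <- kmEstimate(tm, rep(1, 15))
  expect_equal(km5$curve$surv,
               vapply(km5$curve$time, function(u) mean(tm > u), numeric(1)))
})

test_that("tertile stratification freezes interpolated training quantiles", {
  thr <- tertileStratify(1:9)
  expect_equal(thr$q1, 11 / 3, tolerance = 1e-12)
  expect_equal(thr$q2, 19 / 3, tolerance = 1e-12)
  g <- assignRiskGroup(1:9, thr)
  expect_equal(as.integer(table(g)), c(3L, 3L, 3L))
  ## scores below the training range land in the low group
  expect_equal(as.character(assignRiskGroup(-5, thr)), "low")
  ## group sizes differ by <= 1 for distinct scores, n divisible by 3
  set.seed(7)
  for (rep in 1:20) {
    x <- sample(seq_len(1000), 3 * sample(3:30, 1))
    tab <- table(assignRiskGroup(x, tertileStratify(x)))
    expect_lte(diff(range(tab)), 1)
  }
  ## invariance to monotone rescaling
  x <- rnorm(60)
  g1 <- assignRiskGroup(x, tertileStratify(x))
  y <- exp(2 * x + 1)
  g2 <- assignRiskGroup(y, tertileStratify(y))
  expect_identical(g1, g2)
  expect_error(tertileStratify(c(1, 1, 2)), "degenerate")
})

test_that("chi-square independence test reproduces closed-form cases", {
  ct <- chiSquareIndependence(rbind(c(10, 0), c(0, 10)))
  expect_equal(ct$statistic, 20)
  expect_equal(ct$df, 1)
  expect_equal(ct$p, 7.744216e-06, tolerance = 1e-6)
  ## proportional table: statistic 0, p 1
  ct2 <- chiSquareIndependence(rbind(c(10, 20), c(30, 60)))
  expect_equal(ct2$statistic, 0)
  expect_equal(ct2$p, 1)
  expect_error(chiSquareIndependence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Kruskal-Wallis test matches rank arithmetic and holds its size", {
  kt <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kt$H, 27 / 7, tolerance = 1e-12)   # tie-free formula
  expect_equal(kt$p, 0.04953461, tolerance = 1e-6)
  kt2 <- kruskalWallis(list(c(1, 2), c(1, 2)))
  expect_equal(kt2$H, 0)
  expect_equal(kt2$p, 1)
  expect_warning(kruskalWallis(list(c(2, 2), c(2, 2))), "identical")
  ## type-I error near nominal 0.05 under the null
  set.seed(8)
  rej <- mean(replicate(600, {
    kruskalWallis(list(rnorm(40), rnorm(40), rnorm(40)))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.03)
})

test_that("bootstrap comparison is calibrated and deterministic", {
  set.seed(10)
  lab <- rbinom(100, 1, 0.5)
  sc <- runif(100)
  same <- bootstrapCompare("auc", sc, sc, labels = lab, nBoot = 300,
                           seed = 2)
  expect_equal(same$delta, 0)
  expect_gte(same$p, 0.99)
  scB <- runif(100)
  r1 <- bootstrapCompare("auc", sc, scB, labels = lab, nBoot = 300,
                         seed = 2)
  r2 <- bootstrapCompare("auc", sc, scB, labels = lab, nBoot = 300,
                         seed = 2)
  expect_identical(r1, r2)
  ## perfect vs random classifier: decisively significant
  set.seed(12)
  lab2 <- rbinom(200, 1, 0.5)
  perfect <- lab2 + runif(200, 0, 0.1)
  random <- runif(200)
  cmp <- bootstrapCompare("auc", perfect, random, labels = lab2,
                          nBoot = 1000, seed = 3)
  expect_lt(cmp$p, 0.01)
  expect_gt(cmp$ciLow, 0)
})

test_that("trial summaries use the normal-approximation CI", {
  s <- trialsSummary(rep(0.8, 10))
  expect_equal(c(s$point, s$ciLow, s$ciHigh), c(0.8, 0.8, 0.8))
  s2 <- trialsSummary(c(0.7, 0.9))
  expect_equal(s2$point, 0.8)
  expect_equal(s2$ciHigh - s2$point, 1.96 * sd(c(0.7, 0.9)) / sqrt(2))
  expect_error(trialsSummary(0.5), "two trials")
  ## CI width shrinks like 1/sqrt(n)
  set.seed(13)
  v <- rnorm(400, 0.8, 0.05)
  w1 <- with(trialsSummary(v[1:100]), ciHigh - ciLow)
  w2 <- with(trialsSummary(v), ciHigh - ciLow)
  expect_equal(w2 / w1, 0.5, tolerance = 0.25)
})

test_that("baseline table combines categorical and continuous tests", {
  set.seed(14)
  df <- data.frame(split = rep(c("train", "val", "test"), each = 40),
                   stage = sample(c("III", "IV"), 120, replace = TRUE),
                   age = rnorm(120, 55, 8))
  tab <- baselineTable(df, categorical = "stage", continuous = "age")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$test, c("chi-square", "kruskal-wallis"))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
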