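cfgSmall <- function(task = "classification") {
  milConfig(8, 6, task, attentionHidden = 5, fusionDim = 3, kInstances = 1)
}

test_that("attention pooling collapses correctly for degenerate bags", {
  model <- newMILModel(cfgSmall(), seed = 1)
  ## singleton bag: alpha is exactly 1 and M_WSI is the projected row
  bag1 <- makeBag(1, 8, seed = 2)
  at <- attentionPool(model, bag1, "PDS")
  expect_equal(at$alpha, 1)
  p <- model@params
  hp <- pmax(drop(bagFeatures(bag1) %*% p$Wp) + p$bp, 0)
  expect_equal(at$mWSI, hp, tolerance = 1e-12)
  ## identical rows: uniform weights and the common projected row
  H <- matrix(rep(rnorm(8), each = 6), 6, 8)
  at2 <- attentionPool(model, H, "IDS")
  expect_equal(at2$alpha, rep(1 / 6, 6), tolerance = 1e-12)
  ## alpha is a probability vector on random bags
  for (s in 1:10) {
    at3 <- attentionPool(model, makeBag(15, 8, seed = s), "PDS")
    expect_true(all(at3$alpha >= 0))
    expect_equal(sum(at3$alpha), 1, tolerance = 1e-6)
  }
})

test_that("attention pooling matches a hand-computed arithmetic oracle", {
  ## 2-dim everything, fixture weights, 3 hand-set instances; the
  ## tanh/sigmoid/softmax chain is recomputed here with scalar algebra
  cfg <- milConfig(2, 1, "classification", attentionHidden = 2,
                   fusionDim = 2, kInstances = 1)
  model <- newMILModel(cfg, seed = 1)
  p <- model@params
  p$Wp <- diag(2); p$bp <- c(0, 0)                 # identity projection
  p$V_PDS <- rbind(c(0.5, -0.3), c(0.2, 0.4)); p$bv_PDS <- c(0.1, -0.1)
  p$U_PDS <- rbind(c(-0.2, 0.6), c(0.3, 0.1)); p$bu_PDS <- c(0, 0.2)
  p$w_PDS <- c(0.7, -0.5); p$bw_PDS <- 0.05
  model@params <- p
  H <- rbind(c(1, 0.5), c(0.2, 0.4), c(0.9, 0.1))
  at <- attentionPool(model, H, "PDS")
  scores <- numeric(3)
  for (i in 1:3) {
    h <- pmax(H[i, ], 0)
    ta <- tanh(c(h %*% p$V_PDS) + p$bv_PDS)
    sg <- 1 / (1 + exp(-(c(h %*% p$U_PDS) + p$bu_PDS)))
    scores[i] <- sum(ta * sg * p$w_PDS) + p$bw_PDS
  }
  alpha <- exp(scores) / sum(exp(scores))
  expect_equal(at$alpha, alpha, tolerance = 1e-6)
  expect_equal(at$mWSI, colSums(alpha * pmax(H, 0)), tolerance = 1e-6)
})

test_that("gated fusion is an exact convex combination with testable endpoints", {
  cfg <- cfgSmall()
  model <- newMILModel(cfg, seed = 2)
  ## zero gate weights give g = 0.5 elementwise
  model@params$Wg[] <- 0
  model@params$bg[] <- 0
  mWSI <- rnorm(5); clin <- rnorm(6)
  fz <- gateFuse(model, mWSI, clin)
  expect_equal(fz$gate, rep(0.5, 3))
  p <- model@params
  xw <- drop(mWSI %*% p$Ww) + p$bww
  xc <- drop(clin %*% p$Wc) + p$bc
  expect_equal(fz$mFused, 0.5 * xw + 0.5 * xc, tolerance = 1e-12)
  ## forced gate 1: the clinical branch contributes nothing
  f1a <- gateFuse(model, mWSI, clin, forceGate = 1)
  f1b <- gateFuse(model, mWSI, rnorm(6), forceGate = 1)
  expect_equal(f1a$mFused, f1b$mFused)
  expect_equal(f1a$mFused, xw)
  ## forced gate 0: the image branch contributes nothing
  f0a <- gateFuse(model, mWSI, clin, forceGate = 0)
  f0b <- gateFuse(model, rnorm(5), clin, forceGate = 0)
  expect_equal(f0a$mFused, f0b$mFused)
  ## hand computation with 2-dim fusion fixture weights
  cfg2 <- milConfig(2, 2, "classification", attentionHidden = 2,
                    fusionDim = 2, kInstances = 1)
  m2 <- newMILModel(cfg2, seed = 3)
  p2 <- m2@params
  p2$Ww <- rbind(c(1, 0.5), c(-0.5, 0.2)); p2$bww <- c(0.1, 0)
  p2$Wc <- rbind(c(0.3, -0.1), c(0.2, 0.6)); p2$bc <- c(0, -0.2)
  p2$Wg <- rbind(c(0.2, -0.3), c(0.1, 0.4), c(-0.2, 0.1), c(0.5, 0))
  p2$bg <- c(0.05, -0.05)
  m2@params <- p2
  mw <- c(0.4, -0.8); cl <- c(1, 0.5)
  fu <- gateFuse(m2, mw, cl)
  z <- c(sum(c(mw, cl) * p2$Wg[, 1]), sum(c(mw, cl) * p2$Wg[, 2])) + p2$bg
  g <- 1 / (1 + exp(-z))
  xw2 <- c(sum(mw * p2$Ww[, 1]), sum(mw * p2$Ww[, 2])) + p2$bww
  xc2 <- c(sum(cl * p2$Wc[, 1]), sum(cl * p2$Wc[, 2])) + p2$bc
  expect_equal(fu$gate, g, tolerance = 1e-6)
  expect_equal(fu$mFused, g * xw2 + (1 - g) * xc2, tolerance = 1e-6)
})

test_that("task heads produce softmax probabilities or raw risks", {
  model <- newMILModel(cfgSmall(), seed = 4)
  model@params$Wo[] <- 0; model@params$bo[] <- 0
  pr <- predictSlide(model, makeBag(5, 8), rnorm(6), "PDS")
  expect_equal(pr$classProbs, c(0.5, 0.5))
  ms <- newMILModel(cfgSmall("survival"), seed = 4)
  ms@params$Wo[] <- 0; ms@params$bo[] <- 0
  expect_equal(predictSlide(ms, makeBag(5, 8), rnorm(6), "IDS")$risk, 0)
  ## hand softmax on fixture head weights
  model2 <- newMILModel(cfgSmall(), seed = 5)
  fused <- gateFuse(model2,
                    attentionPool(model2, makeBag(7, 8), "PDS")$mWSI,
                    rnorm(6))
  logits <- drop(fused$mFused %*% model2@params$Wo) + model2@params$bo
  pr2 <- predictSlide(model2, makeBag(7, 8), rnorm(6), "PDS")
  expect_equal(sum(pr2$classProbs), 1, tolerance = 1e-9)
})

test_that("instance classifier returns aligned per-instance scores", {
  model <- newMILModel(cfgSmall(), seed = 6)
  expect_equal(dim(instanceLogits(model, makeBag(1, 8))), c(1L, 2L))
  H <- matrix(rep(rnorm(8), each = 4), 4, 8)
  si <- instanceLogits(model, H)
  expect_equal(si[1, ], si[3, ])
  ## fixture weights, hand computation
  model@params$Wp <- diag(1, 8, 5)
  model@params$bp <- rep(0, 5)
  model@params$Wi <- matrix(seq(0.1, 1, length.out = 10), 5, 2)
  model@params$bi <- c(0.2, -0.2)
  h <- c(1, -2, 3, 0.5, -1, 2, 0, 1)
  hp <- pmax(h[1:5], 0)
  expect_equal(drop(instanceLogits(model, rbind(h))),
               c(sum(hp * model@params$Wi[, 1]) + 0.2,
                 sum(hp * model@params$Wi[, 2]) - 0.2), tolerance = 1e-12)
})

test_that("bag predictions are invariant to instance permutation", {
  model <- newMILModel(cfgSmall(), seed = 7)
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    H <- matrix(rnorm(n * 8), n, 8)
    clin <- rnorm(6)
    perm <- sample(n)
    a <- milfuse:::.milForward(model@params, model@config, H, clin, "PDS")
    b <- milfuse:::.milForward(model@params, model@config, H[perm, ],
                               clin, "PDS")
    expect_equal(b$alpha, a$alpha[perm], tolerance = 1e-6)
    expect_equal(b$M, a$M, tolerance = 1e-6)
    expect_equal(b$g, a$g, tolerance = 1e-6)
    expect_equal(b$Mf, a$Mf, tolerance = 1e-6)
    expect_equal(b$probs, a$probs, tolerance = 1e-6)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- milConfig(4, 3, "classification", attentionHidden = 4,
                   fusionDim = 2, kInstances = 1)
  p <- milfuse:::.withSeed(8, milfuse:::.initParams(cfg))
  set.seed(88)
  H <- matrix(rnorm(5 * 4), 5, 4); clin <- rnorm(3); y <- 1L; lam <- 0.9
  lossFun <- function(pp) {
    f <- milfuse:::.milForward(pp, cfg, H, clin, "IDS")
    sel <- milfuse:::.instanceSelect(f$alpha, y, 1L)
    P <- milfuse:::.softmaxRows(f$Si[sel$idx, , drop = FALSE])
    -log(f$probs[y + 1]) -
      lam * mean(log(P[cbind(seq_along(sel$idx), sel$pseudo + 1L)]))
  }
  f <- milfuse:::.milForward(p, cfg, H, clin, "IDS")
  onehot <- c(0, 0); onehot[y + 1] <- 1
  sel <- milfuse:::.instanceSelect(f$alpha, y, 1L)
  P <- milfuse:::.softmaxRows(f$Si[sel$idx, , drop = FALSE])
  tgt <- matrix(0, 2, 2); tgt[cbind(1:2, sel$pseudo + 1L)] <- 1
  dSi <- matrix(0, 5, 2); dSi[sel$idx, ] <- lam * (P - tgt) / 2
  g <- milfuse:::.milBackward(p, cfg, f, H, clin, "IDS",
                              dlogits = f$probs - onehot, dSi = dSi)
  eps <- 1e-6
  for (nm in names(g)) {
    idx <- seq_len(min(length(g[[nm]]), 6L))
    for (i in idx) {
      up <- p; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- p; dn[[nm]][i] <- dn[[nm]][i] - eps
      expect_equal(g[[nm]][i], (lossFun(up) - lossFun(dn)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("surgery routing touches only the active route plus shared weights", {
  cohort <- smallCohort(seed = 3, nPatients = 10)
  m <- cohortManifest(cohort)
  sid <- m$slide_id[m$surgery_type == "PDS"][1]
  bag <- cohortBags(cohort)[[sid]]
  cfg <- milConfig(16, 6, "classification", attentionHidden = 5,
                   fusionDim = 3, kInstances = 1)
  p <- milfuse:::.withSeed(9, milfuse:::.initParams(cfg))
  f <- milfuse:::.milForward(p, cfg, bagFeatures(bag), rnorm(6), "PDS")
  g <- milfuse:::.milBackward(p, cfg, f, bagFeatures(bag), rnorm(6),
                              "PDS", dlogits = f$probs - c(1, 0))
  upd <- milfuse:::.adamStep(p, g, milfuse:::.adamInit(), 1e-3, 0)
  for (nm in grep("_IDS$", names(p), value = TRUE))
    expect_identical(upd$params[[nm]], p[[nm]])
  expect_false(identical(upd$params$V_PDS, p$V_PDS))
  expect_false(identical(upd$params$Wp, p$Wp))
})

test_that("model checkpoints round-trip and reject schema mismatches", {
  model <- newMILModel(cfgSmall(), seed = 10)
  schema <- data.frame(name = letters[1:6], type = "binary")
  path <- tempfile(fileext = ".ckpt")
  saveModel(model, path, schema = schema)
  back <- loadModel(path, schema = schema)
  expect_equal(back@params, model@params)
  expect_equal(back@config, model@config)
  schema2 <- schema[c(2, 1, 3:6), ]
  expect_error(loadModel(path, schema = schema2), "hash mismatch")
  saveRDS(list(bogus = 1), path)
  expect_error(loadModel(path), "not a model checkpoint")
})
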