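## The multimodal gated-attention MIL network: dual surgery-routed
## gated-attention pooling, gated fusion with clinical covariates, and
## task heads. Forward and backward passes are written out explicitly
## (plain matrix algebra), so every gradient is checkable against finite
## differences.

#' Model configuration
#'
#' @param inputDim tile-feature dimensionality D.
#' @param clinicalDim length of the encoded clinical vector C.
#' @param task \code{"classification"} (dual-output head) or
#'   \code{"survival"} (single-output risk head).
#' @param attentionHidden width of the attention embedding (default 256).
#' @param fusionDim width of the shared fusion space (default 256).
#' @param dropout dropout rate applied to the attention embedding and the
#'   fused representation during training; defaults to 0.5 for
#'   classification and 0.25 for survival, per-task conventions of the
#'   architecture.
#' @param lambdaInst weight of the instance clustering loss (default 0.9).
#' @param kInstances instances selected per side for the instance loss.
#' @return list of configuration values.
#' @export
milConfig <- function(inputDim, clinicalDim,
                      task = c("classification", "survival"),
                      attentionHidden = 256L, fusionDim = 256L,
                      dropout = NULL, lambdaInst = 0.9, kInstances = 8L) {
  task <- match.arg(task)
  if (is.null(dropout))
    dropout <- if (task == "classification") 0.5 else 0.25
  stopifnot(inputDim >= 1L, clinicalDim >= 1L, attentionHidden >= 1L,
            fusionDim >= 1L, dropout >= 0, dropout < 1, lambdaInst >= 0,
            kInstances >= 1L)
  list(inputDim = as.integer(inputDim),
       clinicalDim = as.integer(clinicalDim),
       task = task,
       attentionHidden = as.integer(attentionHidden),
       fusionDim = as.integer(fusionDim),
       dropout = dropout,
       lambdaInst = lambdaInst,
       kInstances = as.integer(kInstances),
       nClasses = if (task == "classification") 2L else 1L)
}

## Uniform fan-in initialisation, U(-1/sqrt(fanin), 1/sqrt(fanin)).
.initMat <- function(nin, nout) {
  b <- 1 / sqrt(nin)
  matrix(runif(nin * nout, -b, b), nin, nout)
}

.initParams <- function(cfg) {
  D <- cfg$inputDim; L <- cfg$attentionHidden; A <- cfg$attentionHidden
  Fd <- cfg$fusionDim; Cd <- cfg$clinicalDim; K <- cfg$nClasses
  p <- list(
    Wp = .initMat(D, L), bp = numeric(L),
    Wi = .initMat(L, 2L), bi = numeric(2L),
    Wg = .initMat(L + Cd, Fd), bg = numeric(Fd),
    Ww = .initMat(L, Fd), bww = numeric(Fd),
    Wc = .initMat(Cd, Fd), bc = numeric(Fd),
    Wo = .initMat(Fd, K), bo = numeric(K)
  )
  for (r in c("PDS", "IDS")) {
    p[[paste0("V_", r)]] <- .initMat(L, A)
    p[[paste0("bv_", r)]] <- numeric(A)
    p[[paste0("U_", r)]] <- .initMat(L, A)
    p[[paste0("bu_", r)]] <- numeric(A)
    p[[paste0("w_", r)]] <- .initMat(A, 1L)[, 1L]
    p[[paste0("bw_", r)]] <- 0
  }
  p
}

#' Create an untrained model
#'
#' Initialises all parameter arrays with seeded uniform fan-in scaling;
#' every source of randomness flows from \code{seed}.
#'
#' @param config a [milConfig()] list.
#' @param seed integer RNG seed.
#' @return a [MILModel] object.
#' @export
newMILModel <- function(config, seed = 0L) {
  params <- .withSeed(seed, .initParams(config))
  new("MILModel", config = config, params = params, task = config$task,
      history = data.frame())
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-broadcast addition of a bias vector (faster than sweep()).
.addRow <- function(M, v) M + rep(v, each = nrow(M))

## Full forward pass for one slide. H: N x D feature matrix, C: encoded
## clinical vector, route: "PDS"/"IDS". dropHp / dropMf are optional
## inverted-dropout masks (training only). forceGate pins the fusion
## gate at a constant (diagnostic mode).
.milForward <- function(params, cfg, H, C, route, dropHp = NULL,
                        dropMf = NULL, forceGate = NULL) {
  stopifnot(route %in% c("PDS", "IDS"))
  if (nrow(H) == 0L) stop("empty bag")
  if (ncol(H) != cfg$inputDim)
    stop(sprintf("bag feature dimension %d does not match model input %d",
                 ncol(H), cfg$inputDim))
  if (length(C) != cfg$clinicalDim)
    stop(sprintf("clinical vector length %d does not match model %d",
                 length(C), cfg$clinicalDim))
  V <- params[[paste0("V_", route)]]; bv <- params[[paste0("bv_", route)]]
  U <- params[[paste0("U_", route)]]; bu <- params[[paste0("bu_", route)]]
  w <- params[[paste0("w_", route)]]; bw <- params[[paste0("bw_", route)]]

  Hp0 <- .addRow(H %*% params$Wp, params$bp)
  Hr <- Hp0 * (Hp0 > 0)
  Hp <- if (is.null(dropHp)) Hr else Hr * dropHp

  Ta <- tanh(.addRow(Hp %*% V, bv))
  Sg <- .sigmoid(.addRow(Hp %*% U, bu))
  G <- Ta * Sg
  sc <- drop(G %*% w) + bw
  scm <- sc - max(sc)
  alpha <- exp(scm) / sum(exp(scm))
  M <- drop(crossprod(Hp, alpha))

  xw <- drop(M %*% params$Ww) + params$bww
  xc <- drop(C %*% params$Wc) + params$bc
  z <- drop(c(M, C) %*% params$Wg) + params$bg
  g <- if (is.null(forceGate)) .sigmoid(z) else rep(forceGate, cfg$fusionDim)
  Mf0 <- g * xw + (1 - g) * xc
  Mf <- if (is.null(dropMf)) Mf0 else Mf0 * dropMf

  logits <- drop(Mf %*% params$Wo) + params$bo
  probs <- if (cfg$task == "classification") {
    e <- exp(logits - max(logits)); e / sum(e)
  } else NULL
  Si <- .addRow(Hp %*% params$Wi, params$bi)

  list(Hp0 = Hp0, Hp = Hp, Ta = Ta, Sg = Sg, G = G, sc = sc,
       alpha = alpha, M = M, xw = xw, xc = xc, z = z, g = g,
       Mf0 = Mf0, Mf = Mf, logits = logits, probs = probs, Si = Si,
       dropHp = dropHp, dropMf = dropMf, forceGate = forceGate)
}

## Backward pass: upstream gradients on the head logits (dlogits) and,
## optionally, on the instance scores (dSi, already scaled). Returns a
## named list of gradients covering the shared parameters and the route
## that was used -- the other route is untouched by construction.
.milBackward <- function(params, cfg, fw, H, C, route, dlogits,
                         dSi = NULL) {
  V <- params[[paste0("V_", route)]]
  U <- params[[paste0("U_", route)]]
  w <- params[[paste0("w_", route)]]
  g <- list()

  g$Wo <- outer(fw$Mf, dlogits); g$bo <- dlogits
  dMf <- drop(params$Wo %*% dlogits)
  dMf0 <- if (is.null(fw$dropMf)) dMf else dMf * fw$dropMf
  if (is.null(fw$forceGate)) {
    dg <- dMf0 * (fw$xw - fw$xc)
    dz <- dg * fw$g * (1 - fw$g)
  } else {
    dz <- numeric(cfg$fusionDim)
  }
  dxw <- dMf0 * fw$g
  dxc <- dMf0 * (1 - fw$g)
  g$Wg <- outer(c(fw$M, C), dz); g$bg <- dz
  g$Ww <- outer(fw$M, dxw); g$bww <- dxw
  g$Wc <- outer(C, dxc); g$bc <- dxc
  L <- cfg$attentionHidden
  dM <- drop(params$Ww %*% dxw) + drop(params$Wg[seq_len(L), , drop = FALSE] %*% dz)

  dalpha <- drop(fw$Hp %*% dM)
  dHp <- outer(fw$alpha, dM)
  dsc <- fw$alpha * (dalpha - sum(fw$alpha * dalpha))
  dG <- outer(dsc, w)
  g[[paste0("w_", route)]] <- drop(crossprod(fw$G, dsc))
  g[[paste0("bw_", route)]] <- sum(dsc)
  dZv <- dG * fw$Sg * (1 - fw$Ta^2)
  dZu <- dG * fw$Ta * fw$Sg * (1 - fw$Sg)
  g[[paste0("V_", route)]] <- crossprod(fw$Hp, dZv)
  g[[paste0("bv_", route)]] <- colSums(dZv)
  g[[paste0("U_", route)]] <- crossprod(fw$Hp, dZu)
  g[[paste0("bu_", route)]] <- colSums(dZu)
  dHp <- dHp + dZv %*% t(V) + dZu %*% t(U)

  if (!is.null(dSi)) {
    g$Wi <- crossprod(fw$Hp, dSi)
    g$bi <- colSums(dSi)
    dHp <- dHp + dSi %*% t(params$Wi)
  }

  dHr <- if (is.null(fw$dropHp)) dHp else dHp * fw$dropHp
  dHp0 <- dHr * (fw$Hp0 > 0)
  g$Wp <- crossprod(H, dHp0)
  g$bp <- colSums(dHp0)
  g
}

## ---- public operations --------------------------------------------------

.bagMatrix <- function(bag) {
  if (is(bag, "FeatureBag")) bag@features else as.matrix(bag)
}

#' Gated-attention pooling over a feature bag
#'
#' Selects the attention network for the slide's surgery route, projects
#' each instance into the attention embedding, scores it with the gated
#' (tanh x sigmoid) attention, normalises the scores by softmax into
#' weights \eqn{\alpha_i}, and returns the weighted bag representation
#' \eqn{M_{WSI} = \sum_i \alpha_i h_i'} (computed in the projected
#' space).
#'
#' @param model a [MILModel].
#' @param bag a [FeatureBag] or N x D matrix.
#' @param surgeryType \code{"PDS"} or \code{"IDS"}.
#' @return list with \code{alpha} (length N, sums to 1) and \code{mWSI}.
#' @export
attentionPool <- function(model, bag, surgeryType) {
  H <- .bagMatrix(bag)
  cfg <- model@config
  fw <- .milForward(model@params, cfg, H,
                    numeric(cfg$clinicalDim), surgeryType)
  list(alpha = fw$alpha, mWSI = fw$M, route = surgeryType)
}

#' Gated fusion of image and clinical embeddings
#'
#' Projects the bag representation and the clinical vector into the
#' shared fusion space, computes the vector-valued gate
#' \eqn{g = \sigma(f_{gate}([M_{WSI}; C]))} by a single affine map on
#' the concatenation, and returns the convex elementwise combination
#' \eqn{M_{fused} = g \odot W_w M_{WSI} + (1-g) \odot W_c C}.
#'
#' @param model a [MILModel].
#' @param mWSI bag representation from [attentionPool()].
#' @param clinical encoded clinical vector.
#' @param forceGate optionally pin the gate at a constant in [0, 1]
#'   (diagnostic mode; 1 silences the clinical branch, 0 the image
#'   branch).
#' @return list with \code{mFused} and \code{gate}.
#' @export
gateFuse <- function(model, mWSI, clinical, forceGate = NULL) {
  p <- model@params; cfg <- model@config
  if (length(clinical) != cfg$clinicalDim)
    stop("clinical vector length does not match the model schema")
  xw <- drop(mWSI %*% p$Ww) + p$bww
  xc <- drop(clinical %*% p$Wc) + p$bc
  z <- drop(c(mWSI, clinical) %*% p$Wg) + p$bg
  g <- if (is.null(forceGate)) .sigmoid(z) else rep(forceGate, cfg$fusionDim)
  list(mFused = g * xw + (1 - g) * xc, gate = g)
}

#' Slide-level prediction
#'
#' Full forward pass for one slide: attention pooling, gated fusion and
#' the task head. Classification returns class probabilities (softmax
#' over a dual-output head); survival returns the unsquashed scalar risk
#' score.
#'
#' @inheritParams attentionPool
#' @param clinical encoded clinical vector for the slide's patient.
#' @param forceGate see [gateFuse()].
#' @return list with \code{task}, \code{classProbs} (classification) or
#'   \code{risk} (survival), and \code{attention} (the weights
#'   \eqn{\alpha} with the route used).
#' @export
predictSlide <- function(model, bag, clinical, surgeryType,
                         forceGate = NULL) {
  H <- .bagMatrix(bag)
  cfg <- model@config
  fw <- .milForward(model@params, cfg, H, clinical, surgeryType,
                    forceGate = forceGate)
  out <- list(task = cfg$task,
              attention = list(alpha = fw$alpha, route = surgeryType))
  if (cfg$task == "classification") out$classProbs <- fw$probs
  else out$risk <- unname(fw$logits[1])
  out
}

#' Instance-level class scores
#'
#' Applies the shared instance classifier to the projected instances,
#' giving the N x 2 score matrix consumed by the instance clustering
#' loss.
#'
#' @inheritParams attentionPool
#' @return N x 2 matrix of instance logits.
#' @export
instanceLogits <- function(model, bag) {
  H <- .bagMatrix(bag)
  if (nrow(H) == 0L) stop("empty bag")
  p <- model@params
  Hp0 <- .addRow(H %*% p$Wp, p$bp)
  Hp <- Hp0 * (Hp0 > 0)
  .addRow(Hp %*% p$Wi, p$bi)
}

## ---- checkpoints --------------------------------------------------------

## FNV-1a hash of the clinical schema, so a checkpoint loaded against a
## reordered covariate encoding fails loudly.
.schemaHash <- function(schema) {
  s <- paste(apply(schema, 1L, paste, collapse = "\t"), collapse = "\n")
  ## 32-bit arithmetic carried in doubles; FNV only xors the low byte
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding the configuration echo,
#' the named parameter arrays and the training history; a JSON sidecar
#' records the clinical schema hash so that covariate-ordering
#' mismatches are detected at load time.
#'
#' @param model a [MILModel].
#' @param path checkpoint file path.
#' @param schema optional clinical schema data.frame to stamp/verify.
#' @return \code{loadModel} returns the [MILModel].
#' @export
saveModel <- function(model, path, schema = NULL) {
  saveRDS(list(config = model@config, params = model@params,
               task = model@task, history = model@history), path)
  if (!is.null(schema)) {
    jsonlite::write_json(
      list(schema_hash = .schemaHash(schema),
           clinical_dim = model@config$clinicalDim),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path, schema = NULL) {
  x <- readRDS(path)
  if (!all(c("config", "params", "task") %in% names(x)))
    stop("not a model checkpoint: ", path)
  sidecar <- paste0(path, ".json")
  if (!is.null(schema)) {
    if (!file.exists(sidecar))
      stop("schema supplied but checkpoint has no schema sidecar")
    meta <- jsonlite::read_json(sidecar)
    if (!identical(meta$schema_hash, .schemaHash(schema)))
      stop("clinical schema hash mismatch: the checkpoint was trained ",
           "with a different covariate encoding/order")
  }
  new("MILModel", config = x$config, params = x$params, task = x$task,
      history = if (is.null(x$history)) data.frame() else x$history)
}
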