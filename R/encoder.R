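#' Create a transformer architecture configuration
#'
#' @param hiddenSize hidden state dimension (divisible by `nHeads`).
#' @param nLayers number of transformer layers.
#' @param nHeads attention heads.
#' @param ffSize feed-forward inner dimension.
#' @param textLen text-half length (includes `[CLS]`/`[SEP]`).
#' @param kgLen KG-half length (0 for a text-only encoder). In walk mode it
#'   must equal `2 * walkLength + 2`.
#' @param dropout dropout probability (default 0: deterministic runs).
#' @param textVocabSize,nodeVocabSize,nRelations vocabulary sizes.
#' @return A validated [ModelConfig-class]; `maxLen = textLen + kgLen`.
#' @export
modelConfig <- function(hiddenSize = 64L, nLayers = 2L, nHeads = 4L,
                        ffSize = 128L, textLen = 32L, kgLen = 32L,
                        dropout = 0, textVocabSize = 0L, nodeVocabSize = 0L,
                        nRelations = 0L) {
  new("ModelConfig", hiddenSize = as.integer(hiddenSize),
      nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
      ffSize = as.integer(ffSize),
      maxLen = as.integer(textLen) + as.integer(kgLen),
      textLen = as.integer(textLen), kgLen = as.integer(kgLen),
      dropout = as.numeric(dropout), textVocabSize = as.integer(textVocabSize),
      nodeVocabSize = as.integer(nodeVocabSize),
      nRelations = as.integer(nRelations))
}

#' Full-scale architecture profile
#'
#' The BERT-base geometry used at full scale: 512-position combined input
#' split 256 text + 256 KG, hidden size 768, 12 layers, 12 heads. Useful for
#' structural checks; training it is far outside desk scale.
#'
#' @param textVocabSize,nodeVocabSize,nRelations vocabulary sizes.
#' @return A [ModelConfig-class].
#' @export
bertBaseProfile <- function(textVocabSize, nodeVocabSize, nRelations = 0L) {
  modelConfig(hiddenSize = 768L, nLayers = 12L, nHeads = 12L, ffSize = 3072L,
              textLen = 256L, kgLen = 256L, dropout = 0,
              textVocabSize = textVocabSize, nodeVocabSize = nodeVocabSize,
              nRelations = nRelations)
}

#' @rdname bertBaseProfile
#' @details `nlpBaseProfile()` is the text-only counterpart: the full
#'   512-token input of the language-model baseline, no KG half.
#' @export
nlpBaseProfile <- function(textVocabSize) {
  modelConfig(hiddenSize = 768L, nLayers = 12L, nHeads = 12L, ffSize = 3072L,
              textLen = 512L, kgLen = 0L, textVocabSize = textVocabSize)
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: %d positions (%d text + %d KG), hidden %d,",
                     " %d layers x %d heads, ff %d\n"),
              object@maxLen, object@textLen, object@kgLen, object@hiddenSize,
              object@nLayers, object@nHeads, object@ffSize))
})

rmat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)

initEncoderWeights <- function(cfg, seed, nodeInit = NULL, relInit = NULL) {
  withSeed(deriveSeed(seed, "init"), {
    H <- cfg@hiddenSize
    W <- list(
      textEmb = rmat(cfg@textVocabSize, H),
      posEmb = rmat(cfg@maxLen, H),
      segEmb = rmat(2L, H),
      embLnG = rep(1, H), embLnB = rep(0, H),
      mlmW = rmat(H, cfg@textVocabSize), mlmB = rep(0, cfg@textVocabSize),
      nspW = rmat(H, 2L), nspB = rep(0, 2L)
    )
    if (cfg@kgLen > 0L) {
      W$nodeEmb <- if (is.null(nodeInit)) rmat(cfg@nodeVocabSize, H) else {
        stopifnot(nrow(nodeInit) == cfg@nodeVocabSize)
        if (ncol(nodeInit) == H) unname(nodeInit)
        else nodeInit %*% rmat(ncol(nodeInit), H, sd = 1 / sqrt(ncol(nodeInit)))
      }
      W$memW <- rmat(H, cfg@nodeVocabSize)
      W$memB <- rep(0, cfg@nodeVocabSize)
      if (cfg@nRelations > 0L) {
        W$relEmb <- if (is.null(relInit)) rmat(cfg@nRelations, H) else {
          if (ncol(relInit) == H) unname(relInit)
          else relInit %*% rmat(ncol(relInit), H, sd = 1 / sqrt(ncol(relInit)))
        }
      }
    }
    W$layers <- lapply(seq_len(cfg@nLayers), function(l) list(
      Wq = rmat(H, H), bq = rep(0, H), Wk = rmat(H, H), bk = rep(0, H),
      Wv = rmat(H, H), bv = rep(0, H), Wo = rmat(H, H), bo = rep(0, H),
      ln1G = rep(1, H), ln1B = rep(0, H),
      Wf1 = rmat(H, cfg@ffSize), bf1 = rep(0, cfg@ffSize),
      Wf2 = rmat(cfg@ffSize, H), bf2 = rep(0, H),
      ln2G = rep(1, H), ln2B = rep(0, H)))
    W
  })
}

#' Initialize a cross encoder (or text-only encoder)
#'
#' KG-side embeddings default to trainable weights initialized from the
#' supplied node-embedding table (random-walk skip-gram vectors) or TransE
#' model; when the backbone dimension differs from the hidden size, a fixed
#' seeded linear projection is absorbed into the initialization.
#'
#' @param config a [ModelConfig-class].
#' @param textVocab a [TextVocabulary-class] (sets `textVocabSize`).
#' @param nodeVocab node-token vocabulary from [nodeVocabulary()]
#'   (required when `kgLen > 0`).
#' @param relations relation vocabulary (needed for the TransE-input variant).
#' @param nodeInit optional [NodeEmbeddingTable-class] for initialization.
#' @param transeInit optional [TranseModel-class]; initializes node and
#'   relation embeddings from TransE vectors.
#' @param seed integer seed.
#' @return A [CrossEncoder-class].
#' @export
initCrossEncoder <- function(config, textVocab, nodeVocab = character(0),
                             relations = character(0), nodeInit = NULL,
                             transeInit = NULL, seed = 1L) {
  stopifnot(is(config, "ModelConfig"), is(textVocab, "TextVocabulary"))
  cfg <- config
  cfg@textVocabSize <- vocabSize(textVocab)
  if (cfg@kgLen > 0L) {
    if (!length(nodeVocab)) stop("nodeVocab is required when kgLen > 0")
    cfg@nodeVocabSize <- length(nodeVocab)
    cfg@nRelations <- length(relations)
  }
  validObject(cfg)
  nodeM <- relM <- NULL
  if (!is.null(nodeInit)) {
    stopifnot(is(nodeInit, "NodeEmbeddingTable"))
    idx <- match(nodeVocab, nodeInit@vocab)
    if (anyNA(idx)) stop("nodeInit table does not cover the node vocabulary")
    nodeM <- nodeInit@embeddings[idx, , drop = FALSE]
  }
  if (!is.null(transeInit)) {
    stopifnot(is(transeInit, "TranseModel"))
    ent <- transeInit@entities
    nodeM <- matrix(0, length(nodeVocab), transeInit@dim)
    hit <- match(nodeVocab, rownames(ent))
    nodeM[!is.na(hit), ] <- ent[hit[!is.na(hit)], , drop = FALSE]
    unk <- ent[match("[UNK]", rownames(ent)), ]
    nodeM[is.na(hit) & nodeVocab != "[PAD]", ] <-
      matrix(unk, sum(is.na(hit) & nodeVocab != "[PAD]"), transeInit@dim,
             byrow = TRUE)
    relHit <- match(relations, rownames(transeInit@relationVectors))
    if (length(relations)) {
      relM <- matrix(0, length(relations), transeInit@dim)
      ok <- !is.na(relHit)
      relM[ok, ] <- transeInit@relationVectors[relHit[ok], , drop = FALSE]
    }
  }
  weights <- initEncoderWeights(cfg, seed, nodeInit = nodeM, relInit = relM)
  new("CrossEncoder", config = cfg, weights = weights, textVocab = textVocab,
      nodeVocab = nodeVocab, relations = relations)
}

setMethod("show", "CrossEncoder", function(object) {
  kind <- if (object@config@kgLen > 0L) "CrossEncoder" else "Text-only encoder"
  cat(kind, "with"); show(object@config)
})

# ---- numerical building blocks -------------------------------------------

layerNormF <- function(x, g, b, eps = 1e-12) {
  n <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = xhat * rep(g, each = n) + rep(b, each = n), xhat = xhat, inv = inv)
}

layerNormB <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(g, each = nrow(dy))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

geluF <- function(x) {
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  list(y = 0.5 * x * (1 + t), t = t, x = x)
}

geluB <- function(dy, cache) {
  c0 <- sqrt(2 / pi)
  x <- cache$x; t <- cache$t
  dy * (0.5 * (1 + t) + 0.5 * x * (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2))
}

addBias <- function(x, b) x + rep(b, each = nrow(x))

# Forward through one transformer layer (post-layer-norm, BERT style).
layerForwardOne <- function(lw, X, maskAdd, nHeads) {
  H <- ncol(X); dk <- H / nHeads
  Q <- addBias(X %*% lw$Wq, lw$bq)
  K <- addBias(X %*% lw$Wk, lw$bk)
  V <- addBias(X %*% lw$Wv, lw$bv)
  O <- matrix(0, nrow(X), H)
  A <- vector("list", nHeads)
  maskRow <- rep(maskAdd, each = nrow(X))
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    S <- (Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE])) / sqrt(dk) +
      maskRow
    Ah <- softmaxRows(S)
    A[[h]] <- Ah
    O[, ix] <- Ah %*% V[, ix, drop = FALSE]
  }
  attnOut <- addBias(O %*% lw$Wo, lw$bo)
  ln1 <- layerNormF(X + attnOut, lw$ln1G, lw$ln1B)
  ffPre <- addBias(ln1$y %*% lw$Wf1, lw$bf1)
  gel <- geluF(ffPre)
  ffOut <- addBias(gel$y %*% lw$Wf2, lw$bf2)
  ln2 <- layerNormF(ln1$y + ffOut, lw$ln2G, lw$ln2B)
  list(y = ln2$y,
       cache = list(X = X, Q = Q, K = K, V = V, A = A, O = O, ln1 = ln1,
                    gel = gel, ln2 = ln2, X1 = ln1$y))
}

layerBackwardOne <- function(lw, cache, dY, nHeads) {
  H <- ncol(cache$X); dk <- H / nHeads
  g <- list()
  ln2b <- layerNormB(dY, cache$ln2, lw$ln2G)
  g$ln2G <- ln2b$dg; g$ln2B <- ln2b$db
  dSum2 <- ln2b$dx                       # grad into (X1 + ffOut)
  g$Wf2 <- crossprod(cache$gel$y, dSum2)
  g$bf2 <- colSums(dSum2)
  dGel <- tcrossprod(dSum2, lw$Wf2)
  dFfPre <- geluB(dGel, cache$gel)
  g$Wf1 <- crossprod(cache$X1, dFfPre)
  g$bf1 <- colSums(dFfPre)
  dX1 <- dSum2 + tcrossprod(dFfPre, lw$Wf1)
  ln1b <- layerNormB(dX1, cache$ln1, lw$ln1G)
  g$ln1G <- ln1b$dg; g$ln1B <- ln1b$db
  dSum1 <- ln1b$dx                       # grad into (X + attnOut)
  g$Wo <- crossprod(cache$O, dSum1)
  g$bo <- colSums(dSum1)
  dO <- tcrossprod(dSum1, lw$Wo)
  dQ <- matrix(0, nrow(cache$X), H)
  dK <- matrix(0, nrow(cache$X), H)
  dV <- matrix(0, nrow(cache$X), H)
  for (h in seq_len(nHeads)) {
    ix <- ((h - 1L) * dk + 1L):(h * dk)
    Ah <- cache$A[[h]]
    dOh <- dO[, ix, drop = FALSE]
    dA <- tcrossprod(dOh, cache$V[, ix, drop = FALSE])
    dV[, ix] <- crossprod(Ah, dOh)
    dS <- Ah * (dA - rowSums(dA * Ah))
    dQ[, ix] <- (dS %*% cache$K[, ix, drop = FALSE]) / sqrt(dk)
    dK[, ix] <- (crossprod(dS, cache$Q[, ix, drop = FALSE])) / sqrt(dk)
  }
  g$Wq <- crossprod(cache$X, dQ); g$bq <- colSums(dQ)
  g$Wk <- crossprod(cache$X, dK); g$bk <- colSums(dK)
  g$Wv <- crossprod(cache$X, dV); g$bv <- colSums(dV)
  dX <- dSum1 + tcrossprod(dQ, lw$Wq) + tcrossprod(dK, lw$Wk) +
    tcrossprod(dV, lw$Wv)
  list(dX = dX, grads = g)
}

# Resolve each position of a combined input to an embedding-table row.
# Returns table name ("text"/"node"/"rel"), 1-based row index and the matrix.
inputRows <- function(W, cfg, input) {
  Tl <- cfg@textLen; Kl <- cfg@kgLen
  tab <- c(rep("text", Tl), rep("node", Kl))
  row <- c(input$textIds + 1L,
           if (Kl > 0L) input$kgIds + 1L else integer(0))
  if (Kl > 0L) {
    kgPos <- Tl + seq_len(Kl)
    if (!is.null(input$kgUseTextMask) && any(input$kgUseTextMask)) {
      tab[kgPos[input$kgUseTextMask]] <- "text"
      row[kgPos[input$kgUseTextMask]] <- TEXT_MASK + 1L
    }
    if (!is.null(input$kgIsRelation) && any(input$kgIsRelation)) {
      tab[kgPos[input$kgIsRelation]] <- "rel"
      row[kgPos[input$kgIsRelation]] <- input$relIds[input$kgIsRelation] + 1L
    }
  }
  list(tab = tab, row = row)
}

encoderForwardIds <- function(W, cfg, input, collectCache = FALSE) {
  L <- cfg@maxLen
  src <- inputRows(W, cfg, input)
  E <- matrix(0, L, cfg@hiddenSize)
  for (tb in unique(src$tab)) {
    sel <- src$tab == tb
    M <- switch(tb, text = W$textEmb, node = W$nodeEmb, rel = W$relEmb)
    E[sel, ] <- M[src$row[sel], , drop = FALSE]
  }
  X0 <- E + W$posEmb[seq_len(L), , drop = FALSE] +
    W$segEmb[input$segmentIds + 1L, , drop = FALSE]
  lnE <- layerNormF(X0, W$embLnG, W$embLnB)
  maskAdd <- ifelse(input$attentionMask > 0L, 0, -1e9)
  X <- lnE$y
  caches <- if (collectCache) vector("list", cfg@nLayers) else NULL
  for (l in seq_len(cfg@nLayers)) {
    out <- layerForwardOne(W$layers[[l]], X, maskAdd, cfg@nHeads)
    if (collectCache) caches[[l]] <- out$cache
    X <- out$y
  }
  list(hidden = X, src = src, lnE = lnE, caches = caches, maskAdd = maskAdd)
}

#' Run the cross encoder forward
#'
#' Produces one hidden state per position, masked-language logits for the
#' text half, masked-entity logits for the KG half (over the node
#' vocabulary, separator included) and the binary next-"sentence" logits
#' computed from the `[CLS]` position.
#'
#' @param model a [CrossEncoder-class].
#' @param input a combined input from [assembleInput()] (optionally after
#'   [applyMasking()]).
#' @return List with `hidden` (maxLen x hidden), `mlmLogits`
#'   (textLen x textVocab), `memLogits` (kgLen x nodeVocab or NULL) and
#'   `nspLogits` (length 2).
#' @export
crossEncoderForward <- function(model, input) {
  stopifnot(is(model, "CrossEncoder"))
  cfg <- model@config; W <- model@weights
  fw <- encoderForwardIds(W, cfg, input)
  hidden <- fw$hidden
  textH <- hidden[seq_len(cfg@textLen), , drop = FALSE]
  mlmLogits <- addBias(textH %*% W$mlmW, W$mlmB)
  memLogits <- if (cfg@kgLen > 0L) {
    kgH <- hidden[cfg@textLen + seq_len(cfg@kgLen), , drop = FALSE]
    addBias(kgH %*% W$memW, W$memB)
  } else NULL
  nspLogits <- drop(hidden[1L, , drop = FALSE] %*% W$nspW) + W$nspB
  list(hidden = hidden, mlmLogits = mlmLogits, memLogits = memLogits,
       nspLogits = nspLogits)
}

#' Pool the `[CLS]` state and classify
#'
#' One linear map from the `[CLS]` hidden state followed by softmax — the
#' classification head shared by all fine-tuned models.
#'
#' @param hidden hidden-state matrix (first row = `[CLS]`).
#' @param head list with `W` (hidden x classes) and `b`.
#' @return Probability vector over the head's classes (sums to 1).
#' @export
poolAndClassify <- function(hidden, head) {
  if (ncol(head$W) != length(head$b))
    stop("class count mismatch between head weights and bias")
  if (nrow(head$W) != ncol(hidden))
    stop("head input size does not match hidden size")
  softmaxVec(drop(hidden[1L, , drop = FALSE] %*% head$W) + head$b)
}
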