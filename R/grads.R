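# Backward pass and loss gradients for the cross encoder.
#
# All gradients are exact analytic derivatives of the mean-cross-entropy
# objectives; the test suite checks them against finite differences.

zeroLike <- function(x) {
  if (is.list(x)) lapply(x, zeroLike)
  else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
  else if (is.numeric(x)) numeric(length(x))
  else x
}

mapLeaves2 <- function(a, b, f) {
  if (is.list(a)) {
    for (i in seq_along(a)) {      # indexed: layer lists are unnamed
      if (is.null(a[[i]])) next
      a[[i]] <- mapLeaves2(a[[i]], b[[i]], f)
    }
    a
  } else if (is.numeric(a)) f(a, b) else a
}

# Head losses and their gradients for one example, plus the gradient flowing
# back into the hidden states. mode "pretrain": masked objectives (variant
# full / no_nsp); mode "finetune": cross-entropy of the [CLS] head.
lossHeads <- function(W, cfg, input, hidden, variant, mode, clsHead,
                      clsLabelIdx) {
  L <- cfg@maxLen; Tl <- cfg@textLen; Kl <- cfg@kgLen
  dHidden <- matrix(0, L, cfg@hiddenSize)
  losses <- list(mlm = 0, mem = 0, nsp = 0, total = 0)
  hg <- list()
  if (mode == "pretrain") {
    supT <- which(!is.na(input$mlmLabels))
    if (length(supT)) {
      Ht <- hidden[supT, , drop = FALSE]
      p <- softmaxRows(addBias(Ht %*% W$mlmW, W$mlmB))
      at <- cbind(seq_along(supT), input$mlmLabels[supT] + 1L)
      losses$mlm <- -mean(log(pmax(p[at], 1e-12)))
      p[at] <- p[at] - 1
      p <- p / length(supT)
      hg$mlmW <- crossprod(Ht, p)
      hg$mlmB <- colSums(p)
      dHidden[supT, ] <- dHidden[supT, , drop = FALSE] + tcrossprod(p, W$mlmW)
    }
    if (Kl > 0L) {
      supK <- which(!is.na(input$memLabels))
      if (length(supK)) {
        rows <- Tl + supK
        Hk <- hidden[rows, , drop = FALSE]
        p <- softmaxRows(addBias(Hk %*% W$memW, W$memB))
        at <- cbind(seq_along(supK), input$memLabels[supK] + 1L)
        losses$mem <- -mean(log(pmax(p[at], 1e-12)))
        p[at] <- p[at] - 1
        p <- p / length(supK)
        hg$memW <- crossprod(Hk, p)
        hg$memB <- colSums(p)
        dHidden[rows, ] <- dHidden[rows, , drop = FALSE] + tcrossprod(p, W$memW)
      }
    }
    if (variant != "no_nsp" && !is.na(input$nspLabel)) {
      p <- softmaxVec(drop(hidden[1L, , drop = FALSE] %*% W$nspW) + W$nspB)
      lab <- input$nspLabel + 1L
      losses$nsp <- -log(max(p[lab], 1e-12))
      p[lab] <- p[lab] - 1
      hg$nspW <- hidden[1L, ] %o% p
      hg$nspB <- p
      dHidden[1L, ] <- dHidden[1L, ] + drop(W$nspW %*% p)
    }
    losses$total <- losses$mlm + losses$mem +
      (if (variant == "no_nsp") 0 else losses$nsp)
  } else {
    p <- softmaxVec(drop(hidden[1L, , drop = FALSE] %*% clsHead$W) + clsHead$b)
    losses$total <- -log(max(p[clsLabelIdx], 1e-12))
    p[clsLabelIdx] <- p[clsLabelIdx] - 1
    hg$clsW <- hidden[1L, ] %o% p
    hg$clsB <- p
    dHidden[1L, ] <- dHidden[1L, ] + drop(clsHead$W %*% p)
  }
  list(losses = losses, hg = hg, dHidden = dHidden)
}

# Per-example loss + gradient pieces (embedding-table gradients left as
# per-position rows for batch-level scattering).
lossAndGradsOne <- function(W, cfg, input, variant = "full",
                            mode = c("pretrain", "finetune"),
                            clsHead = NULL, clsLabelIdx = NULL) {
  mode <- match.arg(mode)
  fw <- encoderForwardIds(W, cfg, input, collectCache = TRUE)
  hd <- lossHeads(W, cfg, input, fw$hidden, variant, mode, clsHead,
                  clsLabelIdx)
  dX <- hd$dHidden
  layerGrads <- vector("list", cfg@nLayers)
  for (l in rev(seq_len(cfg@nLayers))) {
    bk <- layerBackwardOne(W$layers[[l]], fw$caches[[l]], dX, cfg@nHeads)
    layerGrads[[l]] <- bk$grads
    dX <- bk$dX
  }
  lnb <- layerNormB(dX, fw$lnE, W$embLnG)
  list(losses = hd$losses, hg = hd$hg, layerGrads = layerGrads,
       embLnG = lnb$dg, embLnB = lnb$db, dX0 = lnb$dx, src = fw$src)
}

# Dense single-example gradients (finite-difference checks, diagnostics).
lossAndGrads <- function(W, cfg, input, variant = "full",
                         mode = c("pretrain", "finetune"),
                         clsHead = NULL, clsLabelIdx = NULL) {
  mode <- match.arg(mode)
  r <- lossAndGradsOne(W, cfg, input, variant, mode, clsHead, clsLabelIdx)
  g <- zeroLike(W)
  for (nm in names(r$hg)) g[[nm]] <- r$hg[[nm]]
  for (l in seq_along(r$layerGrads))
    for (nm in names(r$layerGrads[[l]]))
      g$layers[[l]][[nm]] <- r$layerGrads[[l]][[nm]]
  g$embLnG <- r$embLnG; g$embLnB <- r$embLnB
  g$posEmb[seq_len(cfg@maxLen), ] <- r$dX0
  segSum <- rowsum(r$dX0, input$segmentIds)
  g$segEmb[as.integer(rownames(segSum)) + 1L, ] <-
    g$segEmb[as.integer(rownames(segSum)) + 1L, , drop = FALSE] + segSum
  for (tb in unique(r$src$tab)) {
    sel <- r$src$tab == tb
    nm <- switch(tb, text = "textEmb", node = "nodeEmb", rel = "relEmb")
    rs <- rowsum(r$dX0[sel, , drop = FALSE], r$src$row[sel])
    rows <- as.integer(rownames(rs))
    g[[nm]][rows, ] <- g[[nm]][rows, , drop = FALSE] + rs
  }
  list(losses = r$losses, grads = g)
}

# Average loss and gradients over a batch of inputs, accumulating into one
# gradient tree and scattering embedding rows once.
lossAndGradsBatch <- function(W, cfg, inputs, variant = "full",
                              mode = "pretrain", clsHead = NULL,
                              clsLabelIdx = NULL) {
  B <- length(inputs)
  g <- zeroLike(W)
  tot <- list(mlm = 0, mem = 0, nsp = 0, total = 0)
  posAcc <- matrix(0, cfg@maxLen, cfg@hiddenSize)
  segIds <- integer(0); segD <- vector("list", B)
  srcTab <- vector("list", B); srcRow <- vector("list", B)
  dX0s <- vector("list", B)
  for (i in seq_len(B)) {
    r <- lossAndGradsOne(W, cfg, inputs[[i]], variant = variant, mode = mode,
                         clsHead = clsHead,
                         clsLabelIdx = if (is.null(clsLabelIdx)) NULL
                                       else clsLabelIdx[i])
    tot <- Map(`+`, tot, r$losses)
    for (nm in names(r$hg)) {
      g[[nm]] <- if (is.null(g[[nm]])) r$hg[[nm]] else g[[nm]] + r$hg[[nm]]
    }
    for (l in seq_along(r$layerGrads))
      for (nm in names(r$layerGrads[[l]]))
        g$layers[[l]][[nm]] <- g$layers[[l]][[nm]] + r$layerGrads[[l]][[nm]]
    g$embLnG <- g$embLnG + r$embLnG
    g$embLnB <- g$embLnB + r$embLnB
    posAcc <- posAcc + r$dX0
    srcTab[[i]] <- r$src$tab; srcRow[[i]] <- r$src$row; dX0s[[i]] <- r$dX0
    segD[[i]] <- inputs[[i]]$segmentIds
  }
  g$posEmb[seq_len(cfg@maxLen), ] <- posAcc
  allSeg <- unlist(segD)
  allD <- do.call(rbind, dX0s)
  segSum <- rowsum(allD, allSeg)
  g$segEmb[as.integer(rownames(segSum)) + 1L, ] <-
    g$segEmb[as.integer(rownames(segSum)) + 1L, , drop = FALSE] + segSum
  allTab <- unlist(srcTab); allRow <- unlist(srcRow)
  for (tb in unique(allTab)) {
    sel <- allTab == tb
    nm <- switch(tb, text = "textEmb", node = "nodeEmb", rel = "relEmb")
    rs <- rowsum(allD[sel, , drop = FALSE], allRow[sel])
    rows <- as.integer(rownames(rs))
    g[[nm]][rows, ] <- g[[nm]][rows, , drop = FALSE] + rs
  }
  list(losses = lapply(tot, function(x) x / B),
       grads = mapLeaves2(g, g, function(a, b) a / B))
}

# ---- AdamW ----------------------------------------------------------------

adamInit <- function(W) list(m = zeroLike(W), v = zeroLike(W), t = 0L)

# Decoupled weight decay on matrix-shaped leaves (embeddings and linear
# maps); biases and layer-norm vectors are not decayed. `lrNow` already
# includes the schedule. `freeze` names top-level leaves left untouched.
adamStep <- function(W, g, state, lrNow, weightDecay = 0.01, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, freeze = character(0)) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, gr, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    w <- w - lrNow * (mh / (sqrt(vh) + eps) + (if (decay) weightDecay * w else 0))
    list(w = w, m = m, v = v)
  }
  rec <- function(w, gr, m, v, path) {
    if (is.list(w)) {
      for (i in seq_along(w)) {    # indexed: layer lists are unnamed
        if (is.null(w[[i]]) || is.null(gr[[i]])) next
        nm <- if (is.null(names(w))) "" else names(w)[i]
        r <- rec(w[[i]], gr[[i]], m[[i]], v[[i]], c(path, nm))
        w[[i]] <- r$w; m[[i]] <- r$m; v[[i]] <- r$v
      }
      list(w = w, m = m, v = v)
    } else if (is.numeric(w)) {
      if (length(path) && path[[1]] %in% freeze) return(list(w = w, m = m, v = v))
      upd(w, gr, m, v, decay = is.matrix(w))
    } else list(w = w, m = m, v = v)
  }
  r <- rec(W, g, state$m, state$v, character(0))
  state$m <- r$m; state$v <- r$v
  list(W = r$w, state = state)
}

# Linear warmup over the first `warmupFrac` of the budget, then linear decay
# to 0 — the standard schedule for this architecture family.
lrSchedule <- function(lr0, stepNo, totalSteps, warmupFrac = 0.1) {
  w <- max(1, floor(warmupFrac * totalSteps))
  if (stepNo <= w) return(lr0 * stepNo / w)
  lr0 * max(0, 1 - (stepNo - w) / max(1, totalSteps - w))
}

# Global-norm gradient clipping (norm computed over every leaf).
clipGrads <- function(g, maxNorm = 1) {
  sq <- 0
  acc <- function(x) {
    if (is.list(x)) for (el in x) { if (!is.null(el)) acc(el) }
    else if (is.numeric(x)) sq <<- sq + sum(x * x)
  }
  acc(g)
  nrm <- sqrt(sq)
  if (!is.finite(nrm) || nrm <= maxNorm) return(g)
  mapLeaves2(g, g, function(a, b) a * (maxNorm / nrm))
}
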