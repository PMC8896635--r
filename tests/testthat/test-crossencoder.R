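test_that("assembled inputs obey the length and segment laws", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs(),
             model = fixtureModel())
  ts <- tripleToWalkSequence(fx$pairs[1, ], fx$tab, fx$kg, length = 7, seed = 2)
  inp <- assembleInput(fx$pairs[1, ], fx$model, kgSequence = ts)
  expect_length(inp$textIds, 12L)
  expect_length(inp$kgIds, 16L)
  expect_identical(inp$segmentIds, c(rep(0L, 12), rep(1L, 16)))
  expect_identical(inp$positionIds, 0:27)
  expect_true(all(is.na(inp$mlmLabels)) && all(is.na(inp$memLabels)))
  # initial embeddings equal the table rows position by position
  expect_equal(inp$embeddings[13, ],
               unname(fx$model@weights$nodeEmb[inp$kgIds[1] + 1L, ]))
  expect_equal(inp$embeddings[1, ],
               unname(fx$model@weights$textEmb[inp$textIds[1] + 1L, ]))
  # wrong walk geometry is rejected
  bad <- tripleToWalkSequence(fx$pairs[1, ], fx$tab, fx$kg, length = 5, seed = 2)
  expect_error(assembleInput(fx$pairs[1, ], fx$model, kgSequence = bad),
               "must equal the KG half")
})

test_that("full-scale geometry: walk length 127 fills a 256+256=512 input", {
  profile <- bertBaseProfile(1000L, 500L)
  expect_equal(profile@maxLen, 512L)
  expect_equal(profile@textLen, 256L)
  expect_equal(profile@kgLen, 256L)
  # same sequence law exercised end-to-end at small hidden size
  kg <- fixtureKg()
  tab <- fixtureTable()
  mc <- modelConfig(hiddenSize = 16, nLayers = 1, nHeads = 2, ffSize = 24,
                    textLen = 256, kgLen = 256)
  model <- initCrossEncoder(mc, fixtureVocab(), nodeVocabulary(kg),
                            nodeInit = tab, seed = 1)
  ts <- tripleToWalkSequence(fixturePairs()[1, ], tab, kg, length = 127,
                             seed = 3)
  expect_length(ts@tokenIds, 256L)
  inp <- assembleInput(fixturePairs()[1, ], model, kgSequence = ts)
  expect_length(inp$textIds, 256L)
  expect_equal(length(inp$textIds) + length(inp$kgIds), 512L)
  expect_identical(inp$segmentIds[1:256], rep(0L, 256))
  expect_identical(inp$segmentIds[257:512], rep(1L, 256))
})

test_that("TransE-mode inputs pad the KG half and mask pads from attention", {
  kg <- fixtureKg()
  tm <- trainTransE(kg, d = 16, epochs = 3, seed = 4)
  model <- fixtureModel()
  ed <- fixturePairs()[3, ]
  seqT <- tripleToTranseSequence(ed, tm, nodeVocab = nodeVocabulary(kg))
  inp <- assembleInput(ed, model, kgSequence = seqT)
  expect_length(inp$kgIds, 16L)
  expect_identical(inp$attentionMask[13:15], rep(1L, 3))
  expect_identical(inp$attentionMask[16:28], rep(0L, 13))
  expect_true(inp$kgIsRelation[2])
  fw <- crossEncoderForward(model, inp)
  expect_equal(nrow(fw$memLogits), 16L)
})

test_that("masking hits the 15% / 80-10-10 expectations within 3 sigma", {
  nSel <- 0; nMask <- 0; nRand <- 0; nKeep <- 0; nMaskable <- 0
  reps <- 150L
  for (r in seq_len(reps)) {
    inp <- fixtureMaskedInput(i = (r %% 20) + 1L, maskProb = 0.15,
                              seed = 1000L + r)
    origT <- fixtureMaskedInput(i = (r %% 20) + 1L, maskProb = 0, seed = 1L)
    maskable <- sum(!origT$textIds %in% c(0L, 2L, 3L)) + length(origT$kgIds)
    nMaskable <- nMaskable + maskable
    selT <- which(!is.na(inp$mlmLabels))
    selK <- which(!is.na(inp$memLabels))
    nSel <- nSel + length(selT) + length(selK)
    nMask <- nMask + sum(inp$textIds[selT] == 4L & inp$mlmLabels[selT] != 4L) +
      sum(inp$kgUseTextMask[selK])
    changed <- sum(inp$textIds[selT] != origT$textIds[selT] &
                     inp$textIds[selT] != 4L) +
      sum(inp$kgIds[selK] != origT$kgIds[selK] & !inp$kgUseTextMask[selK])
    nRand <- nRand + changed
  }
  p <- 0.15
  expect_lt(abs(nSel - nMaskable * p), 3 * sqrt(nMaskable * p * (1 - p)))
  expect_lt(abs(nMask - nSel * 0.8), 3 * sqrt(nSel * 0.8 * 0.2))
  # random replacements resample the original id 1/V of the time, so the
  # observed changed fraction sits slightly below 0.10
  expect_lt(abs(nRand - nSel * 0.1), 3 * sqrt(nSel * 0.1 * 0.9) + 0.01 * nSel)
})

test_that("maskProb 0 leaves inputs unchanged with all-ignore labels", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs(),
             model = fixtureModel())
  ts <- tripleToWalkSequence(fx$pairs[1, ], fx$tab, fx$kg, length = 7, seed = 2)
  raw <- assembleInput(fx$pairs[1, ], fx$model, kgSequence = ts)
  m0 <- applyMasking(raw, 0, seed = 5)
  expect_identical(m0$textIds, raw$textIds)
  expect_identical(m0$kgIds, raw$kgIds)
  expect_true(all(is.na(m0$mlmLabels)) && all(is.na(m0$memLabels)))
  expect_error(applyMasking(m0, 0.15), "already masked")
})

test_that("labels stay NA off the selected set and record original ids on it", {
  for (s in 1:10) {
    raw <- fixtureMaskedInput(i = s, maskProb = 0, seed = 1L)
    m <- fixtureMaskedInput(i = s, maskProb = 0.4, seed = 100L + s)
    selT <- which(!is.na(m$mlmLabels))
    expect_identical(m$mlmLabels[selT], raw$textIds[selT])
    expect_identical(m$textIds[-selT], raw$textIds[-selT])
    selK <- which(!is.na(m$memLabels))
    expect_identical(m$memLabels[selK], raw$kgIds[selK])
    keepK <- setdiff(seq_along(m$kgIds), selK)
    expect_identical(m$kgIds[keepK], raw$kgIds[keepK])
    expect_false(any(m$kgUseTextMask[keepK]))
  }
})

test_that("masked KG positions are fed the text-side [MASK] embedding", {
  m <- fixtureMaskedInput(maskProb = 0.9, seed = 77L)
  expect_gt(sum(m$kgUseTextMask), 0)
  src <- kgcross:::inputRows(fixtureModel()@weights, fixtureModel()@config, m)
  kgPos <- 12L + which(m$kgUseTextMask)
  expect_true(all(src$tab[kgPos] == "text"))
  expect_true(all(src$row[kgPos] == 5L))      # [MASK] row (0-based id 4)
})

test_that("forward produces per-position states and normalized probabilities", {
  m <- fixtureMaskedInput()
  fw <- crossEncoderForward(fixtureModel(), m)
  expect_equal(dim(fw$hidden), c(28L, 16L))
  expect_equal(nrow(fw$mlmLogits), 12L)
  expect_equal(nrow(fw$memLogits), 16L)
  expect_length(fw$nspLogits, 2L)
  sm <- kgcross:::softmaxRows(fw$mlmLogits)
  expect_true(all(abs(rowSums(sm) - 1) < 1e-6))
  sm2 <- kgcross:::softmaxRows(fw$memLogits)
  expect_true(all(abs(rowSums(sm2) - 1) < 1e-6))
})

test_that("content at attention-masked positions cannot leak into the rest", {
  m <- fixtureMaskedInput(maskProb = 0)
  padPos <- which(m$attentionMask == 0L)
  expect_gt(length(padPos), 0)
  fw1 <- crossEncoderForward(fixtureModel(), m)
  m2 <- m
  m2$textIds[intersect(padPos, seq_len(12))] <- 7L  # arbitrary real token
  fw2 <- crossEncoderForward(fixtureModel(), m2)
  live <- which(m$attentionMask == 1L)
  expect_lt(max(abs(fw1$hidden[live, ] - fw2$hidden[live, ])), 1e-8)
})

test_that("loss components match an independent cross-entropy oracle", {
  model <- fixtureModel()
  for (s in 1:20) {
    m <- fixtureMaskedInput(i = s, maskProb = 0.3, seed = 500L + s,
                            nspLabel = if (s %% 2) "matched" else "random")
    fw <- crossEncoderForward(model, m)
    got <- computeLosses(fw, m, "full")
    expMlm <- oracleCrossEntropy(fw$mlmLogits, m$mlmLabels)
    expMem <- oracleCrossEntropy(fw$memLogits, m$memLabels)
    expNsp <- oracleCrossEntropy(matrix(fw$nspLogits, 1), m$nspLabel)
    expect_equal(got$mlm, expMlm, tolerance = 1e-9)
    expect_equal(got$mem, expMem, tolerance = 1e-9)
    expect_equal(got$nsp, expNsp, tolerance = 1e-9)
    expect_lt(abs(got$total - (expMlm + expMem + expNsp)), 1e-6)
    noNsp <- computeLosses(fw, m, "no_nsp")
    expect_lt(abs(noNsp$total - (expMlm + expMem)), 1e-6)
  }
})

test_that("degenerate losses: no supervision gives zero, perfect logits too", {
  model <- fixtureModel()
  m0 <- fixtureMaskedInput(maskProb = 0)
  m0$nspLabel <- NA_integer_
  fw <- crossEncoderForward(model, m0)
  expect_equal(computeLosses(fw, m0, "no_nsp")$total, 0)
  # one-hot logits matching the label give (numerically) zero loss
  fake <- fw
  m1 <- m0; m1$mlmLabels[5] <- m1$textIds[5]
  fake$mlmLogits[5, ] <- -1e4
  fake$mlmLogits[5, m1$textIds[5] + 1L] <- 1e4
  expect_equal(computeLosses(fake, m1, "no_nsp")$mlm, 0, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  model <- fixtureModel()
  m <- fixtureMaskedInput(maskProb = 0.3, seed = 42L)
  lg <- kgcross:::lossAndGrads(model@weights, model@config, m, "full")
  num <- function(mut) {
    eps <- 1e-5
    Wp <- mut(model@weights, eps); Wm <- mut(model@weights, -eps)
    (kgcross:::lossAndGrads(Wp, model@config, m)$losses$total -
       kgcross:::lossAndGrads(Wm, model@config, m)$losses$total) / (2 * eps)
  }
  checks <- list(
    list(a = lg$grads$posEmb[1], mut = function(W, e) { W$posEmb[1] <- W$posEmb[1] + e; W }),
    list(a = lg$grads$segEmb[3], mut = function(W, e) { W$segEmb[3] <- W$segEmb[3] + e; W }),
    list(a = lg$grads$mlmW[7], mut = function(W, e) { W$mlmW[7] <- W$mlmW[7] + e; W }),
    list(a = lg$grads$memW[11], mut = function(W, e) { W$memW[11] <- W$memW[11] + e; W }),
    list(a = lg$grads$nspW[2], mut = function(W, e) { W$nspW[2] <- W$nspW[2] + e; W }),
    list(a = lg$grads$embLnG[2], mut = function(W, e) { W$embLnG[2] <- W$embLnG[2] + e; W }),
    list(a = lg$grads$layers[[1]]$Wo[5], mut = function(W, e) { W$layers[[1]]$Wo[5] <- W$layers[[1]]$Wo[5] + e; W }),
    list(a = lg$grads$layers[[2]]$Wf1[9], mut = function(W, e) { W$layers[[2]]$Wf1[9] <- W$layers[[2]]$Wf1[9] + e; W }),
    list(a = lg$grads$layers[[1]]$ln1G[4], mut = function(W, e) { W$layers[[1]]$ln1G[4] <- W$layers[[1]]$ln1G[4] + e; W }))
  for (ch in checks) {
    n <- num(ch$mut)
    expect_lt(abs(ch$a - n) / max(1e-6, abs(ch$a) + abs(n)), 1e-3)
  }
})

test_that("NSP augmentation adds the exact negative count, never colliding", {
  base <- fixturePairs()[1:40, ]
  aug <- makeNspExamples(base, 0.25, seed = 6)
  expect_equal(nrow(aug), 50L)
  expect_equal(sum(aug$nspLabel == "random"), 10L)
  expect_identical(aug$pair_id[1:40], base$pair_id)
  origKey <- paste(base$evidence, base$head, base$relation, base$tail)
  negs <- aug[aug$nspLabel == "random", ]
  expect_false(any(paste(negs$evidence, negs$head, negs$relation,
                         negs$tail) %in% origKey))
  expect_identical(nrow(makeNspExamples(base, 0, seed = 1)), 40L)
  expect_error(makeNspExamples(base[1, ], 0.5, seed = 1), "at least 2")
})

test_that("[CLS] pooling yields normalized class probabilities", {
  m <- fixtureMaskedInput()
  fw <- crossEncoderForward(fixtureModel(), m)
  H <- ncol(fw$hidden)
  p3 <- poolAndClassify(fw$hidden, list(W = matrix(rnorm(H * 3), H), b = rep(0, 3)))
  expect_length(p3, 3L)
  expect_equal(sum(p3), 1, tolerance = 1e-6)
  pz <- poolAndClassify(fw$hidden, list(W = matrix(0, H, 4), b = rep(0, 4)))
  expect_equal(pz, rep(0.25, 4))
  p2 <- poolAndClassify(fw$hidden, list(W = matrix(0, H, 2), b = c(0, 0)))
  expect_length(p2, 2L)
  expect_error(poolAndClassify(fw$hidden, list(W = matrix(0, H, 2), b = 1:3)),
               "mismatch")
})
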