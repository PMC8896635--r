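microPretrain <- function(steps, checkpointSteps = integer(0),
                          variant = "full", seed = 21L) {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs(),
             model = fixtureModel())
  corpus <- makeNspExamples(fx$pairs[1:30, ], 0.25, seed = 2)
  pretrain(corpus, fx$model, fx$kg, fx$tab,
           trainConfig(batchSize = 4, steps = steps, lr = 1e-3,
                       checkpointSteps = checkpointSteps, variant = variant,
                       seed = seed))
}

test_that("checkpoints are prefixes of the same run", {
  long <- microPretrain(6L, checkpointSteps = c(3L, 6L))
  short <- microPretrain(3L)
  expect_named(long$checkpoints, c("step3", "step6"))
  # snapshot at the shared step equals the short run's final state is not
  # required (schedules differ); the prefix property is within one run:
  expect_identical(long$checkpoints$step6@weights, long$model@weights)
  expect_false(identical(long$checkpoints$step3@weights,
                         long$checkpoints$step6@weights))
  # and the identical config reproduces the identical trajectory
  again <- microPretrain(6L, checkpointSteps = c(3L, 6L))
  expect_identical(long$checkpoints$step3@weights,
                   again$checkpoints$step3@weights)
  expect_identical(long$metrics, again$metrics)
})

test_that("the no_nsp variant logs an identically zero NSP loss", {
  run <- microPretrain(3L, variant = "no_nsp")
  expect_identical(run$metrics$l_nsp, rep(0, 3))
  expect_equal(run$metrics$l_total, run$metrics$l_mlm + run$metrics$l_mem)
  full <- microPretrain(3L)
  expect_true(all(full$metrics$l_nsp > 0))
  expect_equal(full$metrics$l_total,
               full$metrics$l_mlm + full$metrics$l_mem + full$metrics$l_nsp)
})

test_that("empty corpora and bad variants are rejected", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), model = fixtureModel())
  empty <- fixturePairs()[0, ]
  expect_error(pretrain(empty, fx$model, fx$kg, fx$tab,
                        trainConfig(steps = 1)), "empty")
  expect_error(pretrain(fixturePairs()[1:4, ], fx$model, fx$kg, fx$tab,
                        trainConfig(steps = 1, variant = "transe_input")),
               "TranseModel")
  expect_error(trainConfig(lr = 0), "positive")
  expect_error(trainConfig(variant = "bogus"), "variant")
})

test_that("the transe_input variant pre-trains over TransE triple inputs", {
  kg <- fixtureKg()
  tm <- trainTransE(kg, d = 16, epochs = 3, seed = 4)
  model <- initCrossEncoder(modelConfig(hiddenSize = 16, nLayers = 1,
                                        nHeads = 2, ffSize = 24,
                                        textLen = 12, kgLen = 16),
                            fixtureVocab(), nodeVocabulary(kg),
                            relations = relations(kg), transeInit = tm,
                            seed = 4)
  corpus <- makeNspExamples(fixturePairs()[1:12, ], 0.25, seed = 2)
  run <- pretrain(corpus, model, kg, tm,
                  trainConfig(batchSize = 4, steps = 3, lr = 1e-3,
                              variant = "transe_input", seed = 5))
  expect_equal(nrow(run$metrics), 3L)
  expect_true(all(is.finite(run$metrics$l_total)))
  expect_true(all(run$metrics$l_mlm > 0))
  # only two entity slots per example are maskable, so some steps may have
  # no MEM supervision (component 0); across steps some masking must occur
  expect_true(any(run$metrics$l_mem > 0))
})

test_that("zero-epoch fine-tuning returns the untrained head", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs(),
             model = fixtureModel())
  task <- defaultTaskSpecs()$correct_binary
  dat <- splitCorpus(filterPairs(fx$pairs, fx$kg))$finetuning$correct_binary
  tc0 <- trainConfig(epochs = 0, seed = 9)
  c1 <- finetune(fx$model, dat[1:20, ], task, tc0, kg = fx$kg,
                 kgBackbone = fx$tab)
  c2 <- finetune(fx$model, dat[1:20, ], task, tc0, kg = fx$kg,
                 kgBackbone = fx$tab)
  expect_identical(c1@head, c2@head)
  expect_identical(c1@encoder@weights, fx$model@weights)  # nothing updated
  tc1 <- trainConfig(epochs = 1, lr = 1e-3, seed = 9)
  c3 <- finetune(fx$model, dat[1:20, ], task, tc1, kg = fx$kg,
                 kgBackbone = fx$tab)
  expect_false(identical(c3@head$W, c1@head$W))
  expect_false(identical(c3@encoder@weights$textEmb, fx$model@weights$textEmb))
})

test_that("the default fine-tune profile is 5 epochs, batch 16, lr 5e-5", {
  tc <- trainConfig()
  expect_equal(tc@epochs, 5L)
  expect_equal(tc@batchSize, 16L)
  expect_equal(tc@lr, 5e-5)
  expect_equal(tc@variant, "full")
})

test_that("labels outside the task's class set are a data error", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs(),
             model = fixtureModel())
  task <- taskSpec("correct_binary", c("yes", "no"), "correctness", "fused")
  dat <- splitCorpus(filterPairs(fx$pairs, fx$kg))$finetuning$correct_binary
  expect_error(finetune(fx$model, dat[1:10, ], task, trainConfig(epochs = 0),
                        kg = fx$kg, kgBackbone = fx$tab),
               "data error")
})

test_that("a linearly separable toy task is learned to training accuracy 1", {
  # keyword-determined binary labels, text-only encoder
  cfg <- synthConfig(nNodes = 20, nRelations = 2, meanDegree = 4, nPairs = 48,
                     vocabSize = 10, annotationFraction = 1, nBlocks = 2,
                     seed = 13)
  kg <- generateKG(cfg)
  pairs <- generateTaskLabels(generatePairs(kg, cfg), kg, "text_determined",
                              2L, seed = 5L, taskName = "ctx")
  vocab <- buildVocabulary(pairs$evidence)
  enc <- initCrossEncoder(modelConfig(hiddenSize = 16, nLayers = 1, nHeads = 2,
                                      ffSize = 32, textLen = 16, kgLen = 0),
                          vocab, seed = 3)
  task <- taskSpec("ctx", 2L, "context_annotation", "text_determined")
  clf <- finetune(enc, pairs, task,
                  trainConfig(batchSize = 16, epochs = 25, lr = 5e-3, seed = 7))
  acc <- mean(predict(clf, pairs = pairs) == pairLabels(pairs, "ctx"))
  expect_equal(acc, 1)
})

test_that("dimension-wise max pooling matches its definition and an oracle", {
  expect_equal(maxPoolSequence(rbind(c(1, 5), c(3, 2))), c(3, 5))
  single <- matrix(c(7, -2, 0.5), 1)
  expect_equal(maxPoolSequence(single), drop(single))
  set.seed(4)
  M <- matrix(rnorm(15 * 6), 15, 6)
  loop <- vapply(seq_len(6), function(j) max(M[, j]), numeric(1))
  expect_equal(maxPoolSequence(M), loop)
  expect_error(maxPoolSequence(M[0, , drop = FALSE]), "empty")
})

test_that("the KG baseline trains only its head; embeddings stay bit-identical", {
  fx <- list(kg = fixtureKg(), tab = fixtureTable(), pairs = fixturePairs())
  before <- fx$tab@embeddings
  dat <- splitCorpus(filterPairs(fx$pairs, fx$kg))$finetuning$correct_binary
  seqs <- lapply(seq_len(20), function(i) {
    tripleToWalkSequence(dat[i, ], fx$tab, fx$kg, length = 6, seed = i)
  })
  task <- defaultTaskSpecs()$correct_binary
  clf <- fitKgBaseline(seqs, pairLabels(dat[1:20, ], "correct_binary"), task,
                       trainConfig(epochs = 10, lr = 0.05, seed = 2))
  expect_identical(fx$tab@embeddings, before)
  expect_equal(clf@type, "kg")
  pred <- predict(clf, sequences = seqs)
  expect_true(all(pred %in% task@classes))
  # ragged dimensions are a data error
  tiny <- trainNodeEmbeddings(fx$kg, d = 4, walkLength = 4, walksPerNode = 1,
                              window = 2, epochs = 1, seed = 1)
  other <- tripleToWalkSequence(dat[1, ], tiny, fx$kg, length = 6, seed = 1)
  expect_error(fitKgBaseline(c(seqs[1], list(other)), c("c0", "c1"), task,
                             trainConfig(epochs = 1)), "ragged")
})
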