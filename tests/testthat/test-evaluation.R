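test_that("weighted F1 matches hand-computed confusion matrices", {
  expect_equal(weightedF1(c("a", "b", "a"), c("a", "b", "a")), 1)
  # true = [0,0,1], pred = [0,1,1]:
  # class 0: prec 1, rec 1/2, F1 2/3; class 1: prec 1/2, rec 1, F1 2/3
  expect_equal(weightedF1(c(0, 0, 1), c(0, 1, 1)),
               (2 / 3) * (2 / 3) + (1 / 3) * (2 / 3))
  # every prediction lands on a class absent from the truth
  expect_equal(weightedF1(c("a", "b"), c("z", "z")), 0)
  expect_error(weightedF1(character(0), character(0)), "empty")
  expect_error(weightedF1(c("a", "b"), "a"), "length")
})

test_that("weighted F1 agrees with an independent oracle on random cases", {
  oracle <- function(true, pred) {
    classes <- unique(true)
    tot <- 0
    for (cl in classes) {
      cm <- table(factor(true == cl, c(FALSE, TRUE)),
                  factor(pred == cl, c(FALSE, TRUE)))
      tp <- cm["TRUE", "TRUE"]; fp <- cm["FALSE", "TRUE"]
      fn <- cm["TRUE", "FALSE"]
      prec <- if (tp + fp) tp / (tp + fp) else 0
      rec <- if (tp + fn) tp / (tp + fn) else 0
      f1 <- if (prec + rec) 2 * prec * rec / (prec + rec) else 0
      tot <- tot + (tp + fn) / length(true) * f1
    }
    tot
  }
  set.seed(17)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    n <- sample(3:40, 1)
    true <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:(k + 1)], n, replace = TRUE)
    expect_equal(weightedF1(true, pred), oracle(true, pred),
                 tolerance = 1e-9)
  }
})

test_that("a constant predictor scores its closed-form weighted F1", {
  set.seed(5)
  true <- rep(c("a", "b"), each = 50)
  # constant "a": class a has prec 0.5, rec 1 -> F1 2/3; class b scores 0
  expect_equal(weightedF1(true, rep("a", 100)), 0.5 * 2 / 3)
  p <- 0.3
  true2 <- c(rep("a", 30), rep("b", 70))
  expect_equal(weightedF1(true2, rep("a", 100)), p * 2 * p / (1 + p))
})

test_that("relative gain reproduces the printed benchmark percentages", {
  expect_equal(round(relativeGain(0.965, 0.881), 2), 9.53)
  expect_equal(round(relativeGain(0.248, 0.214), 2), 15.89)
  expect_equal(relativeGain(0.5, 0.5), 0)
  expect_warning(g0 <- relativeGain(0.3, 0), "undefined")
  expect_true(is.na(g0))
})

test_that("task specs enforce the benchmark's class-count range", {
  expect_error(taskSpec("x", 1L, "correctness", "fused"), "2..10")
  expect_error(taskSpec("x", 11L, "correctness", "fused"), "2..10")
  specs <- defaultTaskSpecs()
  expect_length(specs, 8L)
  expect_equal(unname(vapply(specs, function(t) length(t@classes), integer(1))),
               c(2L, 2L, 10L, 10L, 5L, 3L, 2L, 8L))
  expect_true(excludedForTranse(specs$polarity))
  expect_false(excludedForTranse(specs$species))
})

benchGridFixture <- function() {
  cfg <- synthConfig(nNodes = 40, nRelations = 4, meanDegree = 8, nPairs = 400,
                     vocabSize = 20, annotationFraction = 0.5, nBlocks = 8,
                     seed = 19)
  kg <- generateKG(cfg)
  pairs <- generatePairs(kg, cfg)
  tasks <- defaultTaskSpecs()
  # realizable class counts on this micro graph: relations >= 2, blocks 8
  tasks$cell_line <- taskSpec("cell_line", 4L, "context_annotation",
                              "text_determined")
  tasks$disease <- taskSpec("disease", 4L, "context_annotation",
                            "text_determined")
  for (t in tasks) {
    pairs <- generateTaskLabels(pairs, kg, t@labelKind,
                                length(t@classes), seed = 23L,
                                taskName = t@name)
  }
  flt <- filterPairs(pairs, kg)
  datasets <- splitCorpus(flt)$finetuning
  vocab <- buildVocabulary(flt$evidence)
  tab <- trainNodeEmbeddings(kg, d = 8, walkLength = 6, walksPerNode = 2,
                             window = 2, epochs = 1, seed = 2)
  tm <- trainTransE(kg, d = 8, epochs = 3, seed = 2)
  mc <- modelConfig(hiddenSize = 8, nLayers = 1, nHeads = 2, ffSize = 16,
                    textLen = 12, kgLen = 12)
  encT <- initCrossEncoder(mc, vocab, nodeVocabulary(kg),
                           relations = relations(kg), transeInit = tm,
                           seed = 4)
  nlp <- initCrossEncoder(modelConfig(hiddenSize = 8, nLayers = 1, nHeads = 2,
                                      ffSize = 16, textLen = 24, kgLen = 0),
                          vocab, seed = 4)
  list(kg = kg, datasets = datasets, tasks = tasks, tab = tab, tm = tm,
       models = list(
         benchmarkModel("stonk_transe", "cross", encT, kgInput = "transe"),
         benchmarkModel("nlp_baseline", "nlp", nlp),
         benchmarkModel("kg_transe", "kg", kgInput = "transe",
                        trainConfig = trainConfig(epochs = 0, seed = 1))))
}

test_that("the benchmark grid counts results and exclusions correctly", {
  fx <- benchGridFixture()
  # 3 models x 8 tasks, 2 TransE-flagged models excluded on 2 relation tasks
  res <- runBenchmark(fx$models, fx$tasks, fx$datasets, fx$kg,
                      kgBackbones = list(walk = fx$tab, transe = fx$tm),
                      k = 2, seed = 31,
                      defaultTrainConfig = trainConfig(epochs = 0, seed = 1),
                      kgWalkLength = 5)
  sm <- benchmarkSummary(res)
  expect_equal(nrow(sm), 20L)                   # 3*8 - 4 model-task cells
  expect_equal(nrow(res@excluded), 4L)
  expect_equal(nrow(res@scores), 40L)           # k = 2 folds per cell
  expect_true(all(res@scores$weighted_f1 >= 0 & res@scores$weighted_f1 <= 1))
  expect_setequal(unique(res@excluded$task), c("polarity", "interaction_type"))
  # identical seed, identical table
  res2 <- runBenchmark(fx$models, fx$tasks, fx$datasets, fx$kg,
                       kgBackbones = list(walk = fx$tab, transe = fx$tm),
                       k = 2, seed = 31,
                       defaultTrainConfig = trainConfig(epochs = 0, seed = 1),
                       kgWalkLength = 5)
  expect_identical(res@scores, res2@scores)
  expect_error(runBenchmark(fx$models, fx$tasks, fx$datasets["polarity"],
                            fx$kg, list(walk = fx$tab, transe = fx$tm),
                            k = 2, seed = 1),
               "no dataset")
  gains <- benchmarkGains(res, "stonk_transe", c("nlp_baseline", "kg_transe"))
  expect_true(all(is.finite(gains$relative_gain_pct)))
  tsvDir <- withr::local_tempdir()
  writeBenchmarkTsv(res, tsvDir)
  expect_true(file.exists(file.path(tsvDir, "results.tsv")))
  expect_true(file.exists(file.path(tsvDir, "excluded.tsv")))
  rt <- utils::read.delim(file.path(tsvDir, "results.tsv"))
  expect_equal(nrow(rt), 40L)
})
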