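# Shared micro fixtures, built in code once per test run.

fixtureSynthConfig <- function(seed = 7L, nPairs = 120L) {
  synthConfig(nNodes = 40L, nRelations = 4L, meanDegree = 6, nPairs = nPairs,
              vocabSize = 20L, annotationFraction = 0.5, nBlocks = 4L,
              seed = seed)
}

.fixtures <- local({
  cfg <- fixtureSynthConfig()
  kg <- generateKG(cfg)
  pairs <- generatePairs(kg, cfg)
  pairs <- generateTaskLabels(pairs, kg, "fused", 2L, seed = 3L,
                              taskName = "correct_binary")
  pairs <- generateTaskLabels(pairs, kg, "text_determined", 3L, seed = 3L,
                              taskName = "location")
  vocab <- buildVocabulary(pairs$evidence)
  table <- trainNodeEmbeddings(kg, d = 16L, walkLength = 8L, walksPerNode = 3L,
                               window = 3L, epochs = 1L, seed = 2L)
  mc <- modelConfig(hiddenSize = 16L, nLayers = 2L, nHeads = 2L, ffSize = 24L,
                    textLen = 12L, kgLen = 16L)
  model <- initCrossEncoder(mc, vocab, nodeVocabulary(kg),
                            relations = relations(kg), nodeInit = table,
                            seed = 4L)
  list(cfg = cfg, kg = kg, pairs = pairs, vocab = vocab, table = table,
       mc = mc, model = model)
})

fixtureKg <- function() .fixtures$kg
fixturePairs <- function() .fixtures$pairs
fixtureVocab <- function() .fixtures$vocab
fixtureTable <- function() .fixtures$table
fixtureModel <- function() .fixtures$model

# Masked combined input for the fixture model.
fixtureMaskedInput <- function(i = 1L, maskProb = 0.3, seed = 11L,
                               nspLabel = "matched") {
  fx <- .fixtures
  ts <- tripleToWalkSequence(fx$pairs[i, ], fx$table, fx$kg, length = 7L,
                             seed = 9L)
  inp <- assembleInput(fx$pairs[i, ], fx$model, kgSequence = ts,
                       nspLabel = nspLabel)
  applyMasking(inp, maskProb, seed = seed)
}

# Hand-rolled cross-entropy oracle: mean -log p[label] over supervised rows.
oracleCrossEntropy <- function(logits, labels0based) {
  keep <- which(!is.na(labels0based))
  if (!length(keep)) return(0)
  tot <- 0
  for (i in keep) {
    z <- logits[i, ]
    p <- exp(z - max(z)) / sum(exp(z - max(z)))
    tot <- tot - log(p[labels0based[i] + 1L])
  }
  tot / length(keep)
}
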