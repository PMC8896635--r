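test_that("minimum viable graph: two nodes, at least one edge, no isolates", {
  kg <- generateKG(synthConfig(nNodes = 2, nRelations = 1, meanDegree = 1,
                               nPairs = 0, nBlocks = 1, seed = 1))
  expect_equal(numNodes(kg), 2L)
  expect_gte(numEdges(kg), 1L)
  deg <- lengths(kg@adjUndirected)
  expect_true(all(deg >= 1L))
})

test_that("generator is deterministic: same config gives identical output", {
  cfg <- fixtureSynthConfig(seed = 33L)
  kg1 <- generateKG(cfg); kg2 <- generateKG(cfg)
  expect_identical(kg1@edges, kg2@edges)
  expect_identical(kg1@nodeMeta, kg2@nodeMeta)
  p1 <- generatePairs(kg1, cfg); p2 <- generatePairs(kg2, cfg)
  expect_identical(p1, p2)
})

test_that("degenerate configs are rejected", {
  expect_error(generateKG(synthConfig(nNodes = 1, nBlocks = 1, seed = 1)),
               "at least 2")
  expect_error(synthConfig(annotationFraction = 1.5), "0, 1")
  expect_error(synthConfig(meanDegree = 0), "positive")
})

test_that("edge count tracks the expected n * meanDegree / 2", {
  counts <- vapply(1:5, function(s) {
    numEdges(generateKG(synthConfig(nNodes = 100, meanDegree = 4, nPairs = 0,
                                    nBlocks = 4, seed = s)))
  }, numeric(1))
  # 200 expected before duplicate removal / isolate repair
  expect_true(all(abs(counts - 200) / 200 < 0.2))
  expect_lt(abs(mean(counts) - 200) / 200, 0.1)
})

test_that("pairs reference graph edges and carry the exact annotation count", {
  kg <- fixtureKg()
  cfg <- fixtureSynthConfig()
  expect_identical(nrow(generatePairs(
    kg, synthConfig(nNodes = 40, nPairs = 0, nBlocks = 4, seed = 1))), 0L)
  cfg500 <- synthConfig(nNodes = 40, nRelations = 4, meanDegree = 6,
                        nPairs = 500, annotationFraction = 0.1, nBlocks = 4,
                        seed = 5)
  p <- generatePairs(generateKG(cfg500), cfg500)
  expect_equal(sum(p$annotated), 50L)
  kg500 <- generateKG(cfg500)
  edgeKey <- with(edges(kg500), paste(head, relation, tail))
  expect_true(all(paste(p$head, p$relation, p$tail) %in% edgeKey))
  expect_true(all(nzchar(p$evidence)))
})

test_that("relation-determined labels are a function of the relation type", {
  kg <- fixtureKg()
  p <- generateTaskLabels(fixturePairs(), kg, "relation_determined", 2L,
                          seed = 1L, taskName = "polarity")
  lab <- pairLabels(p, "polarity")
  got <- !is.na(lab)
  map <- tapply(lab[got], p$relation[got], function(x) length(unique(x)))
  expect_true(all(map == 1L))  # one label per relation type
  expect_setequal(unique(lab[got]), c("c0", "c1"))
})

test_that("unrealizable class counts raise invalid-config errors", {
  kg <- fixtureKg()   # 4 relations, 4 blocks
  expect_error(generateTaskLabels(fixturePairs(), kg, "relation_determined",
                                  6L, seed = 1L), "realizable")
  expect_error(generateTaskLabels(fixturePairs(), kg, "node_determined",
                                  9L, seed = 1L), "realizable")
  expect_error(generateTaskLabels(fixturePairs(), kg, "fused", 1L, seed = 1L),
               "2..10")
})

test_that("text-determined labels are independent of head-node identity", {
  cfg <- synthConfig(nNodes = 30, nRelations = 3, meanDegree = 6,
                     nPairs = 2000, annotationFraction = 1, nBlocks = 3,
                     seed = 21)
  kg <- generateKG(cfg)
  p <- generateTaskLabels(generatePairs(kg, cfg), kg, "text_determined", 2L,
                          seed = 9L, taskName = "ctx")
  lab <- pairLabels(p, "ctx")
  mi <- function(x, y) {
    tab <- table(x, y) / length(x)
    px <- rowSums(tab); py <- colSums(tab)
    sum(tab * log(tab / outer(px, py)), na.rm = TRUE)
  }
  obs <- mi(p$head, lab)
  set.seed(99)
  null <- vapply(1:200, function(i) mi(p$head, sample(lab)), numeric(1))
  expect_lt(obs, quantile(null, 0.975) + 1e-12)
  # and the label keyword is present in the evidence
  expect_true(all(mapply(grepl, paste0("ctxkw", match(lab, paste0("c", 0:1)) - 1),
                         p$evidence)))
})

test_that("fused labels need both modalities: unimodal Bayes accuracy < 1", {
  kg <- fixtureKg()
  p <- generateTaskLabels(fixturePairs(), kg, "fused", 2L, seed = 5L,
                          taskName = "fz")
  lab <- pairLabels(p, "fz")
  got <- which(!is.na(lab))
  ev <- p$evidence[got]
  kw <- regmatches(ev, regexpr("fzkw[0-9]+", ev))
  expect_length(kw, length(got))       # every labeled row carries a keyword
  bayesAcc <- function(feature) {
    tab <- table(feature, lab[got])
    sum(apply(tab, 1L, max)) / sum(tab)
  }
  expect_lt(bayesAcc(kw), 1)                         # keyword alone
  expect_lt(bayesAcc(p$head[got]), 1)                # node alone
  # joint keyword x node-block determines the label exactly (truth table)
  blocks <- nodeBlocks(kg)
  joint <- paste(kw, blocks[p$head[got]] %% 2)
  expect_equal(bayesAcc(joint), 1)
})

test_that("every labeled class is populated and labels are deterministic", {
  kg <- fixtureKg()
  for (kind in c("text_determined", "fused")) {
    p1 <- generateTaskLabels(fixturePairs(), kg, kind, 3L, seed = 17L)
    p2 <- generateTaskLabels(fixturePairs(), kg, kind, 3L, seed = 17L)
    expect_identical(p1, p2)
    lab <- pairLabels(p1, kind)
    expect_setequal(unique(lab[!is.na(lab)]), paste0("c", 0:2))
  }
})
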