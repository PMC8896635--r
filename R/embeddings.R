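#' Train node embeddings from random walks (node2vec style)
#'
#' Samples `walksPerNode` uniform second-order walks per node, then trains a
#' skip-gram model with negative sampling (SGNS) on the walk corpus with
#' minibatch SGD and a linearly decaying learning rate. Context-window pairs
#' use a fixed symmetric window; negatives are drawn from the corpus unigram
#' distribution raised to 3/4. Deterministic given `seed` (single-threaded).
#'
#' @param kg a [KnowledgeGraph-class].
#' @param d embedding dimension.
#' @param walkLength training-walk length.
#' @param walksPerNode walks sampled per start node.
#' @param window symmetric context window.
#' @param epochs passes over the pair list.
#' @param negatives negative samples per positive pair.
#' @param lr initial learning rate.
#' @param batchSize minibatch size for the aggregated SGD updates.
#' @param seed integer seed.
#' @return A [NodeEmbeddingTable-class] covering every node of `kg` plus the
#'   reserved `[PAD]` (zero vector), `[UNK]` and `[SEP]` entries.
#' @export
trainNodeEmbeddings <- function(kg, d = 64L, walkLength = 40L,
                                walksPerNode = 10L, window = 5L, epochs = 5L,
                                negatives = 5L, lr = 0.025, batchSize = 1024L,
                                seed = 1L) {
  stopifnot(is(kg, "KnowledgeGraph"))
  d <- as.integer(d)
  if (d <= 0L) stop("invalid config: embedding dimension d must be positive")
  if (numNodes(kg) == 0L) stop("kg is empty")
  n <- numNodes(kg)
  withSeed(deriveSeed(seed, "node2vec"), {
    # walk corpus (integer node indices)
    corpus <- vector("list", n * walksPerNode)
    k <- 1L
    for (w in seq_len(walksPerNode)) {
      for (v in seq_len(n)) {
        corpus[[k]] <- match(
          sampleWalk(kg, kg@nodes[v], walkLength,
                     seed = deriveSeed(seed, paste0("n2v:", w, ":", v))),
          kg@nodes)
        k <- k + 1L
      }
    }
    # skip-gram pairs for a fixed symmetric window
    ctr <- list(); ctx <- list(); k <- 1L
    for (wv in corpus) {
      Lw <- length(wv)
      for (o in seq_len(min(window, Lw - 1L))) {
        a <- wv[seq_len(Lw - o)]
        b <- wv[seq_len(Lw - o) + o]
        ctr[[k]] <- c(a, b); ctx[[k]] <- c(b, a); k <- k + 1L
      }
    }
    ctr <- unlist(ctr); ctx <- unlist(ctx)
    nPairs <- length(ctr)
    freq <- tabulate(unlist(corpus), n)
    negProb <- freq^0.75; negProb <- negProb / sum(negProb)
    lim <- 0.5 / d
    Win <- matrix(runif(n * d, -lim, lim), n, d)
    Wout <- matrix(0, n, d)
    sigm <- function(x) 1 / (1 + exp(-x))
    totalBatches <- epochs * ceiling(nPairs / batchSize)
    batchNo <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nPairs)
      for (s in seq(1L, nPairs, by = batchSize)) {
        sel <- ord[s:min(s + batchSize - 1L, nPairs)]
        B <- length(sel)
        ci <- ctr[sel]; oi <- ctx[sel]
        rate <- lr * max(1e-4, 1 - batchNo / totalBatches)
        batchNo <- batchNo + 1L
        ni <- matrix(sample.int(n, B * negatives, replace = TRUE,
                                prob = negProb), B, negatives)
        Vc <- Win[ci, , drop = FALSE]
        gOut <- (sigm(rowSums(Vc * Wout[oi, , drop = FALSE])) - 1)  # positive
        dIn <- gOut * Wout[oi, , drop = FALSE]
        outIdx <- oi
        outGrad <- gOut * Vc
        for (j in seq_len(negatives)) {
          nj <- ni[, j]
          gNeg <- sigm(rowSums(Vc * Wout[nj, , drop = FALSE]))
          dIn <- dIn + gNeg * Wout[nj, , drop = FALSE]
          outIdx <- c(outIdx, nj)
          outGrad <- rbind(outGrad, gNeg * Vc)
        }
        upIn <- rowsum(dIn, ci)
        Win[as.integer(rownames(upIn)), ] <-
          Win[as.integer(rownames(upIn)), , drop = FALSE] - rate * upIn
        upOut <- rowsum(outGrad, outIdx)
        Wout[as.integer(rownames(upOut)), ] <-
          Wout[as.integer(rownames(upOut)), , drop = FALSE] - rate * upOut
      }
    }
    reserved <- matrix(rnorm(3L * d, sd = 0.1), 3L, d)
    reserved[1L, ] <- 0  # [PAD]
    emb <- rbind(reserved, Win)
    rownames(emb) <- c("[PAD]", "[UNK]", "[SEP]", kg@nodes)
    new("NodeEmbeddingTable", vocab = rownames(emb), embeddings = emb)
  })
}

#' @rdname NodeEmbeddingTable-class
#' @param x a [NodeEmbeddingTable-class].
#' @export
setMethod("embeddingDim", "NodeEmbeddingTable", function(x) ncol(x@embeddings))

#' @rdname NodeEmbeddingTable-class
#' @export
setMethod("vocabSize", "NodeEmbeddingTable", function(x) length(x@vocab))

#' @rdname NodeEmbeddingTable-class
#' @param tokens character node tokens.
#' @export
setMethod("tokenToId", "NodeEmbeddingTable", function(x, tokens) {
  id <- match(tokens, x@vocab)
  id[is.na(id)] <- 2L            # [UNK] row (id 1, 0-based)
  as.integer(id - 1L)
})

#' @rdname NodeEmbeddingTable-class
#' @param ids integer 0-based ids.
#' @export
setMethod("idToToken", "NodeEmbeddingTable", function(x, ids) {
  x@vocab[as.integer(ids) + 1L]
})

setMethod("show", "NodeEmbeddingTable", function(object) {
  cat("NodeEmbeddingTable:", length(object@vocab), "entries x",
      ncol(object@embeddings), "dims (incl. reserved [PAD],[UNK],[SEP])\n")
})

#' Look up embedding rows for node tokens or ids
#' @param table a [NodeEmbeddingTable-class].
#' @param tokens character tokens (or use `ids`).
#' @param ids 0-based integer ids.
#' @return Numeric matrix of embedding rows.
#' @export
lookupEmbeddings <- function(table, tokens = NULL, ids = NULL) {
  stopifnot(is(table, "NodeEmbeddingTable"))
  if (is.null(ids)) ids <- tokenToId(table, tokens)
  if (any(ids < 0L | ids >= length(table@vocab)))
    stop("node id out of range")
  table@embeddings[ids + 1L, , drop = FALSE]
}

#' Represent a triple as a random-walk embedding sequence
#'
#' Builds the sequence walk(head), `[SEP]`, walk(tail), `[SEP]` — the
#' sequential triple representation fed to the KG half of the cross encoder
#' (and, without the separators at full length, to the KG baseline). With
#' the default walk length 127 the sequence has 2 * 127 + 2 = 256 positions.
#' A head or tail missing from the graph falls back to a run of `[UNK]`.
#'
#' @param triple list or one-row data.frame with `head`, `relation`, `tail`.
#' @param table a [NodeEmbeddingTable-class].
#' @param kg the [KnowledgeGraph-class] to walk on.
#' @param length walk length L; output length is `2 * L + 2`.
#' @param seed optional integer seed for the walks.
#' @param cache optional walk cache from `newWalkCache()`.
#' @return A [TripleSequence-class] in walk mode.
#' @export
tripleToWalkSequence <- function(triple, table, kg, length = 127L,
                                 seed = NULL, cache = NULL) {
  stopifnot(is(table, "NodeEmbeddingTable"), is(kg, "KnowledgeGraph"))
  length <- as.integer(length)
  walkFor <- function(node) {
    if (!is.null(cache)) return(cache$get(node))
    if (node %in% kg@nodes) {
      sampleWalk(kg, node, length,
                 seed = if (is.null(seed)) NULL
                        else deriveSeed(seed, paste0("walk:", node)))
    } else rep("[UNK]", length)
  }
  tokens <- c(walkFor(triple$head), "[SEP]", walkFor(triple$tail), "[SEP]")
  ids <- tokenToId(table, tokens)
  new("TripleSequence", tokenIds = ids, tokens = tokens,
      embeddings = lookupEmbeddings(table, ids = ids), mode = "walk")
}

setMethod("show", "TripleSequence", function(object) {
  cat("TripleSequence (", object@mode, " mode): ", length(object@tokenIds),
      " positions x ", ncol(object@embeddings), " dims\n", sep = "")
})
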