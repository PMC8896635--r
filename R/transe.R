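#' Train a TransE knowledge-graph embedding model
#'
#' Margin ranking loss with uniform head-or-tail corruption:
#' `max(0, margin + score(h, r, t) - score(h', r, t'))`, where
#' `score = || e_h + e_r - e_t ||_p`. Minibatch SGD with per-epoch
#' renormalization of entity vectors to the unit sphere. Deterministic
#' given `seed`.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param d embedding dimension.
#' @param margin ranking margin (> 0).
#' @param norm 1 or 2.
#' @param epochs training epochs.
#' @param negativesPerPositive corrupted samples per true triple.
#' @param lr learning rate.
#' @param batchSize minibatch size.
#' @param seed integer seed.
#' @return A [TranseModel-class] covering the graph's nodes and relations.
#' @export
trainTransE <- function(kg, d = 32L, margin = 1, norm = 2L, epochs = 100L,
                        negativesPerPositive = 1L, lr = 0.01, batchSize = 128L,
                        seed = 1L) {
  stopifnot(is(kg, "KnowledgeGraph"))
  d <- as.integer(d)
  if (d <= 0L) stop("invalid config: d must be positive")
  if (margin <= 0) stop("invalid config: margin must be positive")
  norm <- as.integer(norm)
  if (!norm %in% c(1L, 2L)) stop("invalid config: norm must be 1 or 2")
  if (numEdges(kg) == 0L) stop("kg has no edges")
  n <- numNodes(kg)
  rels <- relations(kg)
  hIdx <- match(kg@edges$head, kg@nodes)
  tIdx <- match(kg@edges$tail, kg@nodes)
  rIdx <- match(kg@edges$relation, rels)
  m <- numEdges(kg)
  withSeed(deriveSeed(seed, "transe"), {
    lim <- 6 / sqrt(d)
    E <- matrix(runif(n * d, -lim, lim), n, d)
    R <- matrix(runif(length(rels) * d, -lim, lim), length(rels), d)
    R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
    gradOfDiff <- function(D) {
      if (norm == 2L) D / pmax(sqrt(rowSums(D^2)), 1e-12) else sign(D)
    }
    scoreOfDiff <- function(D) {
      if (norm == 2L) sqrt(rowSums(D^2)) else rowSums(abs(D))
    }
    for (ep in seq_len(epochs)) {
      E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
      ord <- sample.int(m)
      for (s in seq(1L, m, by = batchSize)) {
        sel <- rep(ord[s:min(s + batchSize - 1L, m)], negativesPerPositive)
        B <- length(sel)
        h <- hIdx[sel]; r <- rIdx[sel]; t <- tIdx[sel]
        corruptHead <- runif(B) < 0.5
        hN <- ifelse(corruptHead, sample.int(n, B, replace = TRUE), h)
        tN <- ifelse(corruptHead, t, sample.int(n, B, replace = TRUE))
        Dp <- E[h, , drop = FALSE] + R[r, , drop = FALSE] - E[t, , drop = FALSE]
        Dn <- E[hN, , drop = FALSE] + R[r, , drop = FALSE] - E[tN, , drop = FALSE]
        act <- margin + scoreOfDiff(Dp) - scoreOfDiff(Dn) > 0
        if (!any(act)) next
        Gp <- gradOfDiff(Dp[act, , drop = FALSE])
        Gn <- gradOfDiff(Dn[act, , drop = FALSE])
        entIdx <- c(h[act], t[act], hN[act], tN[act])
        entGrad <- rbind(Gp, -Gp, -Gn, Gn)
        upE <- rowsum(entGrad, entIdx)
        rows <- as.integer(rownames(upE))
        E[rows, ] <- E[rows, , drop = FALSE] - lr * upE
        upR <- rowsum(Gp - Gn, r[act])
        rRows <- as.integer(rownames(upR))
        R[rRows, ] <- R[rRows, , drop = FALSE] - lr * upR
      }
    }
    ents <- rbind(E, matrix(rnorm(d, sd = 0.1), 1L, d))
    rownames(ents) <- c(kg@nodes, "[UNK]")
    relsM <- rbind(R, matrix(rnorm(d, sd = 0.1), 1L, d))
    rownames(relsM) <- c(rels, "[UNK]")
    new("TranseModel", entities = ents, relationVectors = relsM, dim = d,
        normOrder = norm)
  })
}

#' Score triples under a TransE model
#'
#' `|| e_h + e_r - e_t ||_p`; zero iff `e_h + e_r = e_t`, and never negative.
#' Unknown entities/relations use the `[UNK]` rows.
#'
#' @param model a [TranseModel-class].
#' @param head,relation,tail character vectors (recycled to equal length).
#' @return Numeric vector of non-negative scores.
#' @export
transeScore <- function(model, head, relation, tail) {
  stopifnot(is(model, "TranseModel"))
  nmax <- max(length(head), length(relation), length(tail))
  head <- rep_len(head, nmax); relation <- rep_len(relation, nmax)
  tail <- rep_len(tail, nmax)
  lk <- function(tab, keys) {
    i <- match(keys, rownames(tab))
    i[is.na(i)] <- match("[UNK]", rownames(tab))
    tab[i, , drop = FALSE]
  }
  D <- lk(model@entities, head) + lk(model@relationVectors, relation) -
    lk(model@entities, tail)
  unname(if (model@normOrder == 2L) sqrt(rowSums(D^2)) else rowSums(abs(D)))
}

#' @rdname TranseModel-class
#' @param x a [TranseModel-class].
#' @export
setMethod("embeddingDim", "TranseModel", function(x) x@dim)

setMethod("show", "TranseModel", function(object) {
  cat("TranseModel:", nrow(object@entities) - 1L, "entities,",
      nrow(object@relationVectors) - 1L, "relations, d =", object@dim,
      ", L", object@normOrder, "norm\n")
})

#' Represent a triple as its TransE embedding sequence
#'
#' The three vectors (head, relation, tail) in that order — the alternative
#' sequential triple representation. Unknown entities or relations fall back
#' to the `[UNK]` rows (reported via a message). `tokenIds` index the node
#' vocabulary when one is supplied; the relation position carries the node
#' `[UNK]` id since relations are not node-vocabulary members.
#'
#' @param triple list or one-row data.frame with head, relation, tail.
#' @param model a [TranseModel-class].
#' @param nodeVocab optional node-token vocabulary (see [nodeVocabulary()]).
#' @return A [TripleSequence-class] in TransE mode (exactly 3 positions).
#' @export
tripleToTranseSequence <- function(triple, model, nodeVocab = NULL) {
  stopifnot(is(model, "TranseModel"))
  unknowns <- character(0)
  lk <- function(tab, key) {
    i <- match(key, rownames(tab))
    if (is.na(i)) {
      unknowns <<- c(unknowns, key)
      i <- match("[UNK]", rownames(tab))
    }
    tab[i, ]
  }
  emb <- rbind(lk(model@entities, triple$head),
               lk(model@relationVectors, triple$relation),
               lk(model@entities, triple$tail))
  if (length(unknowns))
    message("tripleToTranseSequence: unknown entries mapped to [UNK]: ",
            paste(unique(unknowns), collapse = ", "))
  ids <- if (is.null(nodeVocab)) c(1L, 1L, 1L) else {
    i <- match(c(triple$head, triple$tail), nodeVocab)
    i[is.na(i)] <- 2L
    as.integer(c(i[1L] - 1L, 1L, i[2L] - 1L))
  }
  new("TripleSequence", tokenIds = ids,
      tokens = c(triple$head, triple$relation, triple$tail),
      embeddings = unname(emb), mode = "transe")
}
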