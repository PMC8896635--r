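#' Create a synthetic-corpus configuration
#'
#' The generator emulates the shape of a large assembled biomedical knowledge
#' base at desk scale: grounded node identifiers with distinct surface names,
#' typed directed relations, one evidence sentence per triple, and a minority
#' of pairs carrying class annotations. See the package vignette for the
#' reasoning behind each default.
#'
#' @param nNodes number of nodes (>= 2 required by [generateKG()]).
#' @param nRelations number of typed relations.
#' @param meanDegree target mean total degree; expected edge count is
#'   `nNodes * meanDegree / 2` directed edges.
#' @param nPairs number of text-triple pairs.
#' @param vocabSize number of filler words in the sentence templates.
#' @param annotationFraction fraction of pairs that are annotation-capable.
#' @param nBlocks number of structural node blocks; node-determined and fused
#'   task labels read block membership, and edges prefer to stay within a
#'   block so that the attribute is also visible to structural embeddings.
#' @param pWithinBlock probability an edge stays within its head's block.
#' @param seed integer seed.
#' @return A validated [SynthConfig-class].
#' @export
synthConfig <- function(nNodes = 800L, nRelations = 6L, meanDegree = 8,
                        nPairs = 2000L, vocabSize = 60L,
                        annotationFraction = 0.15, nBlocks = 4L,
                        pWithinBlock = 0.8, seed = 42L) {
  new("SynthConfig", nNodes = as.integer(nNodes),
      nRelations = as.integer(nRelations), meanDegree = as.numeric(meanDegree),
      nPairs = as.integer(nPairs), vocabSize = as.integer(vocabSize),
      annotationFraction = as.numeric(annotationFraction),
      nBlocks = as.integer(nBlocks), pWithinBlock = as.numeric(pWithinBlock),
      seed = as.integer(seed))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d nodes (%d blocks), %d relations, mean ",
                     "degree %.1f, %d pairs (%.0f%% annotated), seed %d\n"),
              object@nNodes, object@nBlocks, object@nRelations,
              object@meanDegree, object@nPairs,
              100 * object@annotationFraction, object@seed))
})

# Deterministic pronounceable surface names, distinct from the toy:%04d ids.
makeSurfaceNames <- function(n) {
  cons <- c("B", "D", "F", "G", "K", "L", "M", "N", "P", "R", "S", "T", "V", "Z")
  vow <- c("A", "E", "I", "O", "U")
  syl <- as.vector(outer(cons, vow, paste0))
  base <- paste0(sample(syl, n, replace = TRUE), sample(syl, n, replace = TRUE))
  paste0(base, seq_len(n))
}

relationVerbs <- function(nRelations) {
  verbs <- c("activates", "inhibits", "binds", "phosphorylates", "upregulates",
             "represses", "degrades", "stabilizes", "transports", "methylates")
  rep_len(verbs, nRelations)
}

fillerWords <- function(vocabSize) {
  withSeed(971L, {
    cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
    vow <- c("a", "e", "i", "o", "u")
    syl <- as.vector(outer(cons, vow, paste0))
    w <- paste0(sample(syl, vocabSize, replace = TRUE),
                sample(syl, vocabSize, replace = TRUE))
    make.unique(w, sep = "q")
  })
}

#' Generate a toy knowledge graph
#'
#' Relation-typed Erdős–Rényi-style edge sampling with block structure:
#' `round(nNodes * meanDegree / 2)` directed edges are drawn (head uniform;
#' tail within the head's block with probability `pWithinBlock`, otherwise
#' uniform elsewhere), self-loops and duplicate triples are dropped, and any
#' node left isolated receives one extra within-block edge, so every node has
#' degree >= 1. Relation types are assigned uniformly. Fully reproducible
#' from `cfg@seed`.
#'
#' @param cfg a [SynthConfig-class].
#' @return A [KnowledgeGraph-class]; `nodeMeta` carries surface names and
#'   block labels `0..nBlocks-1`.
#' @examples
#' kg <- generateKG(synthConfig(nNodes = 50, nPairs = 0, seed = 7))
#' numNodes(kg)
#' @export
generateKG <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  validObject(cfg)
  if (cfg@nNodes < 2L) stop("invalid config: nNodes must be at least 2")
  withSeed(deriveSeed(cfg@seed, "generateKG"), {
    n <- cfg@nNodes
    ids <- sprintf("toy:%04d", seq_len(n))
    names <- makeSurfaceNames(n)
    block <- (seq_len(n) - 1L) %% cfg@nBlocks
    rels <- paste0("rel_", relationVerbs(cfg@nRelations))[seq_len(cfg@nRelations)]
    nEdges <- max(1L, round(n * cfg@meanDegree / 2))
    heads <- sample.int(n, nEdges, replace = TRUE)
    within <- runif(nEdges) < cfg@pWithinBlock
    tails <- integer(nEdges)
    byBlock <- split(seq_len(n), block)
    for (i in seq_len(nEdges)) {
      cand <- if (within[i]) byBlock[[as.character(block[heads[i]])]] else seq_len(n)
      cand <- setdiff(cand, heads[i])
      if (!length(cand)) cand <- setdiff(seq_len(n), heads[i])
      tails[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
    }
    rel <- sample(rels, nEdges, replace = TRUE)
    ed <- data.frame(head = ids[heads], relation = rel, tail = ids[tails],
                     stringsAsFactors = FALSE)
    ed <- ed[!duplicated(ed), , drop = FALSE]
    # re-attach any node the sampling left isolated
    seen <- unique(c(ed$head, ed$tail))
    for (i in which(!ids %in% seen)) {
      cand <- setdiff(byBlock[[as.character(block[i])]], i)
      if (!length(cand)) cand <- setdiff(seq_len(n), i)
      j <- if (length(cand) == 1L) cand else sample(cand, 1L)
      ed <- rbind(ed, data.frame(head = ids[i], relation = sample(rels, 1L),
                                 tail = ids[j], stringsAsFactors = FALSE))
    }
    rownames(ed) <- NULL
    knowledgeGraph(ed, nodes = ids,
                   nodeMeta = data.frame(name = names, block = as.integer(block),
                                         stringsAsFactors = FALSE))
  })
}

emptyPairTable <- function() {
  data.frame(pair_id = character(0), evidence = character(0),
             head = character(0), relation = character(0),
             tail = character(0),
             annotations = I(list()), annotated = logical(0),
             stringsAsFactors = FALSE)
}

#' Generate synthetic text-triple pairs
#'
#' Each pair samples an edge of `kg` (with replacement) and renders an
#' evidence sentence from the template
#' `"<head-name> <verb-phrase(relation)> <tail-name> <filler...>"` using the
#' nodes' surface names, so that sentences mention both endpoints without
#' leaking their grounded identifiers. Exactly
#' `round(annotationFraction * nPairs)` pairs are flagged annotation-capable
#' (`annotated` column); class-indicative keywords are appended later by
#' [generateTaskLabels()] for the task kinds whose label is readable from
#' text.
#'
#' @param kg a [KnowledgeGraph-class] from [generateKG()].
#' @param cfg the same [SynthConfig-class].
#' @return A pair table: data.frame with columns pair_id, evidence, head,
#'   relation, tail, annotations (list column of named label lists) and the
#'   generator-only logical column `annotated`.
#' @export
generatePairs <- function(kg, cfg) {
  stopifnot(is(kg, "KnowledgeGraph"), is(cfg, "SynthConfig"))
  if (numEdges(kg) == 0L) stop("kg has no edges")
  if (cfg@nPairs == 0L) return(emptyPairTable())
  withSeed(deriveSeed(cfg@seed, "generatePairs"), {
    nm <- nodeNames(kg)
    verbs <- stats::setNames(relationVerbs(length(relations(kg))), relations(kg))
    filler <- fillerWords(cfg@vocabSize)
    ei <- sample.int(numEdges(kg), cfg@nPairs, replace = TRUE)
    ed <- edges(kg)[ei, , drop = FALSE]
    nFill <- sample(3:8, cfg@nPairs, replace = TRUE)
    evid <- vapply(seq_len(cfg@nPairs), function(i) {
      paste(c(nm[[ed$head[i]]], verbs[[ed$relation[i]]], nm[[ed$tail[i]]],
              sample(filler, nFill[i], replace = TRUE)), collapse = " ")
    }, character(1))
    nAnn <- round(cfg@annotationFraction * cfg@nPairs)
    annotated <- logical(cfg@nPairs)
    if (nAnn > 0L) annotated[sample.int(cfg@nPairs, nAnn)] <- TRUE
    data.frame(pair_id = sprintf("pair-%05d", seq_len(cfg@nPairs)),
               evidence = evid, head = ed$head, relation = ed$relation,
               tail = ed$tail,
               annotations = I(rep(list(stats::setNames(list(), character(0))),
                                   cfg@nPairs)),
               annotated = annotated, stringsAsFactors = FALSE)
  })
}

#' Attach synthetic task labels to annotation-capable pairs
#'
#' Four label mechanisms cover the ways a classification target can relate
#' to the two modalities:
#' \describe{
#'   \item{relation_determined}{label = relation type modulo `nClasses`;
#'     perfectly predictable from the triple's relation (the polarity /
#'     interaction-type analog).}
#'   \item{node_determined}{label = head-node block modulo `nClasses`; the
#'     sentence carries no class keyword, so the label is invisible to a
#'     text-only model (the species-leakage analog).}
#'   \item{text_determined}{label drawn from `classProbs` and revealed by a
#'     class keyword appended to the sentence; independent of node identity
#'     (the context-annotation analog).}
#'   \item{fused}{a keyword class `k` is drawn and appended, and the label is
#'     `(k + block(head)) mod nClasses` — the modular-sum (XOR for two
#'     classes) of a text bit and a node bit, so neither modality alone
#'     determines the label and each unimodal Bayes accuracy is `1/nClasses`.}
#' }
#'
#' @param pairs a pair table from [generatePairs()] (or any table with an
#'   `annotated` column; without one, all pairs are labeled).
#' @param kg the [KnowledgeGraph-class] the pairs were drawn from.
#' @param taskKind one of the four mechanisms above.
#' @param nClasses number of classes (2..10).
#' @param seed integer seed.
#' @param taskName annotation key; defaults to `taskKind`.
#' @param classProbs class-probability vector for sampled labels
#'   (text_determined / fused keyword classes); default uniform.
#' @return The full pair table with `annotations[[taskName]]` set (labels
#'   `"c0" ... "c<nClasses-1>"`) on labeled rows and keywords appended to
#'   their evidence where the mechanism calls for it.
#' @export
generateTaskLabels <- function(pairs, kg,
                               taskKind = c("text_determined", "node_determined",
                                            "relation_determined", "fused"),
                               nClasses, seed, taskName = NULL,
                               classProbs = NULL) {
  taskKind <- match.arg(taskKind)
  stopifnot(is.data.frame(pairs), is(kg, "KnowledgeGraph"))
  nClasses <- as.integer(nClasses)
  if (nClasses < 2L || nClasses > 10L)
    stop("invalid config: nClasses must lie in 2..10")
  taskName <- taskName %||% taskKind
  if (is.null(classProbs)) classProbs <- rep(1 / nClasses, nClasses)
  if (length(classProbs) != nClasses || any(classProbs < 0))
    stop("invalid config: classProbs must be ", nClasses, " non-negative weights")
  rows <- if ("annotated" %in% names(pairs)) which(pairs$annotated)
          else seq_len(nrow(pairs))
  if (!length(rows)) stop("no annotation-capable pairs to label")
  classes <- paste0("c", seq_len(nClasses) - 1L)

  if (taskKind == "relation_determined") {
    if (length(relations(kg)) < nClasses)
      stop("invalid config: nClasses exceeds distinct realizable labels (",
           length(relations(kg)), " relation types)")
    relIdx <- match(pairs$relation[rows], relations(kg)) - 1L
    lab <- relIdx %% nClasses
  } else if (taskKind == "node_determined") {
    blocks <- nodeBlocks(kg)
    if (length(unique(blocks)) < nClasses)
      stop("invalid config: nClasses exceeds distinct realizable labels (",
           length(unique(blocks)), " node blocks)")
    lab <- as.integer(blocks[pairs$head[rows]]) %% nClasses
  } else {
    lab <- withSeed(deriveSeed(seed, paste0("labels:", taskName)), {
      sample.int(nClasses, length(rows), replace = TRUE, prob = classProbs) - 1L
    })
  }

  # class keywords are task-prefixed so tasks sharing pairs never collide
  if (taskKind == "text_determined") {
    kw <- paste0(taskName, "kw", lab)
    pairs$evidence[rows] <- paste(pairs$evidence[rows], kw)
  } else if (taskKind == "fused") {
    # gated-copy rule: the node bit (head-block parity) gates whether the
    # keyword class is expressed or the label collapses to class 0, so the
    # label is a joint function of both modalities but neither the keyword
    # (Bayes accuracy (n+1)/2n) nor the node bit alone determines it
    blocks <- nodeBlocks(kg)
    nodeBit <- as.integer(blocks[pairs$head[rows]]) %% 2L
    kw <- paste0(taskName, "kw", lab)  # keyword encodes k, not the label
    pairs$evidence[rows] <- paste(pairs$evidence[rows], kw)
    lab <- ifelse(nodeBit == 1L, lab, 0L)
  }

  labChr <- classes[lab + 1L]
  missing <- setdiff(classes, labChr)
  if (length(missing))
    stop("class(es) ", paste(missing, collapse = ", "),
         " received no examples; increase the number of annotated pairs")
  ann <- pairs$annotations
  for (i in seq_along(rows)) {
    a <- ann[[rows[i]]]
    a[[taskName]] <- labChr[i]
    ann[[rows[i]]] <- a
  }
  pairs$annotations <- I(ann)
  attr(pairs$annotations, "class") <- c("AsIs", "list")
  pairs
}
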