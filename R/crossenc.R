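#' Assemble the combined text + KG input for one pair
#'
#' Builds the joint sequence: the tokenized evidence sentence occupies the
#' first `textLen` positions, the triple's embedding sequence the remaining
#' `kgLen`. Segment ids are 0 for the text half and 1 for the KG half;
#' position ids run 0..maxLen-1 across the whole sequence. Walk-mode KG
#' sequences must satisfy `2 * walkLength + 2 == kgLen`; TransE-mode
#' sequences (3 positions) are padded to `kgLen` with `[PAD]` nodes masked
#' out of attention.
#'
#' @param pair one-row pair table (or list with evidence/head/relation/tail).
#' @param model a [CrossEncoder-class].
#' @param kgSequence a [TripleSequence-class] for the pair's triple
#'   (required when the model has a KG half).
#' @param nspLabel optional "matched" or "random" supervision for the
#'   next-"sentence" objective.
#' @param materialize materialize the initial token-embedding rows in
#'   `$embeddings` (skipped inside training loops, which recompute them from
#'   the current tables).
#' @return A `combined_input` list: token ids for both halves, segment /
#'   position ids, attention mask, all-ignore MLM/MEM label slots, the NSP
#'   label, and (if materialized) the initial token-embedding rows.
#' @export
assembleInput <- function(pair, model, kgSequence = NULL, nspLabel = NA,
                          materialize = TRUE) {
  stopifnot(is(model, "CrossEncoder"))
  cfg <- model@config
  tok <- tokenizeText(pair$evidence, model@textVocab, cfg@textLen)
  Kl <- cfg@kgLen
  kgIds <- integer(0); kgMask <- integer(0)
  kgIsRelation <- logical(0); relIds <- integer(0)
  if (Kl > 0L) {
    if (is.null(kgSequence)) stop("kgSequence is required: the model has a KG half")
    stopifnot(is(kgSequence, "TripleSequence"))
    if (kgSequence@mode == "walk") {
      if (length(kgSequence@tokenIds) != Kl)
        stop("invalid config: walk sequence length ", length(kgSequence@tokenIds),
             " (2*L+2) must equal the KG half length ", Kl)
      kgIds <- kgSequence@tokenIds
      kgMask <- rep(1L, Kl)
      kgIsRelation <- rep(FALSE, Kl)
      relIds <- rep(NA_integer_, Kl)
    } else {
      if (Kl < 3L) stop("invalid config: KG half too short for a TransE triple")
      kgIds <- c(kgSequence@tokenIds, rep(NODE_PAD, Kl - 3L))
      kgMask <- c(rep(1L, 3L), rep(0L, Kl - 3L))
      kgIsRelation <- c(FALSE, TRUE, FALSE, rep(FALSE, Kl - 3L))
      relIds <- rep(NA_integer_, Kl)
      ri <- match(kgSequence@tokens[2L], model@relations)
      if (is.na(ri)) {           # relation outside vocabulary: plain [UNK] node
        kgIsRelation[2L] <- FALSE
        kgIds[2L] <- NODE_UNK
      } else relIds[2L] <- ri - 1L
    }
  }
  input <- list(
    textIds = tok@tokenIds,
    kgIds = kgIds,
    kgUseTextMask = rep(FALSE, Kl),
    kgIsRelation = kgIsRelation,
    relIds = relIds,
    segmentIds = c(rep(0L, cfg@textLen), rep(1L, Kl)),
    positionIds = seq_len(cfg@maxLen) - 1L,
    attentionMask = c(tok@attentionMask, kgMask),
    mlmLabels = rep(NA_integer_, cfg@textLen),
    memLabels = rep(NA_integer_, Kl),
    nspLabel = if (is.na(nspLabel)) NA_integer_
               else if (identical(nspLabel, "matched") || identical(nspLabel, 0L)) 0L
               else 1L,
    textVocabSize = cfg@textVocabSize,
    nodeVocabSize = cfg@nodeVocabSize,
    masked = FALSE)
  if (materialize) {
    src <- inputRows(model@weights, cfg, input)
    E <- matrix(0, cfg@maxLen, cfg@hiddenSize)
    for (tb in unique(src$tab)) {
      sel <- src$tab == tb
      M <- switch(tb, text = model@weights$textEmb,
                  node = model@weights$nodeEmb, rel = model@weights$relEmb)
      E[sel, ] <- M[src$row[sel], , drop = FALSE]
    }
    input$embeddings <- E
  }
  class(input) <- "combined_input"
  input
}

#' Apply BERT-style masking to a combined input
#'
#' Each maskable position is selected independently with probability
#' `maskProb`; of the selected positions 80% are replaced by the mask token,
#' 10% by a random id from that half's vocabulary and 10% left unchanged.
#' Text-half maskable positions exclude `[CLS]`, `[SEP]` and `[PAD]`; the
#' KG half's maskable positions are all walk nodes *and* separator positions
#' (the masked-entity vocabulary contains the separator), excluding pads and
#' TransE relation slots. A masked KG position is fed the text-side `[MASK]`
#' embedding vector. Labels record the original id exactly at the selected
#' positions and stay at the ignore marker (`NA`) elsewhere.
#'
#' @param input a `combined_input` from [assembleInput()].
#' @param maskProb selection probability (default 0.15).
#' @param seed optional integer seed.
#' @return The masked `combined_input` with `mlmLabels` / `memLabels` filled.
#' @export
applyMasking <- function(input, maskProb = 0.15, seed = NULL) {
  stopifnot(inherits(input, "combined_input"))
  if (isTRUE(input$masked)) stop("input is already masked")
  if (maskProb < 0 || maskProb > 1) stop("maskProb must lie in [0, 1]")
  withSeed(seed, {
    Tl <- length(input$textIds)
    maskableT <- which(!input$textIds %in% c(TEXT_PAD, TEXT_CLS, TEXT_SEP))
    if (maskProb > 0 && length(maskableT)) {
      sel <- maskableT[runif(length(maskableT)) < maskProb]
      if (length(sel)) {
        input$mlmLabels[sel] <- input$textIds[sel]
        u <- runif(length(sel))
        toMask <- sel[u < 0.8]
        toRand <- sel[u >= 0.8 & u < 0.9]
        input$textIds[toMask] <- TEXT_MASK
        if (length(toRand)) {
          lo <- 5L
          if (input$textVocabSize > lo)
            input$textIds[toRand] <- sample(seq(lo, input$textVocabSize - 1L),
                                            length(toRand), replace = TRUE)
        }
      }
    }
    Kl <- length(input$kgIds)
    if (Kl > 0L) {
      kgAttn <- input$attentionMask[Tl + seq_len(Kl)]
      maskableK <- which(kgAttn > 0L & !input$kgIsRelation)
      if (maskProb > 0 && length(maskableK)) {
        sel <- maskableK[runif(length(maskableK)) < maskProb]
        if (length(sel)) {
          input$memLabels[sel] <- input$kgIds[sel]
          u <- runif(length(sel))
          toMask <- sel[u < 0.8]
          toRand <- sel[u >= 0.8 & u < 0.9]
          input$kgUseTextMask[toMask] <- TRUE
          if (length(toRand)) {
            lo <- 3L            # real nodes start after [PAD],[UNK],[SEP]
            if (input$nodeVocabSize > lo)
              input$kgIds[toRand] <- sample(seq(lo, input$nodeVocabSize - 1L),
                                            length(toRand), replace = TRUE)
          }
        }
      }
    }
    input$masked <- TRUE
    input
  })
}

#' Pre-training loss components
#'
#' Each component is the mean cross-entropy over its supervised positions
#' only (ignore-marker positions contribute nothing); a component with no
#' supervision is 0. The total is `L_MLM + L_MEM + L_NSP`, or
#' `L_MLM + L_MEM` for the `no_nsp` ablation.
#'
#' @param forward output of [crossEncoderForward()].
#' @param input the masked `combined_input` that produced it.
#' @param variant "full" or "no_nsp".
#' @return List with `mlm`, `mem`, `nsp`, `total`.
#' @export
computeLosses <- function(forward, input, variant = c("full", "no_nsp")) {
  variant <- match.arg(variant)
  lMlm <- meanCrossEntropy(softmaxRows(forward$mlmLogits),
                           input$mlmLabels + 1L)
  lMem <- if (is.null(forward$memLogits)) 0 else
    meanCrossEntropy(softmaxRows(forward$memLogits), input$memLabels + 1L)
  lNsp <- if (variant == "no_nsp" || is.na(input$nspLabel)) 0 else {
    p <- softmaxVec(forward$nspLogits)
    -log(max(p[input$nspLabel + 1L], 1e-12))
  }
  total <- lMlm + lMem + (if (variant == "no_nsp") 0 else lNsp)
  list(mlm = lMlm, mem = lMem, nsp = lNsp, total = total)
}

#' Augment a pair corpus with negative next-"sentence" examples
#'
#' All original pairs are kept and labeled "matched"; additionally
#' `round(negativeFraction * n)` synthetic examples labeled "random" are
#' appended, each combining the evidence of one original with the triple of
#' a different original (the combination is guaranteed not to co-occur in
#' any original pair). The default fraction augments by 25% of the original
#' corpus size.
#'
#' @param pairs a pair table (>= 2 rows when `negativeFraction > 0`).
#' @param negativeFraction fraction of negatives to append.
#' @param seed integer seed.
#' @return The augmented pair table with an `nspLabel` column.
#' @export
makeNspExamples <- function(pairs, negativeFraction = 0.25, seed = 1L) {
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  nNeg <- round(negativeFraction * n)
  if (n < 2L && negativeFraction > 0)
    stop("invalid config: need at least 2 pairs to draw negatives")
  out <- pairs
  out$nspLabel <- rep("matched", n)
  if (nNeg > 0L) {
    key <- paste(pairs$evidence, pairs$head, pairs$relation, pairs$tail,
                 sep = "\r")
    negs <- withSeed(deriveSeed(seed, "nsp"), {
      ev <- integer(nNeg); tr <- integer(nNeg)
      for (i in seq_len(nNeg)) {
        repeat {
          a <- sample.int(n, 1L); b <- sample.int(n, 1L)
          if (a == b) next
          cand <- paste(pairs$evidence[a], pairs$head[b], pairs$relation[b],
                        pairs$tail[b], sep = "\r")
          if (!cand %in% key) { ev[i] <- a; tr[i] <- b; break }
        }
      }
      neg <- pairs[tr, , drop = FALSE]
      neg$evidence <- pairs$evidence[ev]
      neg$pair_id <- sprintf("nsp-neg-%05d", seq_len(nNeg))
      neg$annotations <- I(rep(list(emptyAnnotations()), nNeg))
      if ("annotated" %in% names(neg)) neg$annotated <- FALSE
      neg
    })
    negs$nspLabel <- rep("random", nNeg)
    out <- rbind(out, negs)
    rownames(out) <- NULL
  }
  out
}
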