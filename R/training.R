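#' Create a training configuration
#'
#' Defaults are the shared fine-tuning profile: five epochs, batch size 16,
#' AdamW with linearly decreasing learning rate initially 5e-5. Pre-training
#' is usually budgeted in `steps` instead of epochs.
#'
#' @param batchSize minibatch size.
#' @param epochs passes over the data (ignored when `steps > 0`).
#' @param steps absolute optimizer-step budget (0 = use epochs).
#' @param lr initial learning rate (> 0).
#' @param weightDecay decoupled weight decay on matrix-shaped parameters.
#' @param checkpointSteps sorted steps at which to snapshot the weights.
#' @param variant "full", "no_nsp" (drop the NSP objective) or
#'   "transe_input" (TransE triple representation in the KG half).
#' @param seed integer seed.
#' @return A validated [TrainConfig-class].
#' @export
trainConfig <- function(batchSize = 16L, epochs = 5L, steps = 0L, lr = 5e-5,
                        weightDecay = 0.01, checkpointSteps = integer(0),
                        variant = "full", seed = 1L) {
  new("TrainConfig", batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), steps = as.integer(steps),
      lr = as.numeric(lr), weightDecay = as.numeric(weightDecay),
      checkpointSteps = as.integer(checkpointSteps),
      variant = as.character(variant), seed = as.integer(seed))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf("TrainConfig: batch %d, %s, lr %g (linear decay), variant %s\n",
              object@batchSize,
              if (object@steps > 0L) paste(object@steps, "steps")
              else paste(object@epochs, "epochs"),
              object@lr, object@variant))
})

# Build (once) the per-pair combined inputs for a corpus.
prepareInputs <- function(pairs, model, kg, kgBackbone, walkSeed = 1L,
                          withNsp = FALSE) {
  cfg <- model@config
  if (cfg@kgLen == 0L) {
    return(lapply(seq_len(nrow(pairs)), function(i) {
      assembleInput(pairs[i, ], model, materialize = FALSE)
    }))
  }
  transe <- is(kgBackbone, "TranseModel")
  cache <- if (!transe)
    newWalkCache(kg, (cfg@kgLen - 2L) %/% 2L, seed = walkSeed)
  nodeVoc <- if (transe) model@nodeVocab
  lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    seqk <- if (transe) {
      suppressMessages(tripleToTranseSequence(p, kgBackbone, nodeVocab = nodeVoc))
    } else {
      tripleToWalkSequence(p, kgBackbone, kg, length = (cfg@kgLen - 2L) %/% 2L,
                           cache = cache)
    }
    nsp <- if (withNsp && "nspLabel" %in% names(pairs)) p$nspLabel else NA
    assembleInput(p, model, kgSequence = seqk, nspLabel = nsp,
                  materialize = FALSE)
  })
}

#' Pre-train a cross encoder on an unlabeled corpus
#'
#' Runs the joint masked-language / masked-entity / next-"sentence"
#' objective (`L_total = L_MLM + L_MEM + L_NSP`; the `no_nsp` variant drops
#' the last term) with AdamW and a linearly decaying learning rate.
#' Interim checkpoints are snapshots of the same run: the checkpoint at a
#' shared step is weight-identical to the state of the longer run at that
#' step.
#'
#' @param corpus pair table, normally NSP-augmented via [makeNspExamples()]
#'   (an `nspLabel` column; plain corpora are treated as all-matched).
#' @param model an initialized [CrossEncoder-class].
#' @param kg the [KnowledgeGraph-class].
#' @param kgBackbone a [NodeEmbeddingTable-class] (walk variants) or
#'   [TranseModel-class] (`transe_input` variant).
#' @param config a [TrainConfig-class]; `steps` > 0 sets the step budget.
#' @param maskProb masking probability per maskable position.
#' @param metricsPath optional JSON-lines file receiving per-step losses.
#' @return List with `model` (final [CrossEncoder-class]), `checkpoints`
#'   (named list of CrossEncoder snapshots) and `metrics` (data.frame with
#'   step, l_mlm, l_mem, l_nsp, l_total).
#' @export
pretrain <- function(corpus, model, kg, kgBackbone, config,
                     maskProb = 0.15, metricsPath = NULL) {
  stopifnot(is(model, "CrossEncoder"), is(config, "TrainConfig"))
  if (!nrow(corpus)) stop("invalid config: empty pre-training corpus")
  cfg <- model@config
  if (config@variant == "transe_input" && !is(kgBackbone, "TranseModel"))
    stop("variant transe_input requires a TranseModel kgBackbone")
  inputs <- prepareInputs(corpus, model, kg, kgBackbone,
                          walkSeed = deriveSeed(config@seed, "pretrain-walks"),
                          withNsp = TRUE)
  n <- length(inputs)
  nSteps <- if (config@steps > 0L) config@steps
            else config@epochs * ceiling(n / config@batchSize)
  W <- model@weights
  state <- adamInit(W)
  lossVariant <- if (config@variant == "no_nsp") "no_nsp" else "full"
  metrics <- vector("list", nSteps)
  checkpoints <- list()
  if (!is.null(metricsPath) && file.exists(metricsPath)) unlink(metricsPath)
  for (step in seq_len(nSteps)) {
    idx <- withSeed(deriveSeed(config@seed, paste0("batch:", step)), {
      sample.int(n, min(config@batchSize, n),
                 replace = n < config@batchSize)
    })
    batch <- lapply(seq_along(idx), function(j) {
      applyMasking(inputs[[idx[j]]], maskProb = maskProb,
                   seed = deriveSeed(config@seed, paste0("mask:", step, ":", j)))
    })
    bg <- lossAndGradsBatch(W, cfg, batch, variant = lossVariant)
    lrNow <- lrSchedule(config@lr, step, nSteps)
    st <- adamStep(W, clipGrads(bg$grads), state, lrNow,
                   weightDecay = config@weightDecay)
    W <- st$W; state <- st$state
    metrics[[step]] <- data.frame(step = step, l_mlm = bg$losses$mlm,
                                  l_mem = bg$losses$mem, l_nsp = bg$losses$nsp,
                                  l_total = bg$losses$total)
    if (!is.null(metricsPath))
      cat(jsonlite::toJSON(metrics[[step]][1, ], auto_unbox = TRUE,
                           dataframe = "rows"),
          "\n", sep = "", file = metricsPath, append = TRUE)
    if (step %in% config@checkpointSteps) {
      snap <- model; snap@weights <- W
      checkpoints[[paste0("step", step)]] <- snap
    }
  }
  model@weights <- W
  list(model = model, checkpoints = checkpoints,
       metrics = do.call(rbind, metrics))
}

#' Fine-tune an encoder as a classifier for one task
#'
#' Adds a `[CLS]`-pooled linear + softmax head and updates *all* parameters
#' (backbone and head) with AdamW under the configured schedule. With
#' `epochs = 0` the returned head equals its initialization.
#'
#' @param model a pre-trained (or freshly initialized) [CrossEncoder-class];
#'   a text-only encoder (`kgLen = 0`) yields the NLP baseline.
#' @param pairs labeled pair table (annotations carry `task@name`).
#' @param task a [TaskSpec-class].
#' @param config a [TrainConfig-class].
#' @param kg,kgBackbone KG-side plumbing (as in [pretrain()]); ignored for
#'   text-only models.
#' @param freeze character vector of weight names exempt from updates
#'   (e.g. `"nodeEmb"` to keep node embeddings frozen).
#' @return A [Classifier-class].
#' @export
finetune <- function(model, pairs, task, config = trainConfig(), kg = NULL,
                     kgBackbone = NULL, freeze = character(0)) {
  stopifnot(is(model, "CrossEncoder"), is(task, "TaskSpec"),
            is(config, "TrainConfig"))
  labels <- pairLabels(pairs, task@name)
  if (anyNA(labels))
    stop("data error: ", sum(is.na(labels)), " pair(s) lack a '", task@name,
         "' annotation")
  bad <- setdiff(unique(labels), task@classes)
  if (length(bad))
    stop("data error: label(s) outside task classes: ",
         paste(bad, collapse = ", "))
  cfg <- model@config
  labIdx <- match(labels, task@classes)
  walkSeed <- deriveSeed(config@seed, "finetune-walks")
  inputs <- prepareInputs(pairs, model, kg, kgBackbone, walkSeed = walkSeed)
  C <- length(task@classes)
  head <- withSeed(deriveSeed(config@seed, "head-init"), {
    list(W = rmat(cfg@hiddenSize, C), b = rep(0, C))
  })
  W <- model@weights
  W$clsW <- head$W; W$clsB <- head$b
  n <- length(inputs)
  nSteps <- if (config@steps > 0L) config@steps
            else config@epochs * ceiling(n / config@batchSize)
  if (nSteps > 0L) {
    state <- adamInit(W)
    for (step in seq_len(nSteps)) {
      idx <- withSeed(deriveSeed(config@seed, paste0("ft-batch:", step)), {
        sample.int(n, min(config@batchSize, n), replace = n < config@batchSize)
      })
      bg <- lossAndGradsBatch(W, cfg, inputs[idx], mode = "finetune",
                              clsHead = list(W = W$clsW, b = W$clsB),
                              clsLabelIdx = labIdx[idx])
      lrNow <- lrSchedule(config@lr, step, nSteps)
      st <- adamStep(W, clipGrads(bg$grads), state, lrNow,
                     weightDecay = config@weightDecay, freeze = freeze)
      W <- st$W; state <- st$state
    }
  }
  head <- list(W = W$clsW, b = W$clsB)
  W$clsW <- NULL; W$clsB <- NULL
  model@weights <- W
  new("Classifier", type = if (cfg@kgLen > 0L) "cross" else "nlp",
      task = task, encoder = model, head = head,
      kgInput = if (cfg@kgLen == 0L) "none"
                else if (is(kgBackbone, "TranseModel")) "transe" else "walk",
      extra = list(kg = kg, kgBackbone = kgBackbone, walkSeed = walkSeed))
}

#' Dimension-wise max pooling of an embedding sequence
#'
#' Maps a sequence of vectors to the single vector of per-dimension maxima —
#' the pooling used by the static KG baseline.
#'
#' @param embeddings numeric matrix (positions x dims) or a
#'   [TripleSequence-class].
#' @return Numeric vector of column maxima.
#' @export
maxPoolSequence <- function(embeddings) {
  if (is(embeddings, "TripleSequence")) embeddings <- embeddings@embeddings
  if (!nrow(embeddings)) stop("data error: empty sequence")
  apply(embeddings, 2L, max)
}

#' Fit the static KG baseline classifier
#'
#' Pools each triple's embedding sequence by dimension-wise maximum and
#' trains only the linear + softmax head on the pooled vectors; the
#' backbone embeddings stay untouched (static features).
#'
#' @param sequences list of [TripleSequence-class] (equal embedding dims).
#' @param labels character labels parallel to `sequences`.
#' @param task a [TaskSpec-class].
#' @param config a [TrainConfig-class].
#' @return A [Classifier-class] of type "kg" (its `extra$pooledDim` records
#'   the feature dimension).
#' @export
fitKgBaseline <- function(sequences, labels, task, config = trainConfig()) {
  stopifnot(is(task, "TaskSpec"), is(config, "TrainConfig"))
  dims <- vapply(sequences, function(s) ncol(s@embeddings), integer(1))
  if (length(unique(dims)) != 1L)
    stop("data error: ragged embedding dimensions: ",
         paste(unique(dims), collapse = ", "))
  bad <- setdiff(unique(labels), task@classes)
  if (length(bad)) stop("data error: label(s) outside task classes: ",
                        paste(bad, collapse = ", "))
  X <- t(vapply(sequences, maxPoolSequence, numeric(dims[1])))
  y <- match(labels, task@classes)
  C <- length(task@classes)
  head <- withSeed(deriveSeed(config@seed, "kg-head-init"), {
    list(W = rmat(ncol(X), C), b = rep(0, C))
  })
  n <- nrow(X)
  nSteps <- if (config@steps > 0L) config@steps
            else config@epochs * ceiling(n / config@batchSize)
  if (nSteps > 0L) {
    state <- adamInit(head)
    for (step in seq_len(nSteps)) {
      idx <- withSeed(deriveSeed(config@seed, paste0("kg-batch:", step)), {
        sample.int(n, min(config@batchSize, n), replace = n < config@batchSize)
      })
      logits <- addBias(X[idx, , drop = FALSE] %*% head$W, head$b)
      p <- softmaxRows(logits)
      oneHot <- cbind(seq_along(idx), y[idx])
      d <- p; d[oneHot] <- d[oneHot] - 1; d <- d / length(idx)
      g <- list(W = t(X[idx, , drop = FALSE]) %*% d, b = colSums(d))
      lrNow <- lrSchedule(config@lr, step, nSteps)
      st <- adamStep(head, clipGrads(g), state, lrNow,
                     weightDecay = config@weightDecay)
      head <- st$W; state <- st$state
    }
  }
  new("Classifier", type = "kg", task = task, encoder = NULL, head = head,
      kgInput = sequences[[1]]@mode, extra = list(pooledDim = dims[1]))
}

#' Predict task labels for new pairs
#'
#' @param object a [Classifier-class].
#' @param pairs pair table to classify (for type "kg" supply `sequences`,
#'   a list of [TripleSequence-class], instead).
#' @param sequences KG-baseline input sequences.
#' @param ... unused.
#' @return Character vector of predicted class labels; the class-probability
#'   matrix is attached as attribute `"probabilities"`.
#' @export
setMethod("predict", "Classifier", function(object, pairs = NULL,
                                            sequences = NULL, ...) {
  task <- object@task
  if (object@type == "kg") {
    stopifnot(!is.null(sequences))
    X <- t(vapply(sequences, maxPoolSequence,
                  numeric(object@extra$pooledDim)))
    probs <- softmaxRows(addBias(X %*% object@head$W, object@head$b))
  } else {
    stopifnot(!is.null(pairs))
    inputs <- prepareInputs(pairs, object@encoder, object@extra$kg,
                            object@extra$kgBackbone,
                            walkSeed = object@extra$walkSeed %||% 1L)
    probs <- t(vapply(inputs, function(inp) {
      fw <- encoderForwardIds(object@encoder@weights, object@encoder@config, inp)
      poolAndClassify(fw$hidden, object@head)
    }, numeric(length(task@classes))))
  }
  lab <- task@classes[max.col(probs, ties.method = "first")]
  attr(lab, "probabilities") <- probs
  lab
})

setMethod("show", "Classifier", function(object) {
  cat("Classifier (", object@type, ") for task '", object@task@name,
      "' with ", length(object@task@classes), " classes\n", sep = "")
})
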