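#' Describe a fine-tuning task
#'
#' @param name task name (annotation key in the pair tables).
#' @param classes character class labels (2 to 10).
#' @param kind "relation_type", "context_annotation" or "correctness".
#'   Relation-type tasks are excluded for TransE-input models, whose input
#'   encodes the relation directly.
#' @param labelKind the synthetic label mechanism (see
#'   [generateTaskLabels()]).
#' @return A [TaskSpec-class].
#' @export
taskSpec <- function(name, classes, kind, labelKind) {
  if (is.numeric(classes)) classes <- paste0("c", seq_len(classes) - 1L)
  new("TaskSpec", name = name, classes = as.character(classes),
      kind = kind, labelKind = labelKind)
}

setMethod("show", "TaskSpec", function(object) {
  cat("TaskSpec '", object@name, "': ", length(object@classes), " classes, ",
      object@kind, " (", object@labelKind, ")\n", sep = "")
})

#' Is a task excluded for TransE-input models?
#' @param task a [TaskSpec-class].
#' @return Logical.
#' @export
excludedForTranse <- function(task) task@kind == "relation_type"

#' The eight-task benchmark grid
#'
#' Synthetic analogs of the standard eight-task benchmark with matching
#' class counts (2, 2, 10, 10, 5, 3, 2, 8): two relation-type tasks
#' (polarity, interaction type), four context-annotation tasks (cell line,
#' disease, location readable from text; species leaking through node
#' identity) and two correctness-style tasks realized as fused
#' text-and-node labels.
#'
#' @return Named list of [TaskSpec-class].
#' @export
defaultTaskSpecs <- function() {
  specs <- list(
    taskSpec("polarity", 2L, "relation_type", "relation_determined"),
    taskSpec("interaction_type", 2L, "relation_type", "relation_determined"),
    taskSpec("cell_line", 10L, "context_annotation", "text_determined"),
    taskSpec("disease", 10L, "context_annotation", "text_determined"),
    taskSpec("location", 5L, "context_annotation", "text_determined"),
    taskSpec("species", 3L, "context_annotation", "node_determined"),
    taskSpec("correct_binary", 2L, "correctness", "fused"),
    taskSpec("correct_multiclass", 8L, "correctness", "fused"))
  stats::setNames(specs, vapply(specs, function(t) t@name, character(1)))
}

#' Weighted F1 score
#'
#' Average of the per-class F1 scores weighted by the number of true
#' instances per class: `sum_c (n_c / N) * F1_c`, with `F1_c` the harmonic
#' mean of class-c precision and recall. Classes never appearing in the
#' true labels contribute weight 0; a per-class precision, recall or F1
#' with zero denominator is taken as 0.
#'
#' @param true,predicted equal-length label vectors (>= 1 example).
#' @return A number in `[0, 1]`.
#' @export
weightedF1 <- function(true, predicted) {
  if (!length(true)) stop("data error: empty label vector")
  if (length(true) != length(predicted))
    stop("data error: true and predicted labels differ in length")
  true <- as.character(true); predicted <- as.character(predicted)
  out <- 0
  N <- length(true)
  for (cl in unique(true)) {
    tp <- sum(true == cl & predicted == cl)
    fp <- sum(true != cl & predicted == cl)
    fn <- sum(true == cl & predicted != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    out <- out + (tp + fn) / N * f1
  }
  min(max(out, 0), 1)   # guard the accumulated float against 1 + eps
}

#' Relative performance gain, in percent
#'
#' `100 * (a - b) / b`: the gain of the best model variant over the best
#' baseline, expressed as a percentage of the baseline score. Undefined for
#' a zero baseline (returned as `NA` with a warning).
#'
#' @param best best variant score.
#' @param baseline best baseline score (> 0).
#' @return Percentage (may be negative).
#' @export
relativeGain <- function(best, baseline) {
  if (baseline == 0) {
    warning("baseline score is 0; relative gain undefined (reported missing)")
    return(NA_real_)
  }
  100 * (best - baseline) / baseline
}

#' Describe one benchmark entrant
#'
#' @param name model display name.
#' @param type "cross" (multimodal), "nlp" (text-only) or "kg" (static
#'   embedding baseline).
#' @param encoder pre-trained [CrossEncoder-class] (cross / nlp types).
#' @param kgInput "walk" or "transe": how the KG side is represented.
#' @param trainConfig per-model [TrainConfig-class] (default: the shared
#'   fine-tuning profile).
#' @return A `benchmark_model` descriptor.
#' @export
benchmarkModel <- function(name, type = c("cross", "nlp", "kg"),
                           encoder = NULL, kgInput = "walk",
                           trainConfig = NULL) {
  type <- match.arg(type)
  if (type != "kg" && is.null(encoder))
    stop("type '", type, "' requires an encoder")
  structure(list(name = name, type = type, encoder = encoder,
                 kgInput = kgInput, trainConfig = trainConfig),
            class = "benchmark_model")
}

# KG-baseline sequences for a set of pairs (shared walks via cache).
kgBaselineSequences <- function(pairs, kg, kgBackbone, walkLength, walkSeed,
                                nodeVocab = NULL) {
  if (is(kgBackbone, "TranseModel")) {
    lapply(seq_len(nrow(pairs)), function(i) {
      suppressMessages(
        tripleToTranseSequence(pairs[i, ], kgBackbone, nodeVocab = nodeVocab))
    })
  } else {
    cache <- newWalkCache(kg, walkLength, seed = walkSeed)
    lapply(seq_len(nrow(pairs)), function(i) {
      tripleToWalkSequence(pairs[i, ], kgBackbone, kg, length = walkLength,
                           cache = cache)
    })
  }
}

#' Run the cross-validated benchmark
#'
#' For every task, one deterministic stratified k-fold split is created and
#' served to *all* models; each model is trained on k-1 folds and scored by
#' weighted F1 on the held-out fold. TransE-input models are skipped on
#' relation-type tasks (recorded in the result's `excluded` table), since
#' their input encodes the relation directly.
#'
#' @param models list of [benchmarkModel()] descriptors.
#' @param tasks list of [TaskSpec-class].
#' @param datasets named list (by task name) of labeled pair tables.
#' @param kg the [KnowledgeGraph-class].
#' @param kgBackbones named list with entries `walk`
#'   ([NodeEmbeddingTable-class]) and/or `transe` ([TranseModel-class]).
#' @param k fold count (default 5).
#' @param seed integer seed; identical seeds reproduce the identical result
#'   table.
#' @param defaultTrainConfig fallback [TrainConfig-class] for models without
#'   their own.
#' @param kgWalkLength walk length for the static KG baseline's sequences.
#' @param verbose print progress lines.
#' @return A [BenchmarkResult-class].
#' @export
runBenchmark <- function(models, tasks, datasets, kg, kgBackbones, k = 5L,
                         seed = 1L, defaultTrainConfig = trainConfig(),
                         kgWalkLength = 15L, verbose = FALSE) {
  k <- as.integer(k)
  scores <- list(); excluded <- list()
  for (task in tasks) {
    data <- datasets[[task@name]]
    if (is.null(data)) stop("config error: no dataset for task '", task@name, "'")
    labels <- pairLabels(data, task@name)
    split <- makeCvSplits(data, k, seed = deriveSeed(seed, paste0("cv:", task@name)),
                          stratifyBy = labels)
    fold <- split@foldAssignment[data$pair_id]
    walkSeed <- deriveSeed(seed, paste0("bench-walks:", task@name))
    for (mod in models) {
      if (mod$kgInput == "transe" && excludedForTranse(task)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          model = mod$name, task = task@name,
          reason = "excluded: TransE input encodes the relation type",
          stringsAsFactors = FALSE)
        next
      }
      tc <- mod$trainConfig %||% defaultTrainConfig
      backbone <- kgBackbones[[mod$kgInput]]
      for (f in seq_len(k)) {
        trainIdx <- which(fold != f); testIdx <- which(fold == f)
        trainPairs <- data[trainIdx, , drop = FALSE]
        testPairs <- data[testIdx, , drop = FALSE]
        if (mod$type == "kg") {
          walkLength <- kgWalkLength
          trainSeq <- kgBaselineSequences(trainPairs, kg, backbone, walkLength,
                                          walkSeed, nodeVocabulary(kg))
          testSeq <- kgBaselineSequences(testPairs, kg, backbone, walkLength,
                                         walkSeed, nodeVocabulary(kg))
          clf <- fitKgBaseline(trainSeq, pairLabels(trainPairs, task@name),
                               task, tc)
          pred <- predict(clf, sequences = testSeq)
        } else {
          clf <- finetune(mod$encoder, trainPairs, task, tc, kg = kg,
                          kgBackbone = backbone)
          pred <- predict(clf, pairs = testPairs)
        }
        f1 <- weightedF1(pairLabels(testPairs, task@name), pred)
        scores[[length(scores) + 1L]] <- data.frame(
          model = mod$name, task = task@name, fold = f, weighted_f1 = f1,
          stringsAsFactors = FALSE)
        if (verbose)
          message(sprintf("%-18s %-18s fold %d  wF1 = %.3f",
                          mod$name, task@name, f, f1))
      }
    }
  }
  new("BenchmarkResult",
      scores = if (length(scores)) do.call(rbind, scores)
               else data.frame(model = character(0), task = character(0),
                               fold = integer(0), weighted_f1 = numeric(0)),
      excluded = if (length(excluded)) do.call(rbind, excluded)
                 else data.frame(model = character(0), task = character(0),
                                 reason = character(0)),
      k = k)
}

#' Fold-averaged benchmark summary
#'
#' @param result a [BenchmarkResult-class].
#' @return data.frame with one row per (model, task): the per-fold scores'
#'   arithmetic mean in `mean_weighted_f1`.
#' @export
benchmarkSummary <- function(result) {
  stopifnot(is(result, "BenchmarkResult"))
  sc <- result@scores
  if (!nrow(sc)) return(data.frame(model = character(0), task = character(0),
                                   mean_weighted_f1 = numeric(0)))
  ag <- stats::aggregate(weighted_f1 ~ model + task, data = sc, FUN = mean)
  names(ag)[names(ag) == "weighted_f1"] <- "mean_weighted_f1"
  ag[order(ag$task, ag$model), , drop = FALSE]
}

#' Absolute and relative gains of the best variant over the best baseline
#'
#' @param result a [BenchmarkResult-class].
#' @param variantModels names of the model variants under study.
#' @param baselineModels names of the baseline models.
#' @return data.frame per task: best baseline, best variant, absolute gain
#'   and relative gain (percent).
#' @export
benchmarkGains <- function(result, variantModels, baselineModels) {
  sm <- benchmarkSummary(result)
  out <- lapply(unique(sm$task), function(tn) {
    st <- sm[sm$task == tn, ]
    bb <- max(st$mean_weighted_f1[st$model %in% baselineModels], -Inf)
    bv <- max(st$mean_weighted_f1[st$model %in% variantModels], -Inf)
    if (!is.finite(bb) || !is.finite(bv)) return(NULL)
    data.frame(task = tn, best_baseline = bb, best_variant = bv,
               absolute_gain = bv - bb,
               relative_gain_pct = relativeGain(bv, bb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write benchmark tables to TSV
#'
#' `results.tsv` holds the per-fold grid (model, task, fold, weighted_f1);
#' `summary.tsv` the fold-averaged model-by-task means.
#'
#' @param result a [BenchmarkResult-class].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeBenchmarkTsv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result@scores, file.path(dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(benchmarkSummary(result), file.path(dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(result@excluded))
    utils::write.table(result@excluded, file.path(dir, "excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

setMethod("show", "BenchmarkResult", function(object) {
  cat("BenchmarkResult:", nrow(object@scores), "scores over",
      length(unique(object@scores$model)), "models x",
      length(unique(object@scores$task)), "tasks,", object@k, "folds;",
      nrow(object@excluded), "exclusions\n")
  if (nrow(object@scores)) print(utils::head(benchmarkSummary(object), 12L))
})
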