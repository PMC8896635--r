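#' Synthetic-corpus configuration
#'
#' Parameters of the toy knowledge-graph + evidence-sentence generator. The
#' defaults describe the desk-scale study conditions: a graph of 200 grounded
#' nodes in 10 structural blocks, 6 typed relations, mean (total) degree 8,
#' 2000 text-triple pairs of which 15% are annotation-capable — a scaled-down
#' version of the minority-annotated regime of large assembled knowledge
#' bases, where only a small fraction of triples carry curated labels.
#'
#' @slot nNodes number of graph nodes.
#' @slot nRelations number of typed relations.
#' @slot meanDegree target mean total degree (in + out) per node.
#' @slot nPairs number of text-triple pairs to generate.
#' @slot vocabSize number of filler words available to the sentence templates.
#' @slot annotationFraction fraction of pairs that carry task annotations.
#' @slot nBlocks number of structural node blocks (community-like groups).
#' @slot pWithinBlock probability that a sampled edge stays within a block.
#' @slot seed integer seed controlling all generator randomness.
#' @export
setClass("SynthConfig", representation(
  nNodes = "integer", nRelations = "integer", meanDegree = "numeric",
  nPairs = "integer", vocabSize = "integer", annotationFraction = "numeric",
  nBlocks = "integer", pWithinBlock = "numeric", seed = "integer"
), validity = function(object) {
  msg <- character(0)
  if (object@nNodes < 1L) msg <- c(msg, "nNodes must be positive")
  if (object@nRelations < 1L) msg <- c(msg, "nRelations must be positive")
  if (object@meanDegree <= 0) msg <- c(msg, "meanDegree must be positive")
  if (object@nPairs < 0L) msg <- c(msg, "nPairs must be non-negative")
  if (object@vocabSize < 1L) msg <- c(msg, "vocabSize must be positive")
  if (object@annotationFraction < 0 || object@annotationFraction > 1)
    msg <- c(msg, "annotationFraction must lie in [0, 1]")
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be positive")
  if (object@pWithinBlock < 0 || object@pWithinBlock > 1)
    msg <- c(msg, "pWithinBlock must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Knowledge graph of typed, directed triples
#'
#' Nodes are namespace-prefixed identifiers (grounded entities); edges are
#' (head, relation, tail) triples. Adjacency lists (outgoing, incoming and
#' undirected) are precomputed for random-walk sampling. `nodeMeta` carries
#' optional per-node metadata: a human-readable surface `name` (distinct from
#' the identifier, emulating grounding) and a structural `block`.
#'
#' @slot nodes character vector of node identifiers.
#' @slot edges data.frame with character columns head, relation, tail.
#' @slot relations character vector of relation types.
#' @slot nodeMeta data.frame of per-node metadata, rows parallel to `nodes`.
#' @slot adjOut,adjIn,adjUndirected integer adjacency lists (node indices).
#' @export
setClass("KnowledgeGraph", representation(
  nodes = "character", edges = "data.frame", relations = "character",
  nodeMeta = "data.frame", adjOut = "list", adjIn = "list",
  adjUndirected = "list"
), validity = function(object) {
  msg <- character(0)
  ed <- object@edges
  if (!all(c("head", "relation", "tail") %in% names(ed)))
    msg <- c(msg, "edges must have columns head, relation, tail")
  else {
    if (!all(ed$head %in% object@nodes) || !all(ed$tail %in% object@nodes))
      msg <- c(msg, "every edge endpoint must be a node")
    if (nrow(ed) && !all(nzchar(ed$head) & nzchar(ed$relation) & nzchar(ed$tail)))
      msg <- c(msg, "triple fields must be non-empty")
  }
  n <- length(object@nodes)
  if (length(object@adjOut) != n || length(object@adjIn) != n ||
      length(object@adjUndirected) != n)
    msg <- c(msg, "adjacency lists must have one entry per node")
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node identifiers must be unique")
  if (length(msg)) msg else TRUE
})

#' Deterministic cross-validation split
#'
#' @slot k fold count.
#' @slot foldAssignment named integer vector mapping pair_id to a fold in
#'   `1..k`.
#' @export
setClass("CvSplit", representation(
  k = "integer", foldAssignment = "integer"
), validity = function(object) {
  msg <- character(0)
  if (object@k < 2L) msg <- c(msg, "k must be at least 2")
  if (is.null(names(object@foldAssignment)))
    msg <- c(msg, "foldAssignment must be named by pair_id")
  if (length(object@foldAssignment) &&
      (min(object@foldAssignment) < 1L || max(object@foldAssignment) > object@k))
    msg <- c(msg, "fold indices must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' Text vocabulary with reserved special tokens
#'
#' Token ids are 0-based and contiguous; ids 0-4 are the reserved tokens
#' `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` in that order.
#'
#' @slot tokens character vector; element `i` is the token with id `i - 1`.
#' @slot minFreq minimum corpus frequency used when the vocabulary was built.
#' @export
setClass("TextVocabulary", representation(
  tokens = "character", minFreq = "integer"
), validity = function(object) {
  msg <- character(0)
  if (length(object@tokens) < 5L ||
      !identical(object@tokens[1:5], c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")))
    msg <- c(msg, "tokens must start with the reserved [PAD],[UNK],[CLS],[SEP],[MASK]")
  if (anyDuplicated(object@tokens)) msg <- c(msg, "tokens must be unique")
  if (length(msg)) msg else TRUE
})

#' Fixed-length tokenized text
#'
#' @slot tokenIds 0-based token ids of length `targetLength`.
#' @slot attentionMask 0/1 integer vector marking the non-pad prefix.
#' @slot targetLength the fixed length.
#' @export
setClass("TokenizedText", representation(
  tokenIds = "integer", attentionMask = "integer", targetLength = "integer"
), validity = function(object) {
  msg <- character(0)
  if (length(object@tokenIds) != object@targetLength)
    msg <- c(msg, "tokenIds must have length targetLength")
  if (length(object@attentionMask) != object@targetLength)
    msg <- c(msg, "attentionMask must have length targetLength")
  if (length(msg)) msg else TRUE
})

#' Static node-embedding table
#'
#' One row per node-vocabulary entry. The node vocabulary always starts with
#' the reserved entries `[PAD]` (id 0), `[UNK]` (id 1) and `[SEP]` (id 2),
#' followed by the graph's node identifiers; ids are 0-based.
#'
#' @slot vocab character node-token vocabulary (reserved entries first).
#' @slot embeddings numeric matrix, rows parallel to `vocab`.
#' @export
setClass("NodeEmbeddingTable", representation(
  vocab = "character", embeddings = "matrix"
), validity = function(object) {
  msg <- character(0)
  if (length(object@vocab) < 3L ||
      !identical(object@vocab[1:3], c("[PAD]", "[UNK]", "[SEP]")))
    msg <- c(msg, "vocab must start with [PAD],[UNK],[SEP]")
  if (nrow(object@embeddings) != length(object@vocab))
    msg <- c(msg, "one embedding row per vocabulary entry")
  if (anyDuplicated(object@vocab)) msg <- c(msg, "vocab entries must be unique")
  if (length(msg)) msg else TRUE
})

#' Translational (TransE) knowledge-graph embedding model
#'
#' Scores a triple by `|| e_h + e_r - e_t ||_p`; well-trained models assign
#' lower scores to true triples than to corrupted ones. Entity and relation
#' tables each carry an `[UNK]` row used for out-of-vocabulary lookups.
#'
#' @slot entities numeric matrix of entity vectors (rownames = node ids).
#' @slot relationVectors numeric matrix of relation vectors.
#' @slot dim embedding dimension.
#' @slot normOrder 1 or 2, the norm used by the score.
#' @export
setClass("TranseModel", representation(
  entities = "matrix", relationVectors = "matrix", dim = "integer",
  normOrder = "integer"
), validity = function(object) {
  msg <- character(0)
  if (ncol(object@entities) != object@dim ||
      ncol(object@relationVectors) != object@dim)
    msg <- c(msg, "entity/relation vectors must have `dim` columns")
  if (!object@normOrder %in% c(1L, 2L)) msg <- c(msg, "normOrder must be 1 or 2")
  if (!"[UNK]" %in% rownames(object@entities) ||
      !"[UNK]" %in% rownames(object@relationVectors))
    msg <- c(msg, "entity and relation tables must carry an [UNK] row")
  if (length(msg)) msg else TRUE
})

#' Embedding sequence representing one triple
#'
#' In walk mode the sequence is walk(head), [SEP], walk(tail), [SEP] —
#' length `2 * L + 2` for walk length `L`. In TransE mode it is the three
#' vectors (head, relation, tail).
#'
#' @slot tokenIds 0-based ids into the node vocabulary; in TransE mode the
#'   relation position carries the `[UNK]` node id (relations are not part
#'   of the node vocabulary).
#' @slot tokens the token strings (node ids, `[SEP]`, or the relation name).
#' @slot embeddings numeric matrix, one row per position.
#' @slot mode "walk" or "transe".
#' @export
setClass("TripleSequence", representation(
  tokenIds = "integer", tokens = "character", embeddings = "matrix",
  mode = "character"
), validity = function(object) {
  msg <- character(0)
  n <- length(object@tokenIds)
  if (length(object@tokens) != n) msg <- c(msg, "tokens/tokenIds length mismatch")
  if (nrow(object@embeddings) != n) msg <- c(msg, "one embedding row per position")
  if (!object@mode %in% c("walk", "transe")) msg <- c(msg, "mode must be walk or transe")
  if (object@mode == "transe" && n != 3L)
    msg <- c(msg, "TransE sequences have exactly 3 positions")
  if (object@mode == "walk" && (n < 4L || n %% 2L != 0L))
    msg <- c(msg, "walk sequences have length 2L+2")
  if (length(msg)) msg else TRUE
})

#' Transformer architecture configuration
#'
#' The combined input is split into a text half and a KG half
#' (`textLen + kgLen = maxLen`). A text-only encoder uses `kgLen = 0`.
#' `bertBaseProfile()` reproduces the full-scale geometry (512 = 256 + 256);
#' the desk-scale default is 64 = 32 + 32 with hidden size 64.
#'
#' @slot hiddenSize,nLayers,nHeads,ffSize transformer dimensions.
#' @slot maxLen,textLen,kgLen sequence geometry.
#' @slot dropout dropout probability (0 disables; keeps runs deterministic).
#' @slot textVocabSize,nodeVocabSize,nRelations vocabulary sizes.
#' @export
setClass("ModelConfig", representation(
  hiddenSize = "integer", nLayers = "integer", nHeads = "integer",
  ffSize = "integer", maxLen = "integer", textLen = "integer",
  kgLen = "integer", dropout = "numeric", textVocabSize = "integer",
  nodeVocabSize = "integer", nRelations = "integer"
), validity = function(object) {
  msg <- character(0)
  if (object@textLen + object@kgLen != object@maxLen)
    msg <- c(msg, "textLen + kgLen must equal maxLen")
  if (object@hiddenSize %% object@nHeads != 0L)
    msg <- c(msg, "hiddenSize must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@textLen < 2L) msg <- c(msg, "textLen must be at least 2 ([CLS],[SEP])")
  if (length(msg)) msg else TRUE
})

#' Cross encoder (or text-only encoder) with pre-training heads
#'
#' A BERT-style stack of transformer layers applied to the concatenation of a
#' tokenized evidence sentence and a triple's node sequence, with
#' masked-language (MLM), masked-entity (MEM) and next-"sentence" (NSP)
#' prediction heads. When `config@kgLen == 0` the object is the text-only
#' baseline encoder and carries no KG machinery.
#'
#' @slot config a [ModelConfig-class].
#' @slot weights named list of weight tensors.
#' @slot textVocab the [TextVocabulary-class] of the text half.
#' @slot nodeVocab character node-token vocabulary of the KG half.
#' @slot relations character relation vocabulary (TransE-input variant).
#' @export
setClass("CrossEncoder", representation(
  config = "ModelConfig", weights = "list", textVocab = "TextVocabulary",
  nodeVocab = "character", relations = "character"
))

#' Fine-tuning task description
#'
#' @slot name task name.
#' @slot classes class labels.
#' @slot kind one of relation_type, context_annotation, correctness.
#' @slot labelKind the synthetic label mechanism: one of text_determined,
#'   node_determined, relation_determined, fused.
#' @export
setClass("TaskSpec", representation(
  name = "character", classes = "character", kind = "character",
  labelKind = "character"
), validity = function(object) {
  msg <- character(0)
  if (length(object@classes) < 2L || length(object@classes) > 10L)
    msg <- c(msg, "class count must lie in 2..10")
  if (!object@kind %in% c("relation_type", "context_annotation", "correctness"))
    msg <- c(msg, "unknown task kind")
  if (!object@labelKind %in%
      c("text_determined", "node_determined", "relation_determined", "fused"))
    msg <- c(msg, "unknown labelKind")
  if (length(msg)) msg else TRUE
})

#' Trained classifier for one task
#'
#' @slot type "cross", "nlp" or "kg".
#' @slot task the [TaskSpec-class] it was trained for.
#' @slot encoder the fine-tuned [CrossEncoder-class] (cross/nlp types).
#' @slot head list with the linear classification head (W, b).
#' @slot kgInput "walk" or "transe" (how KG halves / baseline features are built).
#' @slot extra list of auxiliary fit information.
#' @export
setClass("Classifier", representation(
  type = "character", task = "TaskSpec", encoder = "ANY", head = "list",
  kgInput = "character", extra = "list"
))

#' Benchmark result grid
#'
#' @slot scores data.frame with columns model, task, fold, weighted_f1.
#' @slot excluded data.frame with columns model, task, reason.
#' @slot k fold count.
#' @export
setClass("BenchmarkResult", representation(
  scores = "data.frame", excluded = "data.frame", k = "integer"
), validity = function(object) {
  msg <- character(0)
  need <- c("model", "task", "fold", "weighted_f1")
  if (!all(need %in% names(object@scores)))
    msg <- c(msg, "scores must have columns model, task, fold, weighted_f1")
  else if (nrow(object@scores) &&
           (min(object@scores$weighted_f1) < 0 || max(object@scores$weighted_f1) > 1))
    msg <- c(msg, "weighted F1 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Training-loop configuration
#'
#' Defaults follow the standard fine-tuning profile: five epochs, batch size
#' 16, AdamW with a linearly decreasing learning rate initially 5e-5.
#'
#' @slot batchSize,epochs,steps loop geometry (`steps` overrides epochs when
#'   positive, as in step-budgeted pre-training).
#' @slot lr,weightDecay AdamW hyperparameters.
#' @slot checkpointSteps sorted ascending steps at which to snapshot weights.
#' @slot variant "full", "no_nsp" or "transe_input".
#' @slot seed integer seed.
#' @export
setClass("TrainConfig", representation(
  batchSize = "integer", epochs = "integer", steps = "integer",
  lr = "numeric", weightDecay = "numeric", checkpointSteps = "integer",
  variant = "character", seed = "integer"
), validity = function(object) {
  msg <- character(0)
  if (object@lr <= 0) msg <- c(msg, "lr must be positive")
  if (is.unsorted(object@checkpointSteps, strictly = TRUE) &&
      length(object@checkpointSteps) > 1L)
    msg <- c(msg, "checkpointSteps must be sorted strictly ascending")
  if (!object@variant %in% c("full", "no_nsp", "transe_input"))
    msg <- c(msg, "variant must be full, no_nsp or transe_input")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be positive")
  if (length(msg)) msg else TRUE
})
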