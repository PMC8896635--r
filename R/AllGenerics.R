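#' @rdname KnowledgeGraph-class
#' @param x object.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("relations", function(x) standardGeneric("relations"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname KnowledgeGraph-class
#' @export
setGeneric("nodeBlocks", function(x) standardGeneric("nodeBlocks"))

#' Vocabulary size (number of distinct ids)
#' @param x a vocabulary-bearing object.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' Embedding dimension of an embedding-bearing object
#' @param x object.
#' @export
setGeneric("embeddingDim", function(x) standardGeneric("embeddingDim"))

#' Map token strings to 0-based ids
#' @param x a vocabulary object.
#' @param tokens character vector.
#' @export
setGeneric("tokenToId", function(x, tokens) standardGeneric("tokenToId"))

#' Map 0-based ids back to token strings
#' @param x a vocabulary object.
#' @param ids integer vector of 0-based ids.
#' @export
setGeneric("idToToken", function(x, ids) standardGeneric("idToToken"))
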