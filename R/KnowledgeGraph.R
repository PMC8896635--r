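#' Construct a KnowledgeGraph from an edge table
#'
#' @param edges data.frame with character columns `head`, `relation`, `tail`.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of edge endpoints (order of first appearance).
#' @param nodeMeta optional data.frame of per-node metadata (columns such as
#'   `name`, `block`), rows parallel to `nodes`.
#' @return A [KnowledgeGraph-class] object with adjacency lists precomputed.
#' @examples
#' kg <- knowledgeGraph(data.frame(head = "toy:0001", relation = "activates",
#'                                 tail = "toy:0002"))
#' numNodes(kg)
#' @export
knowledgeGraph <- function(edges, nodes = NULL, nodeMeta = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cn in c("head", "relation", "tail")) {
    if (!cn %in% names(edges)) stop("edges is missing column '", cn, "'")
    edges[[cn]] <- as.character(edges[[cn]])
  }
  edges <- edges[, c("head", "relation", "tail")]
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- unique(c(rbind(edges$head, edges$tail)))
  nodes <- as.character(nodes)
  if (is.null(nodeMeta)) {
    nodeMeta <- data.frame(name = nodes, block = rep(0L, length(nodes)),
                           stringsAsFactors = FALSE)
  }
  n <- length(nodes)
  hi <- match(edges$head, nodes)
  ti <- match(edges$tail, nodes)
  if (anyNA(hi) || anyNA(ti)) stop("edge endpoint not present in node set")
  adjOut <- adjIn <- adjUn <- rep(list(integer(0)), n)
  if (nrow(edges)) {
    so <- split(ti, factor(hi, levels = seq_len(n)))
    si <- split(hi, factor(ti, levels = seq_len(n)))
    adjOut <- lapply(so, as.integer)
    adjIn <- lapply(si, as.integer)
    adjUn <- mapply(function(a, b) sort(unique(c(a, b))), adjOut, adjIn,
                    SIMPLIFY = FALSE)
  }
  new("KnowledgeGraph", nodes = nodes, edges = edges,
      relations = sort(unique(edges$relation)), nodeMeta = nodeMeta,
      adjOut = unname(adjOut), adjIn = unname(adjIn),
      adjUndirected = unname(adjUn))
}

#' @rdname KnowledgeGraph-class
#' @export
setMethod("nodes", "KnowledgeGraph", function(x) x@nodes)

#' @rdname KnowledgeGraph-class
#' @export
setMethod("edges", "KnowledgeGraph", function(x) x@edges)

#' @rdname KnowledgeGraph-class
#' @export
setMethod("relations", "KnowledgeGraph", function(x) x@relations)

#' @rdname KnowledgeGraph-class
#' @export
setMethod("numNodes", "KnowledgeGraph", function(x) length(x@nodes))

#' @rdname KnowledgeGraph-class
#' @export
setMethod("numEdges", "KnowledgeGraph", function(x) nrow(x@edges))

#' @rdname KnowledgeGraph-class
#' @export
setMethod("nodeNames", "KnowledgeGraph", function(x) {
  stats::setNames(x@nodeMeta$name, x@nodes)
})

#' @rdname KnowledgeGraph-class
#' @export
setMethod("nodeBlocks", "KnowledgeGraph", function(x) {
  stats::setNames(x@nodeMeta$block, x@nodes)
})

setMethod("show", "KnowledgeGraph", function(object) {
  cat("KnowledgeGraph with", length(object@nodes), "nodes,",
      nrow(object@edges), "triples,", length(object@relations),
      "relation types\n")
  if (nrow(object@edges)) {
    ex <- object@edges[1L, ]
    cat("  e.g. (", ex$head, ", ", ex$relation, ", ", ex$tail, ")\n", sep = "")
  }
})

#' Convert a KnowledgeGraph to an igraph object
#'
#' Directed graph with the relation type as an edge attribute; useful for
#' degree/component diagnostics.
#' @param kg a [KnowledgeGraph-class].
#' @return An `igraph` graph.
#' @export
asIgraph <- function(kg) {
  stopifnot(is(kg, "KnowledgeGraph"))
  igraph::graph_from_data_frame(
    data.frame(from = kg@edges$head, to = kg@edges$tail,
               relation = kg@edges$relation, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = kg@nodes, stringsAsFactors = FALSE))
}

#' Read / write a TSV edge list
#'
#' The exchange format is a UTF-8 TSV with header `head`, `relation`,
#' `tail`, one triple per row.
#'
#' @param path file path.
#' @return `readEdgeList()` returns a [KnowledgeGraph-class].
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ed <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          fileEncoding = "UTF-8")
  if (!all(c("head", "relation", "tail") %in% names(ed)))
    stop("edge list must have header: head, relation, tail")
  knowledgeGraph(ed)
}

#' @rdname readEdgeList
#' @param kg a [KnowledgeGraph-class] to serialize.
#' @export
writeEdgeList <- function(kg, path) {
  stopifnot(is(kg, "KnowledgeGraph"))
  utils::write.table(kg@edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Node-token vocabulary of a graph
#'
#' The KG half of a combined input is indexed against this vocabulary:
#' the reserved `[PAD]` (id 0), `[UNK]` (id 1) and `[SEP]` (id 2) entries
#' followed by the graph's node identifiers. The masked-entity head predicts
#' over this same vocabulary, so the separator is a reachable label.
#'
#' @param kg a [KnowledgeGraph-class].
#' @return Character vector of node tokens; ids are positions minus one.
#' @export
nodeVocabulary <- function(kg) {
  stopifnot(is(kg, "KnowledgeGraph"))
  c("[PAD]", "[UNK]", "[SEP]", kg@nodes)
}
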