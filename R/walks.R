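#' Sample a (biased) random walk on a knowledge graph
#'
#' Second-order walk in the node2vec family: edges are traversed as
#' undirected, and given the previous node `s` and current node `v`, a
#' neighbor `x` of `v` is chosen with unnormalized weight `1/p` if `x == s`,
#' `1` if `x` is also a neighbor of `s`, and `1/q` otherwise. With the
#' defaults `p = q = 1` this is the uniform random walk. A node with no
#' traversable neighbor repeats itself until the walk reaches `length`, so
#' walks always have exactly `length` nodes.
#'
#' @param kg a [KnowledgeGraph-class].
#' @param start a node identifier of `kg`.
#' @param length walk length (number of nodes, >= 1).
#' @param p,q node2vec return / in-out parameters.
#' @param seed optional integer seed; the walk is deterministic given it.
#' @return Character vector of `length` node identifiers; the first is
#'   `start` and every consecutive pair is connected in `kg`.
#' @export
sampleWalk <- function(kg, start, length, p = 1, q = 1, seed = NULL) {
  stopifnot(is(kg, "KnowledgeGraph"))
  cur <- match(start, kg@nodes)
  if (is.na(cur)) stop("start node '", start, "' is not in the graph")
  length <- as.integer(length)
  if (length < 1L) stop("walk length must be >= 1")
  adj <- kg@adjUndirected
  withSeed(seed, {
    walk <- integer(length)
    walk[1L] <- cur
    prev <- NA_integer_
    i <- 2L
    while (i <= length) {
      nb <- adj[[cur]]
      if (!length(nb)) {          # dead end: pad by repeating the node
        walk[i:length] <- cur
        break
      }
      nxt <- if (is.na(prev) || (p == 1 && q == 1)) {
        nb[sample.int(length(nb), 1L)]
      } else {
        w <- ifelse(nb == prev, 1 / p,
                    ifelse(nb %in% adj[[prev]], 1, 1 / q))
        nb[sample.int(length(nb), 1L, prob = w)]
      }
      prev <- cur
      cur <- nxt
      walk[i] <- cur
      i <- i + 1L
    }
    kg@nodes[walk]
  })
}

# Per-node walk cache: one walk per node, sampled on first use with a seed
# derived from (seed, node), so a corpus reuses identical walks per node.
newWalkCache <- function(kg, length, p = 1, q = 1, seed = 1L) {
  env <- new.env(parent = emptyenv())
  list(
    get = function(node) {
      key <- node
      if (!is.null(env[[key]])) return(env[[key]])
      w <- if (node %in% kg@nodes) {
        sampleWalk(kg, node, length, p = p, q = q,
                   seed = deriveSeed(seed, paste0("walk:", node)))
      } else rep("[UNK]", length)
      env[[key]] <- w
      w
    },
    reset = function() rm(list = ls(env), envir = env)
  )
}
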