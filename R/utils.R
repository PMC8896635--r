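#' @importFrom stats runif rnorm
#' @importFrom methods new validObject is slot slotNames
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed
#'
#' Mixes a base seed with a character salt so that independent stages of a
#' pipeline (walk sampling, masking, fold shuffling, ...) consume
#' non-overlapping random streams while remaining a pure function of the
#' user-supplied seed. The result always lies in `[0, 2^31 - 2]`.
#'
#' @param seed Integer base seed.
#' @param salt Character scalar naming the consumer.
#' @return A single integer seed.
#' @export
deriveSeed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(paste(salt, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Numerically stable row-wise softmax (max.col avoids apply() overhead).
softmaxRows <- function(m) {
  rmax <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - rmax)
  e / rowSums(e)
}

softmaxVec <- function(v) {
  v <- v - max(v)
  e <- exp(v)
  e / sum(e)
}

# Mean cross-entropy of rows of `probs` against integer class indices
# (1-based). Rows with index NA are ignored; returns 0 when nothing is
# supervised.
meanCrossEntropy <- function(probs, classIdx) {
  keep <- !is.na(classIdx)
  if (!any(keep)) return(0)
  p <- probs[keep, , drop = FALSE]
  idx <- cbind(seq_len(nrow(p)), classIdx[keep])
  -mean(log(pmax(p[idx], 1e-12)))
}

assertScalarNumber <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok) stop("invalid config: '", name, "' must be a single finite number ",
                if (strict) "> " else ">= ", lower, call. = FALSE)
  invisible(x)
}
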