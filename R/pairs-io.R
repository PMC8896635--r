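PAIR_COLUMNS <- c("pair_id", "evidence", "head", "relation", "tail", "annotations")

emptyAnnotations <- function() stats::setNames(list(), character(0))

#' Write text-triple pairs to TSV
#'
#' UTF-8 TSV with header `pair_id, evidence, head, relation, tail,
#' annotations`; the annotations column holds a JSON object of
#' task-name/label entries, or the empty string for unannotated pairs.
#' Tabs or newlines inside fields are rejected rather than escaped so the
#' files stay diff-able.
#'
#' @param pairs a pair table (extra columns such as `annotated` are ignored).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePairs <- function(pairs, path) {
  stopifnot(is.data.frame(pairs))
  miss <- setdiff(PAIR_COLUMNS, names(pairs))
  if (length(miss)) stop("pair table missing column(s): ", paste(miss, collapse = ", "))
  annJson <- vapply(pairs$annotations, function(a) {
    if (length(a) == 0L) "" else
      as.character(jsonlite::toJSON(a, auto_unbox = TRUE))
  }, character(1))
  flat <- data.frame(pairs[setdiff(PAIR_COLUMNS, "annotations")],
                     annotations = annJson, stringsAsFactors = FALSE)
  bad <- vapply(flat, function(col) any(grepl("[\t\n\r]", col)), logical(1))
  if (any(bad)) stop("field values may not contain tabs or newlines (column ",
                     paste(names(flat)[bad], collapse = ", "), ")")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(PAIR_COLUMNS, collapse = "\t"), con)
  if (nrow(flat))
    writeLines(do.call(paste, c(unname(as.list(flat)), sep = "\t")), con)
  invisible(path)
}

#' Read text-triple pairs from TSV
#'
#' Inverse of [writePairs()]: `readPairs(writePairs(x))` reproduces `x`
#' field-by-field. A malformed row (wrong field count) raises an error
#' naming its line number.
#'
#' @param path file path.
#' @return A pair table (data.frame with an `annotations` list column).
#' @export
readPairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file (missing header): ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, PAIR_COLUMNS))
    stop("unexpected header; expected: ", paste(PAIR_COLUMNS, collapse = ", "))
  body <- lines[-1]
  while (length(body) && !nzchar(body[length(body)])) body <- body[-length(body)]
  out <- lapply(seq_along(body), function(i) {
    ln <- body[[i]]
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nTabs <- if (grepl("\t", ln, fixed = TRUE))
      lengths(gregexpr("\t", ln, fixed = TRUE)) else 0L
    nFields <- nTabs + 1L
    length(parts) <- nFields   # restore dropped trailing empty fields
    parts[is.na(parts)] <- ""
    if (nFields != length(PAIR_COLUMNS))
      stop("parse error at line ", i + 1L, ": expected ",
           length(PAIR_COLUMNS), " fields, found ", nFields)
    parts
  })
  if (!length(out)) {
    tab <- emptyPairTable()
    tab$annotated <- NULL
    return(tab)
  }
  m <- do.call(rbind, out)
  ann <- lapply(m[, 6L], function(s) {
    if (!nzchar(s)) emptyAnnotations()
    else {
      a <- jsonlite::fromJSON(s, simplifyVector = FALSE)
      lapply(a, as.character)
    }
  })
  data.frame(pair_id = m[, 1L], evidence = m[, 2L], head = m[, 3L],
             relation = m[, 4L], tail = m[, 5L], annotations = I(ann),
             stringsAsFactors = FALSE)
}

#' Grounding and evidence filter
#'
#' Keeps the pairs whose evidence sentence is non-empty and whose head and
#' tail are both grounded: present in the graph's node set and carrying a
#' namespace prefix (`namespace:id`). Order is preserved and the filter is
#' idempotent.
#'
#' @param pairs a pair table.
#' @param kg a [KnowledgeGraph-class].
#' @return The retained subset of `pairs`.
#' @export
filterPairs <- function(pairs, kg) {
  stopifnot(is.data.frame(pairs), is(kg, "KnowledgeGraph"))
  grounded <- function(x) x %in% nodes(kg) & grepl(":", x, fixed = TRUE)
  keep <- nzchar(trimws(pairs$evidence)) & grounded(pairs$head) &
    grounded(pairs$tail)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition a corpus into pre-training and fine-tuning sides
#'
#' Unannotated pairs form the unlabeled pre-training corpus; annotated pairs
#' are grouped by task name for fine-tuning. A pair annotated for several
#' tasks appears under each of its task keys.
#'
#' @param pairs a filtered pair table.
#' @return `list(pretraining = <pair table>, finetuning = <named list of
#'   pair tables>)`.
#' @export
splitCorpus <- function(pairs) {
  stopifnot(is.data.frame(pairs))
  nAnn <- lengths(pairs$annotations)
  pre <- pairs[nAnn == 0L, , drop = FALSE]
  rownames(pre) <- NULL
  annPairs <- pairs[nAnn > 0L, , drop = FALSE]
  taskNames <- sort(unique(unlist(lapply(annPairs$annotations, names))))
  fine <- lapply(taskNames, function(tn) {
    sel <- vapply(annPairs$annotations, function(a) tn %in% names(a), logical(1))
    out <- annPairs[sel, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  names(fine) <- taskNames
  list(pretraining = pre, finetuning = fine)
}

#' Annotation labels of a pair table for one task
#' @param pairs pair table.
#' @param taskName annotation key.
#' @return Character labels (NA where unannotated for the task).
#' @export
pairLabels <- function(pairs, taskName) {
  vapply(pairs$annotations, function(a) {
    if (taskName %in% names(a)) as.character(a[[taskName]]) else NA_character_
  }, character(1))
}

#' Deterministic k-fold cross-validation split
#'
#' Identical `(ids, k, seed)` always yield the identical assignment, so
#' every model in a benchmark can be served the same folds. Fold sizes
#' differ by at most one; with `stratifyBy`, per-fold class counts differ
#' from perfect proportionality by at most one sample per class.
#'
#' @param x a pair table (uses its `pair_id`) or a character id vector.
#' @param k fold count (>= 2, <= number of ids).
#' @param seed integer seed.
#' @param stratifyBy optional class label vector parallel to the ids.
#' @return A [CvSplit-class].
#' @export
makeCvSplits <- function(x, k, seed, stratifyBy = NULL) {
  ids <- if (is.data.frame(x)) x$pair_id else as.character(x)
  k <- as.integer(k)
  if (anyDuplicated(ids)) stop("duplicate ids in CV input")
  if (length(ids) < k) stop("invalid config: need at least k = ", k,
                            " examples, got ", length(ids))
  fold <- integer(length(ids))
  withSeed(deriveSeed(seed, "makeCvSplits"), {
    if (is.null(stratifyBy)) {
      ord <- sample.int(length(ids))
      fold[ord] <- (seq_along(ord) - 1L) %% k + 1L
    } else {
      stopifnot(length(stratifyBy) == length(ids))
      counter <- 0L
      for (cl in sort(unique(as.character(stratifyBy)))) {
        rows <- which(as.character(stratifyBy) == cl)
        rows <- rows[sample.int(length(rows))]
        fold[rows] <- (counter + seq_along(rows) - 1L) %% k + 1L
        counter <- counter + length(rows)
      }
    }
  })
  new("CvSplit", k = k, foldAssignment = stats::setNames(fold, ids))
}

#' @rdname makeCvSplits
#' @param split a [CvSplit-class].
#' @param fold fold index in `1..k`.
#' @return `foldIds()`: the ids assigned to `fold`.
#' @export
foldIds <- function(split, fold) {
  stopifnot(is(split, "CvSplit"))
  names(split@foldAssignment)[split@foldAssignment == fold]
}

setMethod("show", "CvSplit", function(object) {
  cat("CvSplit:", length(object@foldAssignment), "ids in", object@k,
      "folds (sizes:", paste(tabulate(object@foldAssignment, object@k),
                             collapse = ", "), ")\n")
})
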