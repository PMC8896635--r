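#' Build a whitespace-token vocabulary from a corpus
#'
#' Desk-scale stand-in for a pre-trained subword tokenizer: sentences are
#' split on whitespace and the most frequent tokens (ties broken
#' alphabetically, for determinism) enter the vocabulary after the five
#' reserved tokens `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`, `[MASK]` (ids 0-4).
#' Ids are contiguous from 0. Tokens below `minFreq` map to `[UNK]` at
#' tokenization time.
#'
#' @param corpus character vector of sentences.
#' @param maxSize maximum number of non-reserved tokens.
#' @param minFreq minimum corpus frequency.
#' @return A [TextVocabulary-class].
#' @export
buildVocabulary <- function(corpus, maxSize = Inf, minFreq = 1L) {
  if (!length(corpus) || !any(nzchar(corpus))) stop("corpus must be non-empty")
  toks <- unlist(strsplit(trimws(corpus), "\\s+"))
  toks <- toks[nzchar(toks)]
  tab <- table(toks)
  tab <- tab[tab >= minFreq]
  ord <- order(-as.integer(tab), names(tab))
  keep <- names(tab)[ord]
  if (is.finite(maxSize)) keep <- utils::head(keep, maxSize)
  new("TextVocabulary",
      tokens = c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]", keep),
      minFreq = as.integer(minFreq))
}

#' @rdname TextVocabulary-class
#' @param x a [TextVocabulary-class].
#' @export
setMethod("vocabSize", "TextVocabulary", function(x) length(x@tokens))

#' @rdname TextVocabulary-class
#' @param tokens character tokens.
#' @export
setMethod("tokenToId", "TextVocabulary", function(x, tokens) {
  id <- match(tokens, x@tokens)
  id[is.na(id)] <- 2L           # [UNK] is id 1 (0-based)
  as.integer(id - 1L)
})

#' @rdname TextVocabulary-class
#' @param ids 0-based integer ids.
#' @export
setMethod("idToToken", "TextVocabulary", function(x, ids) {
  x@tokens[as.integer(ids) + 1L]
})

setMethod("show", "TextVocabulary", function(object) {
  cat("TextVocabulary:", length(object@tokens), "tokens",
      "(5 reserved), minFreq =", object@minFreq, "\n")
})

# Reserved 0-based ids shared across the package.
TEXT_PAD <- 0L; TEXT_UNK <- 1L; TEXT_CLS <- 2L; TEXT_SEP <- 3L; TEXT_MASK <- 4L
NODE_PAD <- 0L; NODE_UNK <- 1L; NODE_SEP <- 2L

#' Tokenize a sentence to a fixed-length id sequence
#'
#' Produces `[CLS] tokens... [SEP]` padded with `[PAD]` to `targetLength`;
#' longer sentences are truncated keeping the leading tokens (evidence is
#' sentence-level, so the head of the sentence carries the relation mention)
#' and the kept span always terminates with `[SEP]`. The attention mask is 1
#' exactly on the non-pad prefix.
#'
#' @param text a sentence.
#' @param vocab a [TextVocabulary-class].
#' @param targetLength fixed output length (>= 2).
#' @return A [TokenizedText-class].
#' @export
tokenizeText <- function(text, vocab, targetLength) {
  stopifnot(is(vocab, "TextVocabulary"))
  targetLength <- as.integer(targetLength)
  if (targetLength < 2L) stop("targetLength must be at least 2")
  words <- strsplit(trimws(text), "\\s+")[[1]]
  words <- words[nzchar(words)]
  ids <- c(TEXT_CLS, tokenToId(vocab, words), TEXT_SEP)
  if (length(ids) > targetLength)
    ids <- c(ids[seq_len(targetLength - 1L)], TEXT_SEP)
  mask <- c(rep(1L, length(ids)), rep(0L, targetLength - length(ids)))
  ids <- c(ids, rep(TEXT_PAD, targetLength - length(ids)))
  new("TokenizedText", tokenIds = as.integer(ids),
      attentionMask = as.integer(mask), targetLength = targetLength)
}

#' Recover token strings from a tokenized sequence
#'
#' Drops specials and padding; the round trip
#' `detokenize(tokenizeText(s, v, L), v)` recovers the in-vocabulary token
#' strings of `s` (out-of-vocabulary words come back as `[UNK]`).
#'
#' @param tokenized a [TokenizedText-class].
#' @param vocab the [TextVocabulary-class] used to tokenize.
#' @return Character vector of tokens.
#' @export
detokenize <- function(tokenized, vocab) {
  stopifnot(is(tokenized, "TokenizedText"), is(vocab, "TextVocabulary"))
  ids <- tokenized@tokenIds
  ids <- ids[!ids %in% c(TEXT_PAD, TEXT_CLS, TEXT_SEP, TEXT_MASK)]
  idToToken(vocab, ids)
}

#' Look up token embeddings for an id sequence
#'
#' One vector per position; `[PAD]` (id 0) embeds to the table's pad row.
#' Out-of-range ids are a hard error.
#'
#' @param tokenIds 0-based integer ids.
#' @param embeddingTable numeric matrix with one row per vocabulary id.
#' @return Numeric matrix with `length(tokenIds)` rows.
#' @export
embedTokens <- function(tokenIds, embeddingTable) {
  tokenIds <- as.integer(tokenIds)
  if (any(tokenIds < 0L) || any(tokenIds >= nrow(embeddingTable)))
    stop("token id out of range for embedding table with ",
         nrow(embeddingTable), " rows")
  embeddingTable[tokenIds + 1L, , drop = FALSE]
}

#' Read / write a vocabulary file (one token per line; line i = id i - 1)
#' @param vocab a [TextVocabulary-class].
#' @param path file path.
#' @export
writeVocabulary <- function(vocab, path) {
  writeLines(vocab@tokens, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(path) {
  new("TextVocabulary", tokens = readLines(path, encoding = "UTF-8"),
      minFreq = 1L)
}
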