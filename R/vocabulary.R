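# Token vocabulary with reserved BOS/EOS/PAD symbols and fixed-length
# integer encoding of SMILES token streams.

BOS_TOKEN <- "<bos>"
EOS_TOKEN <- "<eos>"
PAD_TOKEN <- "<pad>"

#' Build a vocabulary from a corpus of canonical SMILES
#'
#' The token set is exactly the set of tokens occurring in the corpus, in
#' deterministic sorted order, preceded by the reserved `<pad>`, `<bos>`,
#' `<eos>` symbols (ids 1, 2, 3). Rebuilding on the same corpus always
#' yields an identical mapping, so checkpoints are portable.
#'
#' @param corpus character vector of canonical SMILES (non-empty)
#' @return a `clm_vocabulary` object
#' @export
build_vocabulary <- function(corpus) {
  stopifnot(length(corpus) > 0)
  toks <- sort(unique(unlist(lapply(corpus, tokenize_smiles))),
               method = "radix")
  all_tokens <- c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN, toks)
  structure(list(tokens = all_tokens,
                 index = stats::setNames(seq_along(all_tokens), all_tokens),
                 pad_id = 1L, bos_id = 2L, eos_id = 3L),
            class = "clm_vocabulary")
}

#' @export
print.clm_vocabulary <- function(x, ...) {
  cat(sprintf("<clm_vocabulary: %d tokens (%d reserved)>\n",
              length(x$tokens), 3L))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

#' Encode a token stream to padded integer ids
#'
#' Layout: `[BOS] tokens [EOS] [PAD ...]`, total length
#' `content_length + 2`.
#'
#' @param tokens character vector of SMILES tokens (may be empty)
#' @param vocab a [build_vocabulary()] result
#' @param content_length fixed number of content-token slots (default 100)
#' @return integer vector of length `content_length + 2`
#' @export
encode_sequence <- function(tokens, vocab, content_length = 100L) {
  stopifnot(inherits(vocab, "clm_vocabulary"))
  if (length(tokens) > content_length) {
    stop(sprintf("sequence of %d tokens exceeds content length %d",
                 length(tokens), content_length))
  }
  unknown <- setdiff(tokens, vocab$tokens)
  if (length(unknown)) {
    stop(sprintf("token(s) not in vocabulary: %s",
                 paste(unique(unknown), collapse = ", ")), call. = FALSE)
  }
  ids <- c(vocab$bos_id, unname(vocab$index[tokens]), vocab$eos_id)
  c(ids, rep(vocab$pad_id, content_length + 2L - length(ids)))
}

#' Decode padded ids back to tokens
#'
#' Strips BOS/EOS/PAD; inverse of [encode_sequence()] for in-vocabulary
#' tokens.
#'
#' @param ids integer id vector
#' @param vocab the vocabulary used for encoding
#' @return character vector of content tokens
#' @export
decode_sequence <- function(ids, vocab) {
  toks <- vocab$tokens[ids]
  toks[!toks %in% c(BOS_TOKEN, EOS_TOKEN, PAD_TOKEN)]
}

#' Encode a whole corpus into an id matrix
#'
#' @param corpus character vector of canonical SMILES
#' @param vocab vocabulary
#' @param content_length content slots per sequence; `"auto"` uses the
#'   longest sequence in the corpus
#' @return integer matrix, one row per molecule, `content_length + 2` columns
#' @export
encode_corpus <- function(corpus, vocab, content_length = 100L) {
  tok <- lapply(corpus, tokenize_smiles)
  if (identical(content_length, "auto")) {
    content_length <- max(lengths(tok))
  }
  out <- t(vapply(tok, encode_sequence, integer(content_length + 2L),
                  vocab = vocab, content_length = content_length))
  rownames(out) <- corpus
  out
}

#' Write / read a vocabulary as a plain-text token-per-line file
#'
#' Reserved tokens come first; the round trip is bit-exact.
#'
#' @param vocab vocabulary object
#' @param path file path
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tokens <- readLines(path)
  stopifnot(identical(tokens[1:3], c(PAD_TOKEN, BOS_TOKEN, EOS_TOKEN)))
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens),
                 pad_id = 1L, bos_id = 2L, eos_id = 3L),
            class = "clm_vocabulary")
}
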