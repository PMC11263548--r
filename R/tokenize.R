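# SMILES tokenization. Token classes, in precedence order:
#   bracket atoms `[...]`  >  `%nn` two-digit ring labels  >  Cl / Br  >
#   single characters.
# Concatenating the tokens always reproduces the input string, so
# detokenization is plain `paste0`.

#' Tokenize a SMILES string
#'
#' @param s a single non-empty SMILES string
#' @return character vector of tokens whose concatenation equals `s`
#' @examples
#' tokenize_smiles("c1ccccc1Cl")
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (!nzchar(s)) stop("cannot tokenize an empty SMILES string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("unterminated bracket atom starting at position %d in '%s'",
                     i, s), call. = FALSE)
      }
      tokens <- c(tokens, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "%" && i + 2L <= n &&
               grepl("^[0-9][0-9]$", paste0(chars[i + 1L], chars[i + 2L]))) {
      tokens <- c(tokens, paste0(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch == "C" && i < n && chars[i + 1L] == "l") {
      tokens <- c(tokens, "Cl"); i <- i + 2L
    } else if (ch == "B" && i < n && chars[i + 1L] == "r") {
      tokens <- c(tokens, "Br"); i <- i + 2L
    } else {
      tokens <- c(tokens, ch); i <- i + 1L
    }
  }
  tokens
}

#' Reassemble tokens into a SMILES string
#'
#' Inverse of [tokenize_smiles()] on any accepted input.
#'
#' @param tokens character vector of tokens
#' @return a single string
#' @export
detokenize_smiles <- function(tokens) paste0(tokens, collapse = "")

#' Count SMILES tokens
#'
#' @param s a SMILES string
#' @return integer token count
#' @export
n_smiles_tokens <- function(s) length(tokenize_smiles(s))
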