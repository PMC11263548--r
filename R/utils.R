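#' @keywords internal
#' @useDynLib s4clm, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom Matrix sparseMatrix
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# numerically stable log-sum-exp over rows of a matrix
logsumexp_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

gelu <- function(x) {
  # tanh approximation of the Gaussian error linear unit
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

gelu_grad <- function(x) {
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * c0 * (1 + 3 * 0.044715 * x^2)
}

#' Deterministic hash of a character vector
#'
#' Used to fingerprint vocabularies inside checkpoints so that models are
#' never scored or fine-tuned with a mismatched token mapping.
#'
#' @param x character vector
#' @return a 32-character md5 string
#' @export
vocab_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(x), f, useBytes = TRUE)
  unname(tools::md5sum(f))
}

s4clm_log <- function(level, stage, msg) {
  if (isTRUE(getOption("s4clm.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %-5s %s: %s",
                  format(Sys.time(), "%H:%M:%S"), level, stage, msg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
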