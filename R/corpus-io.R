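# Corpus file I/O: plain text (one SMILES per line, UTF-8) and CSV with a
# named SMILES column plus optional activity labels.

#' Read a SMILES corpus
#'
#' @param path file path; `.csv` files must have a header row
#' @param smiles_col,label_col column names for CSV input
#' @return for plain text, a character vector; for CSV, a list with
#'   `smiles` and (if present) `labels`
#' @export
read_smiles <- function(path, smiles_col = "smiles", label_col = "label") {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!smiles_col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", smiles_col, path),
           call. = FALSE)
    }
    out <- list(smiles = as.character(df[[smiles_col]]))
    if (label_col %in% names(df)) out$labels <- df[[label_col]]
    if (length(out$smiles) == 0L) warning("empty corpus file: ", path)
    return(out)
  }
  x <- readLines(path)
  x <- x[nzchar(x)]
  if (length(x) == 0L) warning("empty corpus file: ", path)
  x
}

#' Write a SMILES corpus
#'
#' Plain-text output round-trips byte-identically through [read_smiles()].
#'
#' @param smiles character vector
#' @param path destination; a `.csv` suffix selects CSV output
#' @param labels optional label vector for CSV output
#' @export
write_smiles <- function(smiles, path, labels = NULL) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
    if (!is.null(labels)) df$label <- labels
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(smiles, path, useBytes = TRUE)
  }
  invisible(path)
}
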