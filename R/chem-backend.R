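# Bridge to the bundled RDKit helper script. All chemistry that is standard
# toolkit work (canonicalization with valence checks, descriptors, Morgan
# fingerprints, Bemis-Murcko scaffolds, substructure search) is delegated to
# RDKit in batch; results come back line-aligned with the input.

chem_env <- new.env(parent = emptyenv())

chem_python <- function() {
  p <- getOption("s4clm.python", Sys.which("python"))
  if (!nzchar(p)) stop("no `python` interpreter found on PATH", call. = FALSE)
  p
}

chem_script <- function() {
  f <- system.file("python", "chem_tools.py", package = "s4clm")
  if (!nzchar(f)) {
    # during development (pkgload) inst/ may not be flattened
    f <- system.file("inst", "python", "chem_tools.py", package = "s4clm")
  }
  if (!nzchar(f)) stop("chem_tools.py not found in installed package")
  f
}

#' Low-level call into the RDKit helper
#'
#' @param cmd helper subcommand
#' @param smiles character vector of SMILES (one call handles the batch)
#' @param args extra command-line arguments for the helper
#' @return character vector of raw result lines, aligned with `smiles`
#' @keywords internal
chem_call <- function(cmd, smiles, args = character()) {
  if (length(smiles) == 0L) return(character())
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)))
  writeLines(smiles, fin, useBytes = TRUE)
  status <- system2(chem_python(),
                    c(shQuote(chem_script()), cmd, shQuote(fin), shQuote(fout), args),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop(sprintf("RDKit helper failed (command '%s', status %s)", cmd, status),
         call. = FALSE)
  }
  readLines(fout)
}

#' Morgan (extended-connectivity) fingerprints
#'
#' @param smiles character vector of SMILES
#' @param radius circular radius in bonds (default 3)
#' @param nbits folded length (default 2048)
#' @return logical matrix of dim `length(smiles) x nbits`; rows of
#'   unparseable molecules are all-`NA`
#' @export
morgan_fingerprints <- function(smiles, radius = 3L, nbits = 2048L) {
  lines <- chem_call("fingerprint", smiles,
                     c("--radius", radius, "--nbits", nbits))
  out <- matrix(NA, nrow = length(smiles), ncol = nbits)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (parts[[i]][1] == "1") {
      out[i, ] <- strsplit(parts[[i]][2], "", fixed = TRUE)[[1]] == "1"
    }
  }
  rownames(out) <- smiles
  out
}

#' Bemis-Murcko scaffolds
#'
#' Acyclic molecules yield the empty scaffold `""`.
#'
#' @param smiles character vector of valid SMILES
#' @return character vector of canonical scaffold SMILES (`NA` on failure)
#' @export
murcko_scaffolds <- function(smiles) {
  lines <- chem_call("scaffold", smiles)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vapply(parts, function(p) if (p[1] == "1") p[2] %||% "" else NA_character_,
         character(1))
}

#' Substructure match against a SMARTS pattern
#'
#' @param smiles character vector
#' @param smarts a single SMARTS pattern
#' @return logical vector (`NA` for unparseable SMILES)
#' @export
has_substructure <- function(smiles, smarts) {
  lines <- chem_call("substruct", smiles, c("--smarts", shQuote(smarts)))
  ifelse(lines == "NA", NA, lines == "1")
}

# parse/valence diagnostics used by the error taxonomy:
# returns data.frame(parse_ok, sanitize_ok)
chem_sanitize_info <- function(smiles) {
  lines <- chem_call("sanitize", smiles)
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(parse_ok = parts[, 1] == "1", sanitize_ok = parts[, 2] == "1")
}

#' Tanimoto similarity matrix between two fingerprint sets
#'
#' @param fp_a,fp_b logical fingerprint matrices (rows = molecules) as
#'   returned by [morgan_fingerprints()]
#' @return numeric matrix `nrow(fp_a) x nrow(fp_b)`
#' @export
tanimoto_matrix <- function(fp_a, fp_b = fp_a) {
  a <- fp_a * 1; b <- fp_b * 1
  inter <- tcrossprod(a, b)
  ca <- rowSums(a); cb <- rowSums(b)
  uni <- outer(ca, cb, "+") - inter
  sim <- inter / uni
  sim[uni == 0] <- 0   # two empty fingerprints: define similarity 0
  sim
}
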