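# Canonicalization, validation and corpus curation.
#
# Validity follows RDKit's sanitization (aromaticity perception + valence
# checks), the de facto standard in the field. Curation mirrors the usual
# chemical-language-model preprocessing: restrict to a fixed organic element
# set, strip salts then discard remaining multi-fragment entries, remove
# stereochemistry and (trivially removable) charges, and keep only molecules
# whose canonical SMILES has at most `max_tokens` tokens.

#' Canonicalize and validate SMILES strings
#'
#' Never errors on unparseable input; such records come back with
#' `valid = FALSE` and an absent canonical form.
#'
#' @param smiles character vector of raw SMILES
#' @param strip_stereo drop stereochemistry annotations (default `FALSE` here;
#'   curation turns it on)
#' @param strip_charge neutralize trivially protonatable/deprotonatable
#'   centers; molecules whose charge cannot be removed that way are invalid
#'   under curation
#' @param strip_salts remove known counter-ion fragments, then treat any
#'   remaining multi-fragment entry as invalid
#' @return a data.frame (one row per input) with columns `raw`, `canonical`
#'   (NA when invalid), `valid`, `n_tokens`
#' @export
canonicalize_and_validate <- function(smiles, strip_stereo = FALSE,
                                      strip_charge = FALSE,
                                      strip_salts = FALSE) {
  flags <- c(if (strip_stereo) "--strip-stereo",
             if (strip_charge) "--strip-charge",
             if (strip_salts) "--strip-salts")
  lines <- chem_call("canon", smiles, flags)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  valid <- vapply(parts, function(p) p[1] == "1", logical(1))
  canonical <- vapply(parts, function(p) if (p[1] == "1") p[2] else NA_character_,
                      character(1))
  n_tokens <- integer(length(smiles))
  for (i in seq_along(smiles)) {
    n_tokens[i] <- if (valid[i]) {
      length(tokenize_smiles(canonical[i]))
    } else if (nzchar(smiles[i])) {
      # token count of the raw string, best effort (0 if untokenizable)
      tryCatch(length(tokenize_smiles(smiles[i])), error = function(e) 0L)
    } else 0L
  }
  data.frame(raw = smiles, canonical = canonical, valid = valid,
             n_tokens = n_tokens, stringsAsFactors = FALSE)
}

#' Curation policy
#'
#' @param allowed_elements element symbols a molecule may contain (hydrogens
#'   are implicit and always allowed)
#' @param max_tokens maximum canonical-SMILES token count
#' @param strip_stereo,strip_charge,strip_salts preprocessing switches
#' @return a `curation_policy` list
#' @export
curation_policy <- function(allowed_elements = c("C", "H", "O", "N", "S", "P",
                                                 "F", "Cl", "Br", "I"),
                            max_tokens = 100L,
                            strip_stereo = TRUE,
                            strip_charge = TRUE,
                            strip_salts = TRUE) {
  stopifnot(length(allowed_elements) > 0, max_tokens > 0)
  structure(list(allowed_elements = allowed_elements,
                 max_tokens = as.integer(max_tokens),
                 strip_stereo = isTRUE(strip_stereo),
                 strip_charge = isTRUE(strip_charge),
                 strip_salts = isTRUE(strip_salts)),
            class = "curation_policy")
}

# elements present in a canonical SMILES, read off its tokens
smiles_elements <- function(canonical) {
  toks <- tokenize_smiles(canonical)
  els <- character(0)
  for (tk in toks) {
    if (startsWith(tk, "[")) {
      m <- regmatches(tk, regexpr("[A-Za-z][a-z]?", sub("^\\[[0-9]*", "", tk)))
      if (length(m)) els <- c(els, m)
    } else if (grepl("^[A-Za-z]", tk)) {
      els <- c(els, tk)
    }
  }
  # aromatic lowercase -> element symbol
  up <- c(b = "B", c = "C", n = "N", o = "O", p = "P", s = "S",
          se = "Se", si = "Si", te = "Te", as = "As")
  ifelse(els %in% names(up), up[els], els)
}

#' Curate a SMILES corpus
#'
#' Applies the policy and returns the deduplicated canonical SMILES that
#' survive: valid molecules over the allowed elements only, stereochemistry
#' and charges removed, salts stripped (remaining multi-fragment entries
#' discarded), canonical token count within the limit.
#'
#' Curation is idempotent: running it on its own output changes nothing.
#'
#' @param smiles character vector of raw SMILES
#' @param policy a [curation_policy()]
#' @return character vector of curated canonical SMILES (possibly empty,
#'   with a warning)
#' @export
curate_corpus <- function(smiles, policy = curation_policy()) {
  stopifnot(inherits(policy, "curation_policy"))
  rec <- canonicalize_and_validate(smiles,
                                   strip_stereo = policy$strip_stereo,
                                   strip_charge = policy$strip_charge,
                                   strip_salts = policy$strip_salts)
  keep <- rec$valid & rec$n_tokens <= policy$max_tokens
  out <- rec$canonical[keep]
  if (length(out)) {
    allowed <- unique(c(policy$allowed_elements, "H"))
    ok_el <- vapply(out, function(s) all(smiles_elements(s) %in% allowed),
                    logical(1))
    out <- out[ok_el]
  }
  out <- out[!duplicated(out)]
  if (length(out) == 0L) warning("curation removed every molecule")
  unname(out)
}
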