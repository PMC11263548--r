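# Synthetic data generation: grammar-valid SMILES corpora, planted
# bioactivity sets and controlled-error invalid strings, so every pipeline
# stage is testable without external databases.
#
# The corpus generator builds molecules constructively -- atoms are placed
# with explicit valence bookkeeping and rings come from closed templates --
# so every emitted string parses as a valid molecule by construction; the
# final canonical forms are produced (and verified) by the standard
# toolkit.

#' Grammar specification for the synthetic corpus generator
#'
#' @param alphabet chain-atom alphabet (subset of the default curation
#'   elements; aromatic/ring atoms come from built-in templates)
#' @param branch_prob probability of opening a branch at a chain atom
#' @param ring_prob probability that a unit is a ring template
#' @param halogen_prob probability of a terminal halogen decoration
#' @param mean_atoms,sd_atoms,min_atoms,max_atoms heavy-atom budget
#'   distribution (Gaussian, clipped)
#' @param max_tokens hard cap on the token length of emitted strings
#' @param seed default rng seed
#' @return a `grammar_spec` list
#' @export
grammar_spec <- function(alphabet = c("C", "C", "C", "N", "O"),
                         branch_prob = 0.25, ring_prob = 0.15,
                         halogen_prob = 0.08,
                         mean_atoms = 16, sd_atoms = 5,
                         min_atoms = 4, max_atoms = 32,
                         max_tokens = 100L, seed = 1L) {
  stopifnot(branch_prob >= 0, branch_prob <= 1, ring_prob >= 0,
            ring_prob <= 1, min_atoms >= 1, max_atoms >= min_atoms)
  structure(list(alphabet = alphabet, branch_prob = branch_prob,
                 ring_prob = ring_prob, halogen_prob = halogen_prob,
                 mean_atoms = mean_atoms, sd_atoms = sd_atoms,
                 min_atoms = min_atoms, max_atoms = max_atoms,
                 max_tokens = as.integer(max_tokens),
                 seed = as.integer(seed)),
            class = "grammar_spec")
}

# ring templates; "<d>" is the ring-closure digit, "<t>" an optional
# continuation slot on a ring atom. All templates are closed, valence-safe
# units whose head atom spends one bond on the preceding chain atom.
RING_TEMPLATES <- list(
  list(plain = "c<d>ccccc<d>",  tail = "c<d>ccc(<t>)cc<d>"),     # benzene
  list(plain = "c<d>ccncc<d>",  tail = "c<d>ccc(<t>)nc<d>"),     # pyridine
  list(plain = "C<d>CCCCC<d>",  tail = "C<d>CCC(<t>)CC<d>"),     # cyclohexane
  list(plain = "C<d>CCCC<d>",   tail = "C<d>CCC(<t>)C<d>"),      # cyclopentane
  list(plain = "c<d>ccoc<d>",   tail = "c<d>cc(<t>)oc<d>")       # furan
)

HALOGENS <- c("F", "F", "Cl")

# recursively emit a chain; `budget` is an environment carrying the
# remaining heavy-atom allowance, `digit` the next free ring label
gen_chain <- function(spec, budget, digit, depth = 0L, has_prev = FALSE) {
  out <- character(0)
  first <- !has_prev
  repeat {
    if (budget$n <= 0L) break
    use_ring <- spec$ring_prob > 0 && digit <= 9L && budget$n >= 6L &&
      stats::runif(1) < spec$ring_prob
    if (use_ring) {
      tpl <- RING_TEMPLATES[[sample.int(length(RING_TEMPLATES), 1L)]]
      budget$n <- budget$n - 6L
      with_tail <- budget$n >= 2L && stats::runif(1) < 0.5 && digit < 9L
      if (with_tail) {
        tail_str <- gen_chain(spec, budget, digit + 1L, depth + 1L, has_prev = TRUE)
        if (nzchar(tail_str)) {
          out <- c(out, gsub("<t>", tail_str,
                             gsub("<d>", digit, tpl$tail, fixed = TRUE),
                             fixed = TRUE))
        } else {
          out <- c(out, gsub("<d>", digit, tpl$plain, fixed = TRUE))
        }
      } else {
        out <- c(out, gsub("<d>", digit, tpl$plain, fixed = TRUE))
      }
      first <- FALSE
      if (stats::runif(1) < 0.5) break   # rings often terminate a chain
      next
    }
    atom <- sample(spec$alphabet, 1L)
    budget$n <- budget$n - 1L
    cap <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)[[atom]]
    used <- (if (first) 0L else 1L) + 1L  # bond to previous + bond to next
    piece <- atom
    # carbonyl decoration on carbons with spare valence
    if (atom == "C" && cap - used >= 2L && budget$n >= 1L &&
        stats::runif(1) < 0.15) {
      piece <- paste0(piece, "(=O)")
      budget$n <- budget$n - 1L
      used <- used + 2L
    }
    # branch
    if (cap - used >= 1L && budget$n >= 2L && depth < 4L &&
        stats::runif(1) < spec$branch_prob) {
      br <- gen_chain(spec, budget, digit, depth + 1L, has_prev = TRUE)
      if (nzchar(br)) {
        piece <- paste0(piece, "(", br, ")")
        used <- used + 1L
      }
    }
    # terminal halogen
    if (atom == "C" && cap - used >= 1L && budget$n >= 1L &&
        stats::runif(1) < spec$halogen_prob) {
      piece <- paste0(piece, "(", sample(HALOGENS, 1L), ")")
      budget$n <- budget$n - 1L
      used <- used + 1L
    }
    out <- c(out, piece)
    first <- FALSE
    if (budget$n <= 0L || (stats::runif(1) < 0.08 && length(out) > 2L)) break
  }
  paste0(out, collapse = "")
}

gen_one_raw <- function(spec) {
  n_atoms <- round(stats::rnorm(1, spec$mean_atoms, spec$sd_atoms))
  n_atoms <- max(spec$min_atoms, min(spec$max_atoms, n_atoms))
  budget <- new.env(parent = emptyenv()); budget$n <- n_atoms
  s <- gen_chain(spec, budget, 1L)
  if (!nzchar(s)) s <- "CCO"
  s
}

#' Generate a synthetic SMILES corpus
#'
#' All outputs are valid by construction (verified post hoc with the
#' standard toolkit) and returned in canonical form, at most
#' `spec$max_tokens` tokens long. Duplicates are allowed, as in real
#' corpora. Reproducible from the seed.
#'
#' @param spec a [grammar_spec()]
#' @param n number of molecules
#' @param seed rng seed (defaults to `spec$seed`)
#' @return character vector of `n` canonical SMILES
#' @export
synthetic_smiles_corpus <- function(spec = grammar_spec(), n, seed = spec$seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  raw <- vapply(seq_len(n), function(i) {
    repeat {
      s <- gen_one_raw(spec)
      if (length(tokenize_smiles(s)) <= spec$max_tokens) return(s)
    }
  }, character(1))
  rec <- canonicalize_and_validate(raw)
  if (any(!rec$valid)) {
    stop(sprintf("constructive generator emitted %d invalid string(s), e.g. '%s'",
                 sum(!rec$valid), raw[which(!rec$valid)[1]]))
  }
  long <- rec$n_tokens > spec$max_tokens
  if (any(long)) {
    # canonicalization may lengthen a string past the cap; regenerate those
    repl <- synthetic_smiles_corpus(spec, sum(long),
                                    seed = seed + 7919L)
    rec$canonical[long] <- repl
  }
  rec$canonical
}

#' Planted bioactivity dataset
#'
#' Actives all contain a fixed substructure motif (default: a
#' trifluoromethyl group, which the constructive base grammar cannot
#' produce because it never places more than one halogen on a carbon);
#' inactives are guaranteed motif-free. Both properties are re-verified by
#' substructure search after generation.
#'
#' @param motif_attach SMILES fragment prepended to a base molecule to
#'   build actives
#' @param motif_smarts SMARTS pattern used for verification
#' @param n_act,n_inact set sizes
#' @param seed rng seed
#' @param spec base [grammar_spec()] for the molecular context
#' @return list with `actives`, `inactives` (canonical, internally
#'   deduplicated, mutually disjoint), `motif_smarts`, `seed`
#' @export
planted_bioactivity_dataset <- function(motif_attach = "FC(F)(F)",
                                        motif_smarts = "C(F)(F)F",
                                        n_act = 50L, n_inact = 5000L,
                                        seed = 1L,
                                        spec = grammar_spec()) {
  gen_unique <- function(n, make_raw, verify, seed0) {
    out <- character(0)
    tries <- 0L
    set.seed(seed0)
    while (length(out) < n) {
      tries <- tries + 1L
      if (tries > 60L) stop("fixture generator exceeded its retry budget")
      m <- max(16L, 2L * (n - length(out)))
      raw <- vapply(seq_len(m), function(i) make_raw(), character(1))
      rec <- canonicalize_and_validate(raw)
      cand <- rec$canonical[rec$valid & rec$n_tokens <= spec$max_tokens]
      cand <- setdiff(unique(cand), out)
      if (length(cand)) {
        keep <- verify(cand)
        out <- c(out, cand[keep])
      }
    }
    out[seq_len(n)]
  }
  actives <- gen_unique(n_act,
                        function() paste0(motif_attach, gen_one_raw(spec)),
                        function(s) {
                          m <- has_substructure(s, motif_smarts)
                          !is.na(m) & m
                        },
                        seed0 = seed)
  inactives <- gen_unique(n_inact,
                          function() gen_one_raw(spec),
                          function(s) {
                            m <- has_substructure(s, motif_smarts)
                            !is.na(m) & !m
                          },
                          seed0 = seed + 104729L)
  list(actives = actives, inactives = inactives,
       motif_smarts = motif_smarts, seed = seed)
}

#' Corrupt a valid SMILES into a specific error category
#'
#' Produces a string that fails validation and is classified by
#' [classify_invalid_smiles()] as exactly the requested category. Errors if
#' the corruption is not achievable for the given input (e.g. a ring error
#' on a string without ring labels that cannot host one).
#'
#' @param smiles a valid SMILES string
#' @param error_type `"branching"`, `"ring"`, `"bond"` or `"other"`
#' @param seed rng seed for position choices
#' @return an invalid SMILES of the requested category
#' @export
corrupt_smiles <- function(smiles, error_type = c("branching", "ring",
                                                  "bond", "other"),
                           seed = 1L) {
  error_type <- match.arg(error_type)
  set.seed(seed)
  pick <- function(v) v[sample.int(length(v), 1L)]
  toks <- tokenize_smiles(smiles)
  atom_pos <- which(grepl("^[A-Za-z]|^\\[", toks))
  cand <- switch(
    error_type,
    branching = {
      at <- pick(atom_pos)
      paste0(paste0(toks[seq_len(at)], collapse = ""), "(",
             paste0(toks[-seq_len(at)], collapse = ""))
    },
    ring = {
      dig <- which(grepl("^[0-9]$|^%[0-9][0-9]$", toks))
      if (length(dig)) {
        detokenize_smiles(toks[-pick(dig)])
      } else {
        # open an unmatched ring bond on some atom
        detokenize_smiles(append(toks, "9", after = pick(atom_pos)))
      }
    },
    bond = {
      hal <- which(toks %in% c("F", "Cl", "Br", "I"))
      hal <- hal[hal > 1L]
      if (length(hal)) {
        # double bond onto a halogen: parseable, valence-impossible
        detokenize_smiles(append(toks, "=", after = pick(hal) - 1L))
      } else {
        # over-saturate the final atom: syntactically fine, chemically not
        paste0(smiles, "(C)(C)(C)(C)(C)")
      }
    },
    other = paste0(smiles, "=")       # dangling bond: pure parse failure
  )
  rec <- canonicalize_and_validate(cand)
  if (rec$valid[1]) {
    stop(sprintf("corruption of '%s' into type '%s' produced a valid string",
                 smiles, error_type), call. = FALSE)
  }
  got <- classify_invalid_smiles(cand)
  if (!identical(got, error_type)) {
    stop(sprintf("corruption of '%s' yielded category '%s', not '%s'",
                 smiles, got, error_type), call. = FALSE)
  }
  cand
}

#' Memorization corpus: a backbone molecule and single-point variants
#'
#' Corpus for overfitting studies with an exactly computable teacher-forced
#' accuracy ceiling. With n distinct strings, an argmax predictor must lose
#' at least one position per non-majority string at the prefix-tree branch
#' points, capping next-token accuracy at `1 - E/T` (E = branch losses,
#' T = scored tokens). This corpus makes the cap as high as possible: one
#' long backbone (close to `target_tokens` SMILES tokens) plus `n - 1`
#' variants differing from it at a single valence-safe position, so the
#' prefix tree is a caterpillar with E = n - 1 exactly.
#'
#' @param n corpus size (backbone + n-1 variants)
#' @param target_tokens desired backbone token length (default 100)
#' @param seed rng seed
#' @return list with `corpus` (character, backbone first), `backbone`,
#'   `mutation_positions`, and `ceiling` (the exact accuracy cap, counting
#'   one EOS per string)
#' @export
memorization_corpus <- function(n = 32L, target_tokens = 100L, seed = 1L) {
  stopifnot(n >= 2)
  set.seed(seed)
  spec <- grammar_spec(mean_atoms = 64, sd_atoms = 6, min_atoms = 50,
                       max_atoms = 76, ring_prob = 0.12,
                       branch_prob = 0.2, max_tokens = target_tokens,
                       seed = seed)
  # pick the longest backbone under the cap from a candidate pool, then
  # grow it to the target length with validated methylene padding
  pool <- synthetic_smiles_corpus(spec, 60, seed = seed)
  lens <- vapply(pool, n_smiles_tokens, integer(1))
  backbone <- pool[which.max(lens)]
  while (n_smiles_tokens(backbone) < target_tokens) {
    grown <- paste0("C", backbone)
    if (!canonicalize_and_validate(grown)$valid[1]) {
      grown <- paste0(backbone, "C")
      if (!canonicalize_and_validate(grown)$valid[1]) break
    }
    backbone <- grown
  }
  toks <- tokenize_smiles(backbone)
  L <- length(toks)
  # single-token substitutions at plain chain-carbon positions, kept only
  # when the variant is still a valid molecule
  swap_for <- c(C = "N", N = "C", O = "N", S = "O")
  cand_pos <- which(toks %in% names(swap_for))
  cand_pos <- sample(cand_pos)
  variants <- character(0); positions <- integer(0)
  for (p in cand_pos) {
    if (length(variants) >= n - 1L) break
    v <- toks
    v[p] <- swap_for[[toks[p]]]
    s <- detokenize_smiles(v)
    if (canonicalize_and_validate(s)$valid[1]) {
      variants <- c(variants, s)
      positions <- c(positions, p)
    }
  }
  if (length(variants) < n - 1L) {
    stop(sprintf("backbone admits only %d valid single-point variants (need %d)",
                 length(variants), n - 1L))
  }
  corpus <- c(backbone, variants)
  T_total <- n * (L + 1L)                   # content tokens + EOS each
  list(corpus = corpus, backbone = backbone,
       mutation_positions = positions,
       ceiling = 1 - (n - 1L) / T_total)
}
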