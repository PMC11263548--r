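# canonical form of benzene under the fixed toolkit routine, frozen from a
# one-off run of the canonicalizer
BENZENE_CANONICAL <- "c1ccccc1"

test_that("canonicalization validates and normalizes", {
  rec <- canonicalize_and_validate(c("OCC", "C(C", "c1ccccc1", ""))
  expect_equal(rec$valid, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(rec$canonical[1], "CCO")
  expect_equal(rec$canonical[3], BENZENE_CANONICAL)
  expect_true(is.na(rec$canonical[2]))
  # canonical form is deterministic
  rec2 <- canonicalize_and_validate("OCC")
  expect_identical(rec2$canonical, rec$canonical[1])
})

test_that("curation applies element, fragment, stereo and length rules", {
  pol <- curation_policy()
  expect_equal(curate_corpus(c("CCO", "CC[Si](C)C"), pol), "CCO")
  expect_equal(curate_corpus("C[C@H](N)C(=O)O", pol), "CC(N)C(=O)O")
  # salt stripped, remaining parent kept; plain multi-fragment discarded
  expect_equal(curate_corpus("CCO.[Na+].[Cl-]", pol), "CCO")
  expect_equal(suppressWarnings(curate_corpus("CCO.CCN", pol)), character(0))
  # a valid molecule longer than the token cap is dropped
  long <- paste0(rep("C", 120), collapse = "")
  expect_false(long %in% curate_corpus(c(long, "CCO"), pol))
  # token cap measured on the canonical form
  expect_equal(curate_corpus(long, curation_policy(max_tokens = 150)), long)
})

test_that("curation is idempotent and its output re-validates", {
  raw <- c(synthetic_smiles_corpus(grammar_spec(), 30, seed = 8),
           "C[C@H](N)C(=O)O", "CC[Si](C)C", "not_a_smiles", "CCO.[Na+]")
  pol <- curation_policy(max_tokens = 60)
  once <- curate_corpus(raw, pol)
  expect_identical(curate_corpus(once, pol), once)
  rec <- canonicalize_and_validate(once)
  expect_true(all(rec$valid))
  expect_true(all(rec$n_tokens <= 60))
})

test_that("vocabulary is exact, reserved-first and deterministic", {
  v <- build_vocabulary("CCO")
  expect_equal(length(v$tokens), 5L)           # C, O + 3 reserved
  expect_setequal(setdiff(v$tokens, c("<pad>", "<bos>", "<eos>")), c("C", "O"))
  v2 <- build_vocabulary(c("CCO", "CCN"))
  expect_setequal(setdiff(v2$tokens, c("<pad>", "<bos>", "<eos>")),
                  c("C", "O", "N"))
  expect_identical(build_vocabulary(c("CCO", "CCN")), v2)
})

test_that("encoding layout and round trip", {
  v <- build_vocabulary("CCO")
  ids <- encode_sequence(c("C", "C", "O"), v, content_length = 5)
  expect_length(ids, 7L)
  expect_equal(ids[1], v$bos_id)
  expect_equal(ids[5], v$eos_id)
  expect_equal(ids[6:7], rep(v$pad_id, 2))
  expect_equal(decode_sequence(ids, v), c("C", "C", "O"))
  # degenerate empty sequence
  e <- encode_sequence(character(0), v, content_length = 3)
  expect_equal(e[1:2], c(v$bos_id, v$eos_id))
  expect_equal(decode_sequence(e, v), character(0))
  expect_error(encode_sequence("N", v, 5), "not in vocabulary.*N")
  expect_error(encode_sequence(rep("C", 9), v, 5), "exceeds")
})

test_that("vocabulary file round trip is exact", {
  v <- build_vocabulary(c("c1ccccc1Cl", "C%12CCCCCCCCCCC%12"))
  f <- withr::local_tempfile(fileext = ".txt")
  write_vocabulary(v, f)
  expect_identical(read_vocabulary(f), v)
})

test_that("corpus io round trips", {
  f <- withr::local_tempfile(fileext = ".smi")
  write_smiles(c("CCO", "CCN"), f)
  expect_identical(read_smiles(f), c("CCO", "CCN"))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_smiles(c("CCO", "CCN"), fc, labels = c(1, 0))
  got <- read_smiles(fc)
  expect_equal(got$smiles, c("CCO", "CCN"))
  expect_equal(got$labels, c(1, 0))
  fe <- withr::local_tempfile(fileext = ".smi")
  writeLines(character(0), fe)
  expect_warning(out <- read_smiles(fe), "empty")
  expect_length(out, 0L)
  expect_error(read_smiles("/nonexistent/path.smi"), "cannot read")
})
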