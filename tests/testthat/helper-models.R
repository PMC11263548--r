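# Shared fixtures. The expensive trained models are built once per test run
# and memoized, so several test files can reuse them.

options(s4clm.quiet = TRUE)

.cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

toy_vocab <- function(tokens = c("C", "N", "O", "1", "(", ")", "=")) {
  build_vocabulary(paste0(tokens, collapse = ""))
}

# small random-weight model over an explicit vocabulary
toy_model <- function(n_blocks = 2L, width = 8L, state = 4L,
                      content_length = 10L, seed = 5L,
                      vocab = toy_vocab()) {
  init_clm(clm_config(n_blocks = n_blocks, model_width = width,
                      state_size = state, content_length = content_length),
           vocab, seed = seed)
}

# 32-molecule memorization corpus (backbone + single-point variants, see
# memorization_corpus) and the model overfit on it
memorization_fixture <- function() {
  memo("memorization", function() {
    mc <- memorization_corpus(n = 32, target_tokens = 100, seed = 7)
    cfg <- clm_config(n_blocks = 2, model_width = 64, state_size = 16,
                      content_length = "auto")
    tc <- training_config(learning_rate = 4e-3, batch_size = 8,
                          max_epochs = 110, patience = 1e6, seed = 11)
    r <- pretrain(mc$corpus, cfg, tc)
    list(corpus = mc$corpus, model = r$model, history = r$history,
         ceiling = mc$ceiling)
  })
}

# 3000-molecule grammar corpus and the syntax-trained model
syntax_fixture <- function() {
  memo("syntax", function() {
    corp <- synthetic_smiles_corpus(grammar_spec(), 3000, seed = 101)
    cfg <- clm_config(n_blocks = 2, model_width = 64, state_size = 32,
                      content_length = "auto")
    tc <- training_config(learning_rate = 3e-3, batch_size = 64,
                          max_epochs = 32, patience = 1e6, seed = 1,
                          lr_schedule = "constant")
    r <- pretrain(corp, cfg, tc)
    list(corpus = corp, model = r$model, history = r$history)
  })
}

# planted-bioactivity enrichment fixture: fine-tune the syntax model on
# motif-bearing actives, score a held-out labelled set
enrichment_fixture <- function() {
  memo("enrichment", function() {
    syn <- syntax_fixture()
    ps <- planted_bioactivity_dataset(n_act = 60L, n_inact = 1500L,
                                      seed = 77)
    # keep molecules expressible within the pre-trained model window
    cl <- syn$model$config$content_length
    fits <- function(x) vapply(x, n_smiles_tokens, integer(1)) <= cl
    ps$actives <- ps$actives[fits(ps$actives)]
    ps$inactives <- ps$inactives[fits(ps$inactives)]
    splits <- make_splits(length(ps$actives), c(0.6, 0.2, 0.2), seed = 3)[[1]]
    train_act <- ps$actives[c(splits$train, splits$valid)]
    test_act <- ps$actives[splits$test]
    test_inact <- ps$inactives[seq_len(min(1200L, length(ps$inactives)))]
    tc <- training_config(learning_rate = 1e-3, batch_size = 16,
                          max_epochs = 12, patience = 5, seed = 5)
    ft <- finetune(syn$model, train_act, tc)
    list(pretrained = syn$model, finetuned = ft$model, ft = ft,
         train_actives = train_act, test_actives = test_act,
         test_inactives = test_inact, planted = ps)
  })
}
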