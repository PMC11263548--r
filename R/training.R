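# Next-token pre-training and transfer-learning fine-tuning.
#
# Optimizer: Adam. State-space-specific parameters (Lambda, P, Q, log_dt)
# get a reduced learning rate and, like everything else here, no weight
# decay -- the usual regime for this architecture family. Complex
# parameters are updated component-wise (real and imaginary parts carry
# independent second-moment estimates).

#' Training configuration
#'
#' @param learning_rate Adam step size
#' @param ssm_lr_factor multiplier on the learning rate for the structured
#'   state-space parameters (Lambda, P, Q, log_dt)
#' @param batch_size sequences per gradient step
#' @param max_epochs upper bound on epochs
#' @param patience early-stopping patience, epochs (default 5)
#' @param tolerance minimum validation-loss improvement that counts
#'   (default 1e-5)
#' @param seed rng seed controlling shuffling and dropout
#' @param keep_last number of trailing epoch checkpoints retained by
#'   [finetune()] (default 5)
#' @param lr_schedule `"cosine"` (decay to a tenth of the base rate over
#'   `max_epochs`) or `"constant"`
#' @return a `training_config` list
#' @export
training_config <- function(learning_rate = 2e-3, ssm_lr_factor = 0.5,
                            batch_size = 64L, max_epochs = 20L,
                            patience = 5L, tolerance = 1e-5,
                            seed = 1L, keep_last = 5L,
                            lr_schedule = c("cosine", "constant")) {
  stopifnot(patience >= 1, tolerance >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 ssm_lr_factor = ssm_lr_factor,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = patience,
                 tolerance = tolerance,
                 seed = as.integer(seed),
                 keep_last = as.integer(keep_last),
                 lr_schedule = match.arg(lr_schedule)),
            class = "training_config")
}

# per-epoch learning rate under the configured schedule
epoch_lr <- function(tc, epoch) {
  if (identical(tc$lr_schedule, "constant")) return(tc$learning_rate)
  frac <- (epoch - 1) / max(1L, tc$max_epochs - 1L)
  tc$learning_rate * (0.1 + 0.9 * 0.5 * (1 + cos(pi * frac)))
}

#' Random training/validation/test splits
#'
#' Disjoint, exhaustive index sets, reproducible from the seed. Fractions
#' are resolved by `floor`, with remainders assigned to the training set.
#'
#' @param n corpus size (or a corpus whose length is used)
#' @param fractions train/valid/test fractions summing to 1
#' @param n_runs number of independent shuffles
#' @param seed rng seed
#' @return a list of `n_runs` lists with integer `train`, `valid`, `test`
#' @export
make_splits <- function(n, fractions = c(0.8, 0.1, 0.1), n_runs = 1L,
                        seed = 1L) {
  if (length(n) > 1L) n <- length(n)
  stopifnot(abs(sum(fractions) - 1) < 1e-8, n >= 10)
  n_valid <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_valid - n_test
  set.seed(seed)
  lapply(seq_len(n_runs), function(r) {
    perm <- sample.int(n)
    list(train = sort(perm[seq_len(n_train)]),
         valid = sort(perm[n_train + seq_len(n_valid)]),
         test = sort(perm[n_train + n_valid + seq_len(n_test)]))
  })
}

# ---------------------------------------------------------------------------
# Adam over the nested parameter list

adam_init <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    list(m = x * 0, v = abs(x) * 0)   # v real-valued shapes via abs
  }
  list(state = walk(params), t = 0L)
}

SSM_SLOW <- c("Lambda", "P", "Q", "log_dt")

adam_step <- function(params, grads, opt, lr, ssm_factor,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  t <- opt$t
  upd <- function(p, g, s, rate) {
    if (is.complex(p)) {
      gr <- Re(g); gi <- Im(g)
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * complex(real = gr^2, imaginary = gi^2)
      mh <- s$m / (1 - b1^t)
      vr <- Re(s$v) / (1 - b2^t); vi <- Im(s$v) / (1 - b2^t)
      p <- p - rate * complex(real = Re(mh) / (sqrt(vr) + eps),
                              imaginary = Im(mh) / (sqrt(vi) + eps))
    } else {
      s$m <- b1 * s$m + (1 - b1) * g
      s$v <- b2 * s$v + (1 - b2) * g^2
      p <- p - rate * (s$m / (1 - b1^t)) / (sqrt(s$v / (1 - b2^t)) + eps)
    }
    list(p = p, s = s)
  }
  walk <- function(p, g, s, path = character()) {
    nms <- names(p)
    if (is.null(nms)) nms <- as.character(seq_along(p))
    for (nm in nms) {
      key <- if (grepl("^[0-9]+$", nm)) as.integer(nm) else nm
      pe <- p[[key]]; ge <- g[[key]]; se <- s[[key]]
      if (is.null(ge)) next
      if (is.list(pe) && !is.numeric(pe)) {
        r <- walk(pe, ge, se, c(path, nm))
        p[[key]] <- r$p; s[[key]] <- r$s
      } else {
        rate <- lr
        if (any(path == "ssm") && nm %in% SSM_SLOW) rate <- lr * ssm_factor
        r <- upd(pe, ge, se, rate)
        # drop any cached discretization on the ssm container later
        p[[key]] <- r$p; s[[key]] <- r$s
      }
    }
    list(p = p, s = s)
  }
  r <- walk(params, grads, opt$state)
  opt$state <- r$s
  # invalidate cached discretizations after every update
  for (i in seq_along(r$p$blocks)) {
    r$p$blocks[[i]]$ssm$Abar <- NULL
    r$p$blocks[[i]]$ssm$Bbar <- NULL
    r$p$blocks[[i]]$ssm$dt <- NULL
  }
  list(params = r$p, opt = opt)
}

# ---------------------------------------------------------------------------

evaluate_ids <- function(model, ids, batch_size = 256L) {
  n <- nrow(ids)
  tot_loss <- 0; tot_acc <- 0; tot_n <- 0
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    r <- clm_loss_grad(model, ids[s:e, , drop = FALSE], compute_grads = FALSE)
    tot_loss <- tot_loss + r$loss * r$n_scored
    tot_acc <- tot_acc + r$acc * r$n_scored
    tot_n <- tot_n + r$n_scored
  }
  list(loss = tot_loss / tot_n, acc = tot_acc / tot_n)
}

train_epochs <- function(model, ids_train, ids_valid, tc,
                         on_epoch = NULL, stage = "train") {
  opt <- adam_init(model$params)
  history <- data.frame()
  best_loss <- Inf; best_epoch <- 0L; wait <- 0L
  n <- nrow(ids_train)
  set.seed(tc$seed)
  for (epoch in seq_len(tc$max_epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; ep_acc <- 0; ep_n <- 0
    for (s in seq(1L, n, by = tc$batch_size)) {
      idx <- perm[s:min(n, s + tc$batch_size - 1L)]
      r <- clm_loss_grad(model, ids_train[idx, , drop = FALSE])
      st <- adam_step(model$params, r$grads, opt,
                      lr = epoch_lr(tc, epoch), ssm_factor = tc$ssm_lr_factor)
      model$params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + r$loss * r$n_scored
      ep_acc <- ep_acc + r$acc * r$n_scored
      ep_n <- ep_n + r$n_scored
    }
    vl <- if (!is.null(ids_valid) && nrow(ids_valid) > 0) {
      evaluate_ids(model, ids_valid)
    } else list(loss = NA_real_, acc = NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss / ep_n, train_acc = ep_acc / ep_n,
      val_loss = vl$loss, val_acc = vl$acc))
    s4clm_log("INFO", stage,
              sprintf("epoch %d: train loss %.4f acc %.3f | val loss %s",
                      epoch, ep_loss / ep_n, ep_acc / ep_n,
                      ifelse(is.na(vl$loss), "-", sprintf("%.4f", vl$loss))))
    if (!is.null(on_epoch)) on_epoch(model, epoch, history)
    mon <- if (is.na(vl$loss)) ep_loss / ep_n else vl$loss
    if (mon < best_loss - tc$tolerance) {
      best_loss <- mon; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) {
        s4clm_log("INFO", stage,
                  sprintf("early stop at epoch %d (best %d)", epoch, best_epoch))
        break
      }
    }
  }
  list(model = model, history = history, best_epoch = best_epoch)
}

#' Pre-train a chemical language model on a SMILES corpus
#'
#' Minimizes next-token cross entropy with teacher forcing in the
#' convolutional mode; PAD positions carry no loss, the end-of-sequence
#' token does.
#'
#' @param corpus character vector of curated canonical SMILES
#' @param clm_cfg a [clm_config()] (its `content_length` may be `"auto"` to
#'   fit the longest training sequence)
#' @param train_cfg a [training_config()]
#' @param valid optional held-out SMILES for per-epoch validation
#' @return `list(model, history, vocab)`; `model` is the final-epoch model
#' @export
pretrain <- function(corpus, clm_cfg = clm_config(), train_cfg = training_config(),
                     valid = NULL) {
  stopifnot(length(corpus) >= 1)
  vocab <- build_vocabulary(c(corpus, valid))
  cl <- clm_cfg$content_length
  if (identical(cl, "auto") || is.na(cl)) {
    cl <- max(lengths(lapply(c(corpus, valid), tokenize_smiles)))
    clm_cfg$content_length <- as.integer(cl)
  }
  ids <- encode_corpus(corpus, vocab, clm_cfg$content_length)
  ids_v <- if (!is.null(valid)) encode_corpus(valid, vocab, clm_cfg$content_length)
  model <- init_clm(clm_cfg, vocab, seed = train_cfg$seed)
  r <- train_epochs(model, ids, ids_v, train_cfg, stage = "pretrain")
  list(model = r$model, history = r$history, vocab = vocab,
       best_epoch = r$best_epoch)
}

#' Fine-tune a pre-trained model on a small task-focused set
#'
#' Continues training on the fine-tuning molecules with early stopping on
#' the validation cross entropy (patience and tolerance from the training
#' config). The vocabulary and model shape are never altered; fine-tuning
#' molecules containing out-of-vocabulary tokens are dropped with a
#' warning. The parameter snapshots of the last `keep_last` epochs are
#' retained, supporting last-epochs ensemble generation.
#'
#' @param model a pre-trained `clm_model`
#' @param corpus fine-tuning SMILES
#' @param train_cfg a [training_config()]
#' @param valid optional validation SMILES; when omitted, a 20% tail split
#'   of `corpus` (after seeded shuffling) is held out
#' @return `list(model, models_last, history, selected_epoch)`;
#'   `models_last` holds the trailing epoch checkpoints (newest last) and
#'   `model` is the selected-epoch model
#' @export
finetune <- function(model, corpus, train_cfg = training_config(),
                     valid = NULL) {
  vocab <- model$vocab
  ok <- vapply(corpus, function(s) {
    all(tokenize_smiles(s) %in% vocab$tokens) &&
      length(tokenize_smiles(s)) <= model$config$content_length
  }, logical(1))
  if (any(!ok)) {
    warning(sprintf("dropping %d fine-tuning molecule(s) not expressible in the pre-training vocabulary",
                    sum(!ok)))
  }
  corpus <- corpus[ok]
  if (length(corpus) == 0L) stop("no usable fine-tuning molecules", call. = FALSE)
  if (is.null(valid)) {
    set.seed(train_cfg$seed)
    perm <- sample(seq_along(corpus))
    n_val <- max(1L, floor(0.2 * length(corpus)))
    valid <- corpus[perm[seq_len(n_val)]]
    corpus <- corpus[perm[-seq_len(n_val)]]
  } else {
    ok_v <- vapply(valid, function(s) all(tokenize_smiles(s) %in% vocab$tokens) &&
                     length(tokenize_smiles(s)) <= model$config$content_length,
                   logical(1))
    valid <- valid[ok_v]
  }
  ids <- encode_corpus(corpus, vocab, model$config$content_length)
  ids_v <- if (length(valid)) encode_corpus(valid, vocab, model$config$content_length)
  snaps <- new.env(parent = emptyenv()); snaps$list <- list()
  keeper <- function(mod, epoch, history) {
    snaps$list[[length(snaps$list) + 1L]] <- list(epoch = epoch,
                                                  params = mod$params)
    if (length(snaps$list) > train_cfg$keep_last) {
      snaps$list <- snaps$list[-1L]
    }
  }
  r <- train_epochs(model, ids, ids_v, train_cfg, on_epoch = keeper,
                    stage = "finetune")
  models_last <- lapply(snaps$list, function(s) {
    m <- r$model; m$params <- s$params; attr(m, "epoch") <- s$epoch; m
  })
  sel <- r$best_epoch
  sel_model <- r$model
  for (s in snaps$list) if (s$epoch == sel) { sel_model$params <- s$params }
  list(model = sel_model, models_last = models_last,
       history = r$history, selected_epoch = sel)
}

# ---------------------------------------------------------------------------
# checkpoints

#' Save / load a model checkpoint
#'
#' A checkpoint bundles the weights, configuration, vocabulary, vocabulary
#' hash and free-form metadata. Loading verifies the vocabulary hash.
#'
#' @param model a `clm_model`
#' @param path destination file
#' @param meta optional metadata list (epoch, seed, stage, ...)
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  obj <- list(params = model$params, config = model$config,
              vocab = model$vocab, vocab_hash = model$vocab_hash,
              meta = meta)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$vocab_hash, vocab_hash(obj$vocab$tokens))) {
    stop("checkpoint vocabulary hash mismatch: file corrupted or vocabulary tampered",
         call. = FALSE)
  }
  structure(list(params = obj$params, config = obj$config, vocab = obj$vocab,
                 vocab_hash = obj$vocab_hash, meta = obj$meta),
            class = "clm_model")
}

#' Write a training history as CSV
#'
#' @param history data.frame from [pretrain()]/[finetune()]
#' @param path destination CSV
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
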