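# Temperature-controlled autoregressive SMILES sampling in recurrent mode.

#' Temperature-scaled sampling probabilities
#'
#' `p_i = exp(y_i / T) / sum_j exp(y_j / T)` over the unnormalized logits
#' `y`, computed with max subtraction for stability. `T = 1` uses the model
#' distribution unchanged; `T = 0` is greedy (a point mass on the argmax,
#' first index on exact ties); larger `T` flattens the distribution.
#'
#' @param logits numeric vector of finite unnormalized scores
#' @param temperature non-negative sampling temperature
#' @return probability vector summing to 1
#' @export
temperature_probabilities <- function(logits, temperature) {
  stopifnot(temperature >= 0)
  if (all(logits == -Inf)) stop("all logits are -Inf")
  if (temperature == 0) {
    p <- numeric(length(logits))
    p[which.max(logits)] <- 1
    return(p)
  }
  softmax(logits / temperature)
}

#' Draw token ids from a sampling distribution
#'
#' Weighted random sampling; the greedy (`point mass`) path never consumes
#' random numbers, so greedy generation is rng-state neutral.
#'
#' @param p probability vector (from [temperature_probabilities()])
#' @param n number of draws
#' @return integer token id(s)
#' @export
sample_next_token <- function(p, n = 1L) {
  hit <- which(p == 1)
  if (length(hit) == 1L && all(p[-hit] == 0)) return(rep(hit, n))
  sample.int(length(p), n, replace = TRUE, prob = p)
}

#' Generation configuration
#'
#' @param temperature sampling temperature (0 = greedy)
#' @param n_samples number of SMILES to generate
#' @param max_len maximum content tokens per design (default 100)
#' @param seed rng seed
#' @return a `generation_config` list
#' @export
generation_config <- function(temperature = 1.0, n_samples = 1024L,
                              max_len = 100L, seed = 1L) {
  stopifnot(temperature >= 0, n_samples >= 1, max_len >= 1)
  structure(list(temperature = temperature, n_samples = as.integer(n_samples),
                 max_len = as.integer(max_len), seed = as.integer(seed)),
            class = "generation_config")
}

#' Generate a batch of SMILES designs
#'
#' Starts every sequence from BOS with zeroed recurrent states and steps
#' the linear recurrence (never the convolution) until EOS or `max_len`
#' content tokens. Truncated sequences are returned with
#' `completed = FALSE`.
#'
#' @param model a trained `clm_model` (or checkpoint loaded with
#'   [load_checkpoint()])
#' @param config a [generation_config()]
#' @return data.frame with columns `smiles`, `temperature`, `seed`,
#'   `epoch`, `completed`
#' @export
generate_batch <- function(model, config = generation_config()) {
  stopifnot(inherits(model, "clm_model"))
  vocab <- model$vocab
  n <- config$n_samples
  max_len <- min(config$max_len, model$config$content_length)
  set.seed(config$seed)
  rnn <- rnn_init(model, n)
  cur <- rep(vocab$bos_id, n)
  alive <- rep(TRUE, n)
  toks <- matrix(NA_integer_, n, max_len)
  for (k in seq_len(max_len)) {
    st <- rnn_step(rnn, cur)
    logits <- st$logits
    # the generative alphabet is content tokens + EOS: BOS/PAD never emitted
    logits[, c(vocab$pad_id, vocab$bos_id)] <- -Inf
    if (config$temperature == 0) {
      nxt <- max.col(logits, ties.method = "first")
    } else {
      pm <- exp(sweep(logits / config$temperature, 1L,
                      apply(logits / config$temperature, 1L, max), `-`))
      pm <- pm / rowSums(pm)
      u <- stats::runif(n)
      cum <- t(apply(pm, 1L, cumsum))
      cum[, ncol(cum)] <- 1           # guard against rounding below 1
      nxt <- max.col(cum >= u, ties.method = "first")
    }
    nxt[!alive] <- vocab$pad_id
    toks[alive, k] <- nxt[alive]
    alive <- alive & nxt != vocab$eos_id
    cur <- nxt
    if (!any(alive)) break
  }
  smiles <- character(n); completed <- logical(n)
  for (i in seq_len(n)) {
    row <- toks[i, ]
    row <- row[!is.na(row)]
    eos_at <- match(vocab$eos_id, row)
    completed[i] <- !is.na(eos_at)
    content <- if (completed[i]) row[seq_len(eos_at - 1L)] else row
    smiles[i] <- detokenize_smiles(vocab$tokens[content])
  }
  data.frame(smiles = smiles,
             temperature = config$temperature,
             seed = config$seed,
             epoch = attr(model, "epoch") %||% NA_integer_,
             completed = completed,
             stringsAsFactors = FALSE)
}

#' Temperature-sweep generation protocol
#'
#' Runs [generate_batch()] at each temperature of the sweep (default 1.0
#' to 2.0 in steps of 0.25) for each supplied model checkpoint, the
#' campaign-level loop used for chemical-space exploration.
#'
#' @param models a list of `clm_model`s (e.g. the last fine-tuning epochs)
#' @param temperatures temperature grid
#' @param n_per designs per (model, temperature) pair
#' @param max_len maximum content tokens
#' @param seed base seed; each (model, temperature) cell derives its own
#' @return data.frame of pooled designs with provenance columns
#' @export
temperature_sweep <- function(models, temperatures = seq(1, 2, by = 0.25),
                              n_per = 10240L, max_len = 100L, seed = 1L) {
  if (inherits(models, "clm_model")) models <- list(models)
  out <- list()
  cell <- 0L
  for (mi in seq_along(models)) {
    for (temp in temperatures) {
      cell <- cell + 1L
      gc_cfg <- generation_config(temperature = temp, n_samples = n_per,
                                  max_len = max_len,
                                  seed = (seed * 131L + cell) %% .Machine$integer.max)
      b <- generate_batch(models[[mi]], gc_cfg)
      b$model_index <- mi
      out[[cell]] <- b
    }
  }
  do.call(rbind, out)
}

#' Size of a full design campaign
#'
#' Number of designs produced by a checkpoint-ensemble temperature sweep:
#' `n_models * n_temperatures * n_per`.
#'
#' @param n_models checkpoints used (default: the last 5 fine-tuning epochs)
#' @param temperatures temperature grid (default 1.0--2.0, step 0.25)
#' @param n_per designs per model-temperature cell (default 10240)
#' @return integer design count
#' @export
campaign_design_count <- function(n_models = 5L,
                                  temperatures = seq(1, 2, by = 0.25),
                                  n_per = 10240L) {
  as.integer(n_models) * length(temperatures) * as.integer(n_per)
}
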