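# Joint log-likelihoods, bias-corrected fine-tuning scores, ranking and
# enrichment analysis.

#' Joint log-likelihood of molecules under a model
#'
#' Teacher-forced convolutional pass; sums the log probability of every
#' content token and of the end-of-sequence token, each conditioned on the
#' true prefix. BOS is conditioning only; PAD positions are ignored, so the
#' value is invariant to padding length.
#'
#' @param model a `clm_model`
#' @param smiles character vector of canonical, in-vocabulary SMILES
#' @param batch_size molecules per forward pass
#' @return data.frame with `smiles`, `n_tokens` (scored positions incl.
#'   EOS), `log_likelihood` (nats, always <= 0)
#' @export
sequence_log_likelihood <- function(model, smiles, batch_size = 256L) {
  vocab <- model$vocab
  toks <- lapply(smiles, tokenize_smiles)
  cl <- min(model$config$content_length, max(lengths(toks)))
  n <- length(smiles)
  ll <- numeric(n); ntok <- integer(n)
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1L)
    ids <- t(vapply(toks[s:e], encode_sequence, integer(cl + 2L),
                    vocab = vocab, content_length = cl))
    lg <- clm_forward(model, ids, mode = "convolutional")
    L <- ncol(ids)
    for (bi in seq_len(nrow(ids))) {
      tgt <- ids[bi, -1L]
      sc <- which(tgt != vocab$pad_id)       # content + EOS positions
      lse <- apply(lg[sc, bi, , drop = FALSE], 1L, function(v) {
        mx <- max(v); mx + log(sum(exp(v - mx)))
      })
      lp <- lg[cbind(sc, bi, tgt[sc])] - lse
      ll[s + bi - 1L] <- sum(lp)
      ntok[s + bi - 1L] <- length(sc)
    }
  }
  data.frame(smiles = smiles, n_tokens = ntok, log_likelihood = ll,
             stringsAsFactors = FALSE)
}

#' Bias-corrected fine-tuning score
#'
#' `L_score = L(M_ft) - L(M_pt)`: the fine-tuned log-likelihood minus the
#' pre-trained one, removing general-chemistry bias to isolate
#' target-specific signal. Higher scores rank better. Both models must
#' share the same vocabulary (checked by hash).
#'
#' @param ft_model fine-tuned model
#' @param pt_model pre-trained model
#' @param smiles molecules to score
#' @return data.frame with `smiles`, `ll_ft`, `ll_pt`, `score`
#' @export
bias_corrected_score <- function(ft_model, pt_model, smiles) {
  if (!identical(ft_model$vocab_hash, pt_model$vocab_hash)) {
    stop("vocabulary hash mismatch between fine-tuned and pre-trained models",
         call. = FALSE)
  }
  ft <- sequence_log_likelihood(ft_model, smiles)
  pt <- sequence_log_likelihood(pt_model, smiles)
  data.frame(smiles = smiles, ll_ft = ft$log_likelihood,
             ll_pt = pt$log_likelihood,
             score = ft$log_likelihood - pt$log_likelihood,
             stringsAsFactors = FALSE)
}

#' Rank molecules by score
#'
#' Descending order; exact ties are broken by a seeded shuffle so that
#' rankings are reproducible and unbiased.
#'
#' @param scores numeric vector (higher is better)
#' @param tie_seed seed for the tie-breaking shuffle
#' @return integer permutation: `rank_molecules(s)[1]` is the index of the
#'   best molecule
#' @export
rank_molecules <- function(scores, tie_seed = 1L) {
  stopifnot(all(is.finite(scores)))
  set.seed(tie_seed)
  jitter_order <- sample(seq_along(scores))
  order(-scores, jitter_order)
}

#' Enrichment: recall at k
#'
#' Fraction of all actives found among the top k ranked molecules,
#' the axis convention of retrospective enrichment plots. Set
#' `normalize = "k"` for precision@k instead.
#'
#' @param ranking integer permutation from [rank_molecules()]
#' @param labels logical (or 0/1) activity labels aligned with the
#'   *unranked* molecules
#' @param ks top-list sizes (default 10, 50, 100)
#' @param normalize `"actives"` (recall@k, default) or `"k"` (precision@k)
#' @return data.frame with `k`, `n_actives_topk`, `value`
#' @export
enrichment_at_k <- function(ranking, labels, ks = c(10L, 50L, 100L),
                            normalize = c("actives", "k")) {
  normalize <- match.arg(normalize)
  labels <- as.logical(labels)
  stopifnot(length(ranking) == length(labels))
  n_act <- sum(labels)
  if (n_act == 0) stop("no actives among the labels", call. = FALSE)
  res <- lapply(ks, function(k) {
    if (k > length(ranking)) {
      warning(sprintf("k = %d exceeds list length %d; clamped", k,
                      length(ranking)))
      k <- length(ranking)
    }
    hits <- sum(labels[ranking[seq_len(k)]])
    data.frame(k = k, n_actives_topk = hits,
               value = hits / if (normalize == "actives") n_act else k)
  })
  do.call(rbind, res)
}

#' Permutation null for recall at k
#'
#' Monte-Carlo distribution of recall@k under random ranking.
#'
#' @param n_total list length
#' @param n_actives number of actives
#' @param k top-list size
#' @param n_perm permutations (default 10000)
#' @param seed rng seed
#' @return list with `mean`, `quantiles` (2.5/50/97.5%), `values`
#' @export
recall_permutation_null <- function(n_total, n_actives, k,
                                    n_perm = 10000L, seed = 1L) {
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(i) {
    top <- sample.int(n_total, k)
    sum(top <= n_actives) / n_actives   # actives placed first wlog
  }, numeric(1))
  list(mean = mean(vals),
       quantiles = stats::quantile(vals, c(0.025, 0.5, 0.975)),
       values = vals)
}

#' Score, rank and write an enrichment table
#'
#' Convenience wrapper producing the per-molecule scores CSV used by the
#' command-line interface.
#'
#' @param ft_model,pt_model models for [bias_corrected_score()]
#' @param smiles molecules
#' @param labels optional activity labels
#' @param tie_seed tie-break seed
#' @return data.frame sorted by rank with score components and labels
#' @export
score_and_rank <- function(ft_model, pt_model, smiles, labels = NULL,
                           tie_seed = 1L) {
  sc <- bias_corrected_score(ft_model, pt_model, smiles)
  rk <- rank_molecules(sc$score, tie_seed)
  out <- sc[rk, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(labels)) out$label <- labels[rk]
  rownames(out) <- NULL
  out
}
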