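# Chemical language model assembled from state-space layers.
#
# Architecture: token embedding -> n_blocks x [ layer norm -> per-channel
# state-space convolution (+ skip D) -> GELU -> channel-mixing linear ->
# residual ] -> final layer norm -> projection to vocabulary logits.
# Output position k conditions only on positions <= k: the state-space
# convolution is causal and every other stage is position-wise.
#
# The same weights run in two modes: "convolutional" (whole sequence at
# once, used for training and likelihood scoring) and "recurrent"
# (token-by-token via Eq.-style linear recurrences, used for generation).

#' Model configuration
#'
#' @param n_blocks number of residual state-space blocks
#' @param model_width channels H
#' @param state_size state dimension N of each per-channel system
#' @param dropout dropout fraction on the mixing output during training
#' @param vocab_size vocabulary size (set from the vocabulary at init)
#' @param content_length content tokens per padded sequence
#' @return a `clm_config` list
#' @export
clm_config <- function(n_blocks = 2L, model_width = 96L, state_size = 16L,
                       dropout = 0, vocab_size = NULL,
                       content_length = 100L) {
  stopifnot(n_blocks >= 1, model_width >= 1, state_size >= 1,
            dropout >= 0, dropout < 1)
  structure(list(n_blocks = as.integer(n_blocks),
                 model_width = as.integer(model_width),
                 state_size = as.integer(state_size),
                 dropout = dropout,
                 vocab_size = if (is.null(vocab_size)) NULL else as.integer(vocab_size),
                 content_length = if (identical(content_length, "auto"))
                   "auto" else as.integer(content_length)),
            class = "clm_config")
}

#' Initialize a chemical language model
#'
#' @param config a [clm_config()]; `vocab_size` is taken from `vocab`
#' @param vocab a [build_vocabulary()] result
#' @param seed integer seed; identical seeds give identical weights
#' @return a `clm_model` list with `params`, `config`, `vocab`,
#'   `vocab_hash`
#' @export
init_clm <- function(config, vocab, seed = 1L) {
  stopifnot(inherits(config, "clm_config"), inherits(vocab, "clm_vocabulary"))
  config$vocab_size <- vocab_size(vocab)
  V <- config$vocab_size; H <- config$model_width
  set.seed(seed)
  blocks <- vector("list", config$n_blocks)
  for (i in seq_len(config$n_blocks)) {
    blocks[[i]] <- list(
      ssm = init_state_space(config$state_size, H,
                             rng_seed = seed * 1000L + i),
      W_mix = matrix(stats::rnorm(H * H, sd = 1 / sqrt(H)), H, H),
      b_mix = rep(0, H),
      ln_g = rep(1, H), ln_b = rep(0, H)
    )
  }
  params <- list(
    emb = matrix(stats::rnorm(V * H, sd = 0.1), V, H),
    blocks = blocks,
    ln_f_g = rep(1, H), ln_f_b = rep(0, H),
    W_out = matrix(stats::rnorm(H * V, sd = 0.02), H, V),
    b_out = rep(0, V)
  )
  structure(list(params = params, config = config, vocab = vocab,
                 vocab_hash = vocab_hash(vocab$tokens)),
            class = "clm_model")
}

#' @export
print.clm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<clm_model: %d block(s), width %d, state size %d, ",
                     "vocab %d, content length %d>\n"),
              cfg$n_blocks, cfg$model_width, cfg$state_size,
              cfg$vocab_size, cfg$content_length))
  invisible(x)
}

# ---------------------------------------------------------------------------
# layer norm over channels (rows of an (positions x H) matrix)

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2L, g, `*`), 2L, b, `+`),
       xhat = xhat, inv = inv, xc = xc)
}

layernorm_bwd <- function(cache, g, dy) {
  H <- ncol(dy)
  dxhat <- sweep(dy, 2L, g, `*`)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  # dx = inv/H * (H*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- (cache$inv / H) * (H * dxhat - s1 - cache$xhat * s2)
  list(dx = dx, dg = dg, db = db)
}

# ---------------------------------------------------------------------------
# state-space layer, convolutional mode. Input/output as (L x B*H) matrices
# with column order (h-1)*B + b.

pad_rows <- function(m, n2) {
  out <- matrix(0, n2, ncol(m))
  out[seq_len(nrow(m)), ] <- m
  out
}

# sum an (n2 x B*H) matrix over the batch within each channel -> n2 x H
sum_over_batch <- function(m, n2, B, H) {
  a <- aperm(array(m, c(n2, B, H)), c(1, 3, 2))
  dim(a) <- c(n2 * H, B)
  matrix(rowSums(a), n2, H)
}

ssm_conv_fwd <- function(ssm, u, L, B, H) {
  n2 <- stats::nextn(2L * L, c(2, 3))
  kr <- kernel_recurrence(ssm, L, keep_states = TRUE)
  Kf <- stats::mvfft(pad_rows(kr$K, n2))              # n2 x H
  Kfbig <- Kf[, rep(seq_len(H), each = B), drop = FALSE]
  Uf <- stats::mvfft(pad_rows(u, n2))
  y <- Re(stats::mvfft(Uf * Kfbig, inverse = TRUE))[seq_len(L), , drop = FALSE] / n2
  y <- y + u * rep(ssm$D, each = L * B)
  list(y = y, Uf = Uf, Kfbig = Kfbig, K = kr$K, X = kr$X, n2 = n2)
}

ssm_conv_bwd <- function(ssm, cache, u, dy, L, B, H) {
  n2 <- cache$n2
  Gyf <- stats::mvfft(pad_rows(dy, n2))
  du <- Re(stats::mvfft(Conj(cache$Kfbig) * Gyf, inverse = TRUE))[seq_len(L), , drop = FALSE] / n2
  du <- du + dy * rep(ssm$D, each = L * B)
  # kernel gradient: aggregate over the batch in the frequency domain,
  # then one small inverse transform
  Sf <- sum_over_batch(Conj(cache$Uf) * Gyf, n2, B, H)
  gK <- Re(stats::mvfft(Sf, inverse = TRUE))[seq_len(L), , drop = FALSE] / n2
  gD <- colSums(matrix(colSums(u * dy), B, H))
  kg <- kernel_backward(ssm, cache$X, gK, L)
  dg <- discretize_backward(ssm, kg$G_Abar, kg$G_Bbar)
  dg$C <- kg$G_C
  dg$D <- gD
  list(du = du, grads = dg)
}

# BPTT through the kernel recurrence K_k = Re(C^T Abar^k Bbar) and through
# the bilinear discretization, both delegated to the compiled core.
# Complex gradients use the conjugate convention (G = dL/dRe + i dL/dIm).
kernel_backward <- function(ssm, X, gK, L) {
  N <- attr(ssm, "N"); H <- attr(ssm, "H")
  r <- cpp_kernel_backward(ssm$Abar, X, gK, matrix(ssm$C, N, H))
  list(G_C = matrix(r$G_C, N, H), G_Abar = r$G_Abar,
       G_Bbar = matrix(r$G_Bbar, N, H))
}

discretize_backward <- function(ssm, G_Abar, G_Bbar) {
  N <- attr(ssm, "N"); H <- attr(ssm, "H")
  r <- cpp_discretize_backward(matrix(ssm$Lambda, N, H), matrix(ssm$P, N, H),
                               matrix(ssm$Q, N, H), matrix(ssm$B, N, H),
                               ssm$dt, ssm$Abar, matrix(ssm$Bbar, N, H),
                               G_Abar, matrix(G_Bbar, N, H))
  list(Lambda = matrix(r$Lambda, N, H), P = matrix(r$P, N, H),
       Q = matrix(r$Q, N, H), B = matrix(r$B, N, H),
       log_dt = as.vector(r$log_dt))
}

# ---------------------------------------------------------------------------
# full-model convolutional forward (+ optional backward caches)

# ids: B x Lfull integer matrix. Returns logits array (L, B, V) and caches.
clm_conv_forward <- function(model, ids, keep = FALSE, dropout_masks = NULL) {
  p <- model$params; cfg <- model$config
  B <- nrow(ids); L <- ncol(ids); H <- cfg$model_width; V <- cfg$vocab_size
  ids_flat <- as.vector(t(ids))                 # position fastest, then batch
  X <- p$emb[ids_flat, , drop = FALSE]          # (L*B) x H
  caches <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    blk <- p$blocks[[i]]
    ssm <- blk$ssm
    if (is.null(ssm$Abar)) ssm <- discretize(ssm)
    ln <- layernorm_fwd(X, blk$ln_g, blk$ln_b)
    zc <- matrix(ln$y, L, B * H)                # (L) x (B*H), col (h-1)B+b
    sc <- ssm_conv_fwd(ssm, zc, L, B, H)
    s_mat <- matrix(sc$y, L * B, H)
    g <- gelu(s_mat)
    mix <- g %*% blk$W_mix
    mix <- sweep(mix, 2L, blk$b_mix, `+`)
    if (!is.null(dropout_masks)) mix <- mix * dropout_masks[[i]]
    Xnew <- X + mix
    if (keep) {
      caches[[i]] <- list(ln = ln, zc = zc, sc = sc, s_mat = s_mat, g = g,
                          X_in = X, ssm = ssm)
    } else {
      caches[[i]] <- list(ssm = ssm)
    }
    X <- Xnew
  }
  lnf <- layernorm_fwd(X, p$ln_f_g, p$ln_f_b)
  logits <- sweep(lnf$y %*% p$W_out, 2L, p$b_out, `+`)   # (L*B) x V
  list(logits = logits, caches = caches, lnf = lnf, X_final = X,
       ids_flat = ids_flat, L = L, B = B)
}

#' Forward pass: per-position next-token logits
#'
#' @param model a `clm_model`
#' @param ids integer id matrix (rows = sequences, columns = positions),
#'   e.g. from [encode_corpus()]
#' @param mode `"convolutional"` (whole sequence at once) or `"recurrent"`
#'   (token-by-token stepping); both modes use the same weights and agree
#'   within numerical tolerance
#' @return numeric array `(positions, sequences, vocabulary)` of logits;
#'   entry `[k, b, ]` conditions only on positions `<= k` of sequence `b`
#' @export
clm_forward <- function(model, ids,
                        mode = c("convolutional", "recurrent")) {
  mode <- match.arg(mode)
  if (is.null(dim(ids))) ids <- matrix(ids, nrow = 1L)
  if (mode == "convolutional") {
    fw <- clm_conv_forward(model, ids)
    return(array(fw$logits, c(fw$L, fw$B, model$config$vocab_size)))
  }
  B <- nrow(ids); L <- ncol(ids); V <- model$config$vocab_size
  rnn <- rnn_init(model, B)
  out <- array(0, c(L, B, V))
  for (k in seq_len(L)) {
    st <- rnn_step(rnn, ids[, k])
    out[k, , ] <- st$logits
  }
  out
}

# ---------------------------------------------------------------------------
# recurrent mode. State per block kept as a real (2*N*H x B) matrix holding
# the complex channel states stacked [Re; Im] per channel; the per-channel
# Abar matrices form one sparse block-diagonal real operator, so one sparse
# product advances every channel of every sequence.

rnn_init <- function(model, B) {
  cfg <- model$config; p <- model$params
  H <- cfg$model_width; N <- cfg$state_size
  blocks <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    blk <- p$blocks[[i]]
    ssm <- blk$ssm
    if (is.null(ssm$Abar)) ssm <- discretize(ssm)
    # real embedding of the complex block-diagonal update
    per <- 2L * N
    base <- rep((seq_len(H) - 1L) * per, each = N * N)
    rr <- rep(rep(seq_len(N), times = N), H)
    cc <- rep(rep(seq_len(N), each = N), H)
    Ar <- as.vector(Re(ssm$Abar)); Ai <- as.vector(Im(ssm$Abar))
    i_idx <- c(base + rr,      base + rr,          base + N + rr, base + N + rr)
    j_idx <- c(base + cc,      base + N + cc,      base + cc,     base + N + cc)
    x_val <- c(Ar,             -Ai,                Ai,            Ar)
    S <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x_val,
                              dims = c(per * H, per * H))
    bexp <- as.vector(rbind(matrix(Re(ssm$Bbar), N, H),
                            matrix(Im(ssm$Bbar), N, H)))
    cvec <- as.vector(rbind(matrix(Re(ssm$C), N, H),
                            -matrix(Im(ssm$C), N, H)))
    blocks[[i]] <- list(S = S, bexp = bexp, cvec = cvec, D = ssm$D,
                        W_mix = blk$W_mix, b_mix = blk$b_mix,
                        ln_g = blk$ln_g, ln_b = blk$ln_b,
                        state = matrix(0, per * H, B))
  }
  env <- new.env(parent = emptyenv())
  env$blocks <- blocks
  env$model <- model
  env$B <- B
  env$rowrep <- rep(seq_len(H), each = 2L * N)
  env
}

# advance one token for all sequences; ids_k integer vector length B
rnn_step <- function(rnn, ids_k) {
  model <- rnn$model; p <- model$params
  H <- model$config$model_width
  x <- p$emb[ids_k, , drop = FALSE]               # B x H
  for (i in seq_along(rnn$blocks)) {
    blk <- rnn$blocks[[i]]
    z <- layernorm_fwd(x, blk$ln_g, blk$ln_b)$y
    uexp <- t(z)[rnn$rowrep, , drop = FALSE]      # (2NH) x B
    st <- as.matrix(blk$S %*% blk$state) + blk$bexp * uexp
    rnn$blocks[[i]]$state <- st
    y <- t(rowsum(blk$cvec * st, group = rnn$rowrep))  # B x H
    y <- y + sweep(z, 2L, blk$D, `*`)
    g <- gelu(y)
    mix <- sweep(g %*% blk$W_mix, 2L, blk$b_mix, `+`)
    x <- x + mix
  }
  f <- layernorm_fwd(x, p$ln_f_g, p$ln_f_b)$y
  logits <- sweep(f %*% p$W_out, 2L, p$b_out, `+`)     # B x V
  list(logits = logits)
}

# ---------------------------------------------------------------------------
# loss + full backward (next-token cross entropy, PAD targets masked)

clm_loss_grad <- function(model, ids, compute_grads = TRUE, rng = NULL) {
  cfg <- model$config; p <- model$params
  B <- nrow(ids); L <- ncol(ids); H <- cfg$model_width; V <- cfg$vocab_size
  pad_id <- model$vocab$pad_id
  drop_masks <- NULL
  if (compute_grads && cfg$dropout > 0) {
    drop_masks <- lapply(seq_len(cfg$n_blocks), function(i) {
      matrix(stats::rbinom((L * B) * H, 1L, 1 - cfg$dropout) /
               (1 - cfg$dropout), L * B, H)
    })
  }
  fw <- clm_conv_forward(model, ids, keep = compute_grads,
                         dropout_masks = drop_masks)
  # targets: position l predicts ids[, l+1]; row index of (l,b) in the
  # (L*B) stack is (b-1)*L + l
  tg <- t(ids[, -1L, drop = FALSE])               # (L-1) x B
  keep_rows <- as.vector(outer(seq_len(L - 1L), (seq_len(B) - 1L) * L, `+`))
  logits <- fw$logits[keep_rows, , drop = FALSE]
  targets <- as.vector(tg)
  mask <- targets != pad_id
  lse <- logsumexp_rows(logits)
  lp_target <- logits[cbind(seq_along(targets), targets)] - lse
  n_scored <- sum(mask)
  loss <- -sum(lp_target[mask]) / n_scored
  acc <- sum((max.col(logits, ties.method = "first") == targets)[mask]) / n_scored
  if (!is.finite(loss)) stop("training diverged: non-finite loss", call. = FALSE)
  if (!compute_grads) return(list(loss = loss, acc = acc, n_scored = n_scored))

  # gradient at logits
  Pm <- exp(logits - lse)
  Pm[cbind(seq_along(targets), targets)] <-
    Pm[cbind(seq_along(targets), targets)] - 1
  Pm <- Pm * (mask / n_scored)
  G_logits <- matrix(0, L * B, V)
  G_logits[keep_rows, ] <- Pm

  grads <- list(blocks = vector("list", cfg$n_blocks))
  # output head
  grads$W_out <- crossprod(fw$lnf$y, G_logits)
  grads$b_out <- colSums(G_logits)
  dF <- G_logits %*% t(p$W_out)
  lb <- layernorm_bwd(fw$lnf, p$ln_f_g, dF)
  grads$ln_f_g <- lb$dg; grads$ln_f_b <- lb$db
  dX <- lb$dx
  for (i in rev(seq_len(cfg$n_blocks))) {
    blk <- p$blocks[[i]]; ca <- fw$caches[[i]]
    dmix <- dX
    if (!is.null(drop_masks)) dmix <- dmix * drop_masks[[i]]
    gW <- crossprod(ca$g, dmix)
    gb <- colSums(dmix)
    dg_act <- dmix %*% t(blk$W_mix)
    ds <- dg_act * gelu_grad(ca$s_mat)
    ds_c <- matrix(ds, L, B * H)
    sb <- ssm_conv_bwd(ca$ssm, ca$sc, ca$zc, ds_c, L, B, H)
    dz <- matrix(sb$du, L * B, H)
    lnb <- layernorm_bwd(ca$ln, blk$ln_g, dz)
    dX <- dX + lnb$dx                              # residual + branch
    grads$blocks[[i]] <- list(ssm = sb$grads,
                              W_mix = gW, b_mix = gb,
                              ln_g = lnb$dg, ln_b = lnb$db)
    grads$blocks[[i]]$ssm$C <- sb$grads$C
  }
  # embedding gradient: scatter-add over token ids
  gE <- rowsum(dX, group = fw$ids_flat)
  grads$emb <- matrix(0, V, H)
  grads$emb[as.integer(rownames(gE)), ] <- gE
  list(loss = loss, acc = acc, grads = grads, n_scored = n_scored)
}
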