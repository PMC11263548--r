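# Structured state-space (S4) core.
#
# Each model channel carries an independent single-input single-output
# linear state-space system. The continuous-time state matrix is kept in
# structured diagonal-plus-low-rank (DPLR) form
#     A = diag(Lambda) - P Q^H
# initialized from the HiPPO-LegS operator expressed in the eigenbasis of
# its normal part. Discretization is bilinear (Tustin). The same parameters
# drive two computation paths:
#   * a global causal convolution, whose filter taps are K_k = C A^k B
#     (training mode), and
#   * the linear recurrence x_k = A x_{k-1} + B u_k, y_k = C x_k + D u_k
#     (generation mode).
# Their agreement is the model's central structural property and is enforced
# by tests.

#' HiPPO-LegS matrix
#'
#' The scaled Legendre memory operator: `A[n,k] = -sqrt((2n+1)(2k+1))` below
#' the diagonal, `-(n+1)` on it (0-based indices), `0` above.
#'
#' @param N state dimension
#' @return an `N x N` real matrix
#' @export
hippo_legs_matrix <- function(N) {
  n <- 0:(N - 1)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(i)) {
      A[i, j] <- if (i == j) -(n[i] + 1) else -sqrt((2 * n[i] + 1) * (2 * n[j] + 1))
    }
  }
  A
}

# DPLR decomposition of HiPPO-LegS: A = V (diag(Lambda) - Pt Pt^H) V^H.
# Returns the triple in the eigenbasis of the normal part (Lambda, Pt) with
# Re(Lambda) = -1/2.
hippo_legs_dplr <- function(N) {
  A <- hippo_legs_matrix(N)
  p <- sqrt(0:(N - 1) + 0.5)
  S <- A + tcrossprod(p)                 # normal part: -1/2 I + skew
  skew <- S - diag(diag(S))
  herm <- 1i * skew                      # Hermitian
  e <- eigen(herm, symmetric = TRUE)
  Lambda <- complex(real = mean(diag(S)), imaginary = -e$values)
  V <- e$vectors
  Pt <- as.vector(Conj(t(V)) %*% p)
  list(Lambda = Lambda, P = Pt, V = V)
}

#' Initialize structured state-space parameters for a layer of channels
#'
#' Lambda, P, Q follow the HiPPO-LegS diagonal-plus-low-rank decomposition
#' (identical across channels at initialization, trained per channel);
#' B and C are random complex Gaussians; the step size Delta is log-uniform
#' in `dt_range`.
#'
#' @param N state dimension
#' @param model_width number of channels H
#' @param rng_seed integer seed (deterministic init)
#' @param dt_range range for the log-uniform Delta initialization
#' @return a `state_space_params` list with complex `N x H` members
#'   `Lambda`, `P`, `Q`, `B`, `C`, real `log_dt` (length H) and `D`
#'   (length H)
#' @export
init_state_space <- function(N, model_width, rng_seed = 1L,
                             dt_range = c(1e-3, 1e-1)) {
  stopifnot(N >= 1, model_width >= 1)
  set.seed(rng_seed)
  d <- hippo_legs_dplr(N)
  H <- model_width
  rc <- function(sd) matrix(complex(real = stats::rnorm(N * H, sd = sd),
                                    imaginary = stats::rnorm(N * H, sd = sd)),
                            N, H)
  params <- list(
    Lambda = matrix(d$Lambda, N, H),
    P = matrix(d$P, N, H),
    Q = matrix(d$P, N, H),
    B = rc(1 / sqrt(2)),
    C = rc(1 / sqrt(2 * N)),
    log_dt = stats::runif(H, log(dt_range[1]), log(dt_range[2])),
    D = rep(1, H)
  )
  structure(params, class = "state_space_params", N = N, H = H)
}

#' Materialize the continuous state matrix of one channel
#'
#' @param params `state_space_params`
#' @param h channel index
#' @return complex `N x N` matrix `diag(Lambda) - P Q^H`
#' @export
materialize_A <- function(params, h = 1L) {
  diag(params$Lambda[, h], nrow = nrow(params$Lambda)) -
    params$P[, h] %*% t(Conj(params$Q[, h]))
}

#' Bilinear (Tustin) discretization
#'
#' Computes, per channel, `Abar = (I - dt/2 A)^{-1} (I + dt/2 A)` and
#' `Bbar = (I - dt/2 A)^{-1} dt B` from the structured continuous
#' parameters.
#'
#' @param params `state_space_params`
#' @return the params with `Abar` (complex `N x N x H`), `Bbar`
#'   (complex `N x H`) and `dt` populated
#' @export
discretize <- function(params) {
  N <- attr(params, "N"); H <- attr(params, "H")
  dt <- exp(params$log_dt)
  dc <- cpp_discretize(matrix(params$Lambda, N, H), matrix(params$P, N, H),
                       matrix(params$Q, N, H), matrix(params$B, N, H), dt)
  params$Abar <- dc$Abar
  params$Bbar <- matrix(dc$Bbar, N, H)
  params$dt <- dt
  params
}

# ---------------------------------------------------------------------------
# kernel computation

# brute-force oracle: K_k = Re(C^T Abar^k Bbar), materialized matrix powers
kernel_naive <- function(params, L) {
  N <- attr(params, "N"); H <- attr(params, "H")
  K <- matrix(0, L, H)
  for (h in seq_len(H)) {
    x <- params$Bbar[, h]
    A <- matrix(params$Abar[, , h], N, N)
    for (k in seq_len(L)) {
      K[k, h] <- Re(sum(params$C[, h] * x))
      if (k < L) x <- A %*% x
    }
  }
  K
}

# recurrence path: same taps, vectorized across channels; optionally keeps
# the state trajectory (needed for backpropagation through the kernel)
kernel_recurrence <- function(params, L, keep_states = FALSE) {
  N <- attr(params, "N"); H <- attr(params, "H")
  r <- cpp_kernel_states(params$Abar, matrix(params$Bbar, N, H),
                         matrix(params$C, N, H), L, keep_states)
  list(K = r$K, X = r$X)
}

# linear index (a plain vector, column-major over an N*H x N layout)
# mapping a flattened (N x H) state to its channel-replicated expansion
gather_index <- function(N, H) {
  base <- rep((seq_len(H) - 1L) * N, each = N)       # (h-1)*N per row
  rep(base, N) + rep(seq_len(N), each = N * H)
}

# structured generating-function path: evaluate the truncated kernel
# generating function at the L-th roots of unity through Cauchy dot products
# (Woodbury on the DPLR resolvent), then invert the DFT. The truncation
# correction (I - Abar^L) is folded into C.
kernel_cauchy <- function(params, L) {
  N <- attr(params, "N"); H <- attr(params, "H")
  K <- matrix(0, L, H)
  z <- exp(-2i * pi * (0:(L - 1)) / L)
  for (h in seq_len(H)) {
    A_bar <- matrix(params$Abar[, , h], N, N)
    # A_bar^L by repeated squaring
    AL <- diag(1 + 0i, N); Pw <- A_bar; e <- L
    while (e > 0) {
      if (e %% 2 == 1) AL <- AL %*% Pw
      Pw <- Pw %*% Pw
      e <- e %/% 2
    }
    Ct <- as.vector(t(diag(1 + 0i, N) - AL) %*% params$C[, h])
    lam <- params$Lambda[, h]; Pv <- params$P[, h]; Qv <- params$Q[, h]
    Bv <- params$B[, h]
    dlt <- params$dt[h] / 2
    vals <- complex(length.out = L)
    reg <- Mod(1 + z) > 1e-9
    if (any(reg)) {
      zr <- z[reg]
      g <- (1 - zr) / (dlt * (1 + zr))
      # Cauchy kernels: cd[n, j] = 1 / (g_j - lambda_n)
      cd <- 1 / outer(-lam, g, `+`)
      k00 <- colSums(Ct * cd * Bv)
      k01 <- colSums(Ct * cd * Pv)
      k10 <- colSums(Conj(Qv) * cd * Bv)
      k11 <- colSums(Conj(Qv) * cd * Pv)
      vals[reg] <- (2 / (1 + zr)) * (k00 - k01 * k10 / (1 + k11))
    }
    if (any(!reg)) {
      # z = -1: resolvent collapses to (2 I)^{-1} dt B
      vals[!reg] <- dlt * sum(Ct * Bv)
    }
    K[, h] <- Re(stats::fft(vals, inverse = TRUE)) / L
  }
  K
}

#' Convolution kernel of the discretized system
#'
#' Filter taps `K_k = C Abar^k B`, `k = 0..L-1`, one column per channel.
#'
#' @param params discretized `state_space_params` (see [discretize()])
#' @param L kernel length (sequence length)
#' @param method `"cauchy"` for the structured generating-function path,
#'   `"naive"` for materialized matrix powers (the in-repo oracle, intended
#'   for moderate N), `"recurrence"` for the state-stepping path used during
#'   training
#' @return real `L x H` matrix of filter taps
#' @export
compute_kernel <- function(params, L,
                           method = c("cauchy", "naive", "recurrence")) {
  if (L < 1) stop("kernel length L must be >= 1")
  if (is.null(params$Abar)) params <- discretize(params)
  method <- match.arg(method)
  switch(method,
         naive = kernel_naive(params, L),
         recurrence = kernel_recurrence(params, L)$K,
         cauchy = kernel_cauchy(params, L))
}

#' One step of the linear recurrence
#'
#' `x_k = Abar x_{k-1} + Bbar u_k`; `y_k = Re(C x_k) + D u_k`, applied to
#' all channels at once.
#'
#' @param params discretized `state_space_params`
#' @param x_prev complex `N x H` state (zero matrix at sequence start)
#' @param u numeric input, one value per channel (length H, or scalar when
#'   H = 1)
#' @return `list(x = new state, y = numeric outputs per channel)`
#' @export
recurrent_step <- function(params, x_prev, u) {
  N <- attr(params, "N"); H <- attr(params, "H")
  if (is.null(params$Abar)) stop("params must be discretized first")
  x_prev <- matrix(x_prev, N, H)
  if (length(u) != H) stop("dimension mismatch: input must have one value per channel")
  Amat <- matrix(aperm(params$Abar, c(1, 3, 2)), N * H, N)
  x <- matrix(rowSums(Amat * matrix(x_prev[gather_index(N, H)], N * H, N)),
              N, H) + params$Bbar * rep(u, each = N)
  y <- Re(colSums(params$C * x)) + params$D * u
  list(x = x, y = y)
}

#' Causal convolution of an input sequence with a kernel
#'
#' `y_k = sum_{j <= k} K_{k-j} u_j + D u_k`, computed with FFTs; strictly
#' causal (zero-padded linear convolution, no wrap-around).
#'
#' @param u numeric input: length-L vector or `L x H` matrix
#' @param kernel matching length-L vector or `L x H` matrix of filter taps
#' @param D skip (feed-through) coefficient per channel (default 0)
#' @return output of the same shape as `u`
#' @export
convolve_sequence <- function(u, kernel, D = 0) {
  uvec <- is.null(dim(u))
  u <- as.matrix(u); kernel <- as.matrix(kernel)
  if (!all(dim(u) == dim(kernel))) stop("length mismatch between input and kernel")
  L <- nrow(u)
  n2 <- stats::nextn(2L * L, 2)
  pad <- function(m) rbind(m, matrix(0, n2 - L, ncol(m)))
  Uf <- stats::mvfft(pad(u)); Kf <- stats::mvfft(pad(kernel))
  y <- Re(stats::mvfft(Uf * Kf, inverse = TRUE))[seq_len(L), , drop = FALSE] / n2
  y <- y + sweep(u, 2L, rep_len(D, ncol(u)), `*`)
  if (uvec) as.vector(y) else y
}
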