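rel_err <- function(a, b) max(abs(a - b)) / max(abs(b))

test_that("structured initialization has the expected spectral properties", {
  p1 <- init_state_space(4, 2, rng_seed = 3)
  p2 <- init_state_space(4, 2, rng_seed = 3)
  expect_identical(p1, p2)                       # seed determinism
  # decay: real parts of the diagonal are non-positive (computed
  # eigenstructure of the scaled Legendre operator's normal part)
  expect_true(all(Re(p1$Lambda) <= 0))
  # materialized continuous matrix reproduces the Legendre operator's
  # eigenvalues: strictly stable
  A <- materialize_A(p1, 1)
  expect_true(all(Re(eigen(A)$values) < 0))
  # discretized spectral radius stays within the unit disk
  for (N in c(4, 16, 64)) {
    p <- discretize(init_state_space(N, 1, rng_seed = N))
    ev <- eigen(matrix(p$Abar[, , 1], N, N))$values
    expect_lte(max(Mod(ev)), 1 + 1e-12)
  }
})

test_that("bilinear discretization matches closed forms", {
  scalar_params <- function(a, dt) {
    structure(list(Lambda = matrix(a + 0i, 1, 1), P = matrix(0i, 1, 1),
                   Q = matrix(0i, 1, 1), B = matrix(1 + 0i, 1, 1),
                   C = matrix(1 + 0i, 1, 1), log_dt = log(dt), D = 0),
              class = "state_space_params", N = 1L, H = 1L)
  }
  p <- discretize(scalar_params(0, 0.1))
  expect_equal(Re(p$Abar[1, 1, 1]), 1)
  expect_equal(Re(p$Bbar[1, 1]), 0.1)
  # pole mapped to the origin: a = -1, dt = 2
  p2 <- discretize(scalar_params(-1, 2))
  expect_equal(Mod(p2$Abar[1, 1, 1]), 0)
})

test_that("bilinear discretization converges to the matrix exponential", {
  # first-order agreement with the exact exponential map as dt -> 0,
  # checked against an independent scaling-and-squaring oracle
  expm_oracle <- function(M, n_sq = 30) {
    X <- M / 2^n_sq
    E <- diag(1 + 0i, nrow(M))
    term <- X
    for (k in 1:20) { E <- E + term; term <- term %*% X / (k + 1) }
    for (i in seq_len(n_sq)) E <- E %*% E
    E
  }
  set.seed(6)
  p <- init_state_space(6, 1, rng_seed = 6)
  A <- materialize_A(p, 1)
  errs <- vapply(c(1e-2, 1e-3), function(dt) {
    p$log_dt <- log(dt)
    pd <- discretize(p)
    exact <- expm_oracle(dt * A)
    max(abs(pd$Abar[, , 1] - exact))
  }, numeric(1))
  # second-order accurate: error drops ~100x for a 10x smaller step
  expect_lt(errs[2], errs[1] / 50)
  expect_lt(errs[1], 1e-3)
})

test_that("kernel paths agree and match closed forms", {
  # scalar geometric series
  ps <- structure(list(Lambda = matrix(0i, 1, 1), P = matrix(0i, 1, 1),
                       Q = matrix(0i, 1, 1), B = matrix(0i, 1, 1),
                       C = matrix(1 + 0i, 1, 1), log_dt = 0, D = 0,
                       Abar = array(0.5 + 0i, c(1, 1, 1)),
                       Bbar = matrix(1 + 0i, 1, 1), dt = 1),
                  class = "state_space_params", N = 1L, H = 1L)
  expect_equal(compute_kernel(ps, 3, method = "naive")[, 1], c(1, 0.5, 0.25))
  expect_equal(compute_kernel(ps, 3, method = "recurrence")[, 1],
               c(1, 0.5, 0.25))
  # K_0 = C B for any parameters
  p <- discretize(init_state_space(8, 3, rng_seed = 1))
  K <- compute_kernel(p, 16, method = "naive")
  expect_equal(K[1, ], Re(colSums(p$C * p$Bbar)))
  # structured Cauchy path vs brute-force matrix powers
  for (seed in 1:4) {
    p <- discretize(init_state_space(8, 2, rng_seed = seed))
    kn <- compute_kernel(p, 32, method = "naive")
    kc <- compute_kernel(p, 32, method = "cauchy")
    kr <- compute_kernel(p, 32, method = "recurrence")
    expect_lt(rel_err(kc, kn), 1e-6)
    expect_lt(rel_err(kr, kn), 1e-10)
  }
  expect_error(compute_kernel(p, 0), "L")
})

test_that("recurrent step reproduces the impulse response", {
  ps <- structure(list(Lambda = matrix(0i, 1, 1), P = matrix(0i, 1, 1),
                       Q = matrix(0i, 1, 1), B = matrix(0i, 1, 1),
                       C = matrix(1 + 0i, 1, 1), log_dt = 0, D = 0,
                       Abar = array(0.5 + 0i, c(1, 1, 1)),
                       Bbar = matrix(1 + 0i, 1, 1), dt = 1),
                  class = "state_space_params", N = 1L, H = 1L)
  x <- matrix(0i, 1, 1); y <- numeric(3)
  for (k in 1:3) {
    st <- recurrent_step(ps, x, u = c(1, 0, 0)[k])
    x <- st$x; y[k] <- st$y
  }
  expect_equal(y, c(1, 0.5, 0.25))
  # impulse response equals the kernel for any parameters (D = 0)
  p <- discretize(init_state_space(6, 2, rng_seed = 9))
  p$D <- c(0, 0)
  L <- 20
  x <- matrix(0i, 6, 2); Y <- matrix(0, L, 2)
  for (k in seq_len(L)) {
    st <- recurrent_step(p, x, u = if (k == 1) c(1, 1) else c(0, 0))
    x <- st$x; Y[k, ] <- st$y
  }
  expect_equal(Y, compute_kernel(p, L, method = "naive"), tolerance = 1e-12)
  # zero input, zero state stays zero
  st <- recurrent_step(p, matrix(0i, 6, 2), c(0, 0))
  expect_equal(st$y, c(0, 0))
  expect_equal(max(Mod(st$x)), 0)
  expect_error(recurrent_step(p, matrix(0i, 6, 2), c(0, 0, 0)),
               "dimension mismatch")
})

test_that("causal convolution matches its definition", {
  expect_equal(convolve_sequence(c(1, 0, 0), c(1, 0.5, 0.25)),
               c(1, 0.5, 0.25))
  u <- rnorm(8)
  expect_equal(convolve_sequence(u, c(1, rep(0, 7))), u)   # identity filter
  expect_error(convolve_sequence(1:4, 1:3), "length mismatch")
  # no future leakage: changing u_k never affects y_{<k}
  set.seed(2)
  K <- rnorm(16); u <- rnorm(16)
  y1 <- convolve_sequence(u, K, D = 0.3)
  u2 <- u; u2[10] <- u2[10] + 5
  y2 <- convolve_sequence(u2, K, D = 0.3)
  expect_equal(y1[1:9], y2[1:9])
  expect_false(isTRUE(all.equal(y1[10], y2[10])))
})

test_that("dual-mode equivalence holds across random parameter draws", {
  # the central structural property: full-sequence convolution equals the
  # unrolled linear recurrence with the same parameters
  set.seed(123)
  worst <- 0
  for (i in 1:25) {
    N <- sample(c(2, 4, 8, 16, 32, 64), 1)
    H <- sample(1:3, 1)
    L <- sample(c(16, 64, 128), 1)
    p <- discretize(init_state_space(N, H, rng_seed = i))
    K <- compute_kernel(p, L, method = "recurrence")
    u <- matrix(rnorm(L * H), L, H)
    y_conv <- convolve_sequence(u, K, p$D)
    x <- matrix(0i, N, H); y_rec <- matrix(0, L, H)
    for (k in seq_len(L)) {
      st <- recurrent_step(p, x, u[k, ])
      x <- st$x; y_rec[k, ] <- st$y
    }
    worst <- max(worst, rel_err(y_conv, y_rec))
  }
  expect_lt(worst, 1e-4)
})

test_that("trajectories stay bounded on bounded input", {
  for (N in c(8, 32)) {
    p <- discretize(init_state_space(N, 1, rng_seed = N + 1))
    L <- 10L * N
    set.seed(N)
    u <- matrix(runif(L, -1, 1), L, 1)
    K <- compute_kernel(p, L, method = "recurrence")
    y <- convolve_sequence(u, K, p$D)
    expect_true(all(is.finite(y)))
    expect_lt(max(abs(y)), 1e3)
  }
})
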