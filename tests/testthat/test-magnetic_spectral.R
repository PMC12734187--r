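test_that("symmetrization averages the two directions", {
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  S <- symmetrize(A)
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[2, 1], 0.5)
  A[2, 1] <- 1
  expect_equal(symmetrize(A)[1, 2], 1)
  expect_equal(symmetrize(matrix(0, 2, 2)), matrix(0, 2, 2))
})

test_that("the phase matrix is skew-symmetric with entries 2*pi*q", {
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  Th <- phase_matrix(A, 0.25)
  expect_equal(Th[1, 2], pi / 2)
  expect_equal(Th[2, 1], -pi / 2)
  A[2, 1] <- 1
  expect_equal(phase_matrix(A, 0.25)[1, 2], 0)  # reciprocal edge: zero phase
  expect_equal(phase_matrix(A, 0), matrix(0, 2, 2))
  expect_error(phase_matrix(A, -0.1), ">= 0")
})

test_that("the Hermitian adjacency combines magnitude and phase", {
  A <- matrix(0, 2, 2); A[1, 2] <- 1
  H <- hermitian_adjacency(symmetrize(A), phase_matrix(A, 0.25))
  expect_equal(H[1, 2], 0.5i)
  expect_equal(H[2, 1], -0.5i)
  expect_equal(hermitian_adjacency(symmetrize(A), phase_matrix(A, 0))[1, 2], 0.5 + 0i)
  A[2, 1] <- 1
  expect_equal(hermitian_adjacency(symmetrize(A), phase_matrix(A, 0.25))[1, 2], 1 + 0i)
  # direction sensitivity: a one-way edge carries phase exactly 2*pi*q
  for (q in c(0.05, 0.1, 0.25)) {
    A1 <- matrix(0, 2, 2); A1[1, 2] <- 1
    H1 <- hermitian_adjacency(symmetrize(A1), phase_matrix(A1, q))
    expect_equal(Arg(H1[1, 2]), 2 * pi * q)
  }
})

test_that("a single directed edge gives the known 2x2 Laplacian", {
  g <- gene_graph(data.frame(from = "A", to = "B"))
  op <- magnetic_laplacian(g, q = 0.25)
  expect_equal(op$L, matrix(c(1, 1i, -1i, 1), 2, 2), tolerance = 1e-12)
  ev <- eigen(op$L, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 2), tolerance = 1e-12)
  expect_equal(op$L_tilde, matrix(c(0, 1i, -1i, 0), 2, 2), tolerance = 1e-12)
})

test_that("q = 0 recovers the classical symmetric normalized Laplacian", {
  set.seed(21)
  for (rep in 1:3) {
    A <- random_adjacency(15, 0.2)
    op <- magnetic_laplacian(A, q = 0)
    S <- symmetrize(A)
    deg <- rowSums(S)
    dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
    L_classical <- diag(15) - outer(dinv, dinv) * S
    expect_lt(max(abs(op$L - L_classical)), 1e-12)
    expect_equal(max(abs(Im(op$L))), 0)
  }
})

test_that("eigenvalues stay within [0, 2] across q, and L is Hermitian", {
  set.seed(22)
  for (rep in 1:3) {
    A <- random_adjacency(25, 0.15)
    for (q in c(0, 0.05, 0.1, 0.25)) {
      op <- magnetic_laplacian(A, q)
      expect_equal(max(abs(op$H - Conj(t(op$H)))), 0)
      expect_lt(max(abs(op$L - Conj(t(op$L)))), 1e-12)
      ev <- eigen(op$L, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-9)
      expect_lte(max(ev), 2 + 1e-9)
    }
  }
  # 3-cycle worked case
  A3 <- matrix(0, 3, 3); A3[1, 2] <- A3[2, 3] <- A3[3, 1] <- 1
  op3 <- magnetic_laplacian(A3, 0.25)
  ev3 <- eigen(op3$L, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev3), -1e-9)
  expect_lte(max(ev3), 2 + 1e-9)
})

test_that("zero-degree nodes become identity rows", {
  g <- gene_graph(data.frame(from = "A", to = "B"), nodes = c("A", "B", "C"))
  op <- magnetic_laplacian(g, 0.25)
  expect_equal(op$L[3, ], c(0, 0, 1) + 0i)
  expect_equal(op$L_tilde[3, ], c(0, 0, 0) + 0i)
})

test_that("the shifted operator has spectral radius at most 1", {
  set.seed(23)
  A <- random_adjacency(20, 0.2)
  op <- magnetic_laplacian(A, 0.1)
  expect_equal(shift_operator(op$L), op$L_tilde, tolerance = 1e-14)
  expect_equal(shift_operator(diag(4) + 0i), matrix(0i, 4, 4))
  ev <- eigen(op$L_tilde, symmetric = TRUE, only.values = TRUE)$values
  expect_lte(max(abs(ev)), 1 + 1e-9)
})

test_that("Chebyshev recurrence matches the explicit spectral polynomial", {
  # K = 0 is a pure rescaling
  x <- matrix(rnorm(8), 8, 1)
  expect_equal(cheb_filter(matrix(0i, 8, 8), x, 3), 3 * (x + 0i))
  # worked K = 1 case on the 2-node operator
  g <- gene_graph(data.frame(from = "A", to = "B"))
  op <- magnetic_laplacian(g, 0.25)
  expect_equal(drop(cheb_filter(op$L_tilde, c(1, 0), c(1, 1))), c(1, 1i),
               tolerance = 1e-12)
  # random 8-node graphs, K up to 4, against the dense spectral oracle
  set.seed(24)
  for (K in 1:4) {
    A <- random_adjacency(8, 0.3)
    op <- magnetic_laplacian(A, 0.25)
    thetas <- rnorm(K + 1)
    x <- matrix(rnorm(8 * 3), 8, 3)
    y_rec <- cheb_filter(op$L_tilde, x, thetas)
    y_orc <- cheb_spectral_oracle(op$L_tilde, x, thetas)
    expect_lt(max(abs(y_rec - y_orc)), 1e-10)
  }
})

test_that("the sparse path agrees with the dense path", {
  set.seed(25)
  for (n in c(16, 64)) {
    A <- random_adjacency(n, 0.1)
    opd <- magnetic_laplacian(A, 0.25)
    ops <- magnetic_laplacian(A, 0.25, sparse = TRUE)
    expect_s3_class(ops$L_tilde, "sparse_complex")
    expect_true(sc_is_hermitian(ops$L))
    expect_lt(max(abs(as.matrix(ops$L_tilde) - opd$L_tilde)), 1e-14)
    thetas <- rnorm(3)
    x <- matrix(rnorm(n * 4), n, 4)
    expect_lt(max(abs(cheb_filter(ops$L_tilde, x, thetas) -
                        cheb_filter(opd$L_tilde, x, thetas))), 1e-10)
  }
})

test_that("operators round-trip through triplet serialization", {
  set.seed(26)
  A <- random_adjacency(12, 0.2)
  op <- magnetic_laplacian(A, 0.1)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_operator(op, f)
  sc <- read_operator(f)
  expect_lt(max(abs(as.matrix(sc) - op$L_tilde)), 1e-12)
})
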