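test_that("complex ReLU gates on the sign of the real part", {
  expect_equal(complex_relu(1 + 2i), 1 + 2i)
  expect_equal(complex_relu(-1 + 2i), 0 + 0i)
  expect_equal(complex_relu(0 + 3i), 0 + 3i)   # boundary Re = 0 kept
  z <- c(2 - 1i, -0.5 + 0i, 0 - 4i)
  expect_equal(complex_relu(z), c(2 - 1i, 0 + 0i, 0 - 4i))
})

test_that("unwind concatenates real and imaginary parts", {
  expect_equal(unwind(matrix(1 + 2i)), matrix(c(1, 2), 1, 2))
  Xr <- matrix(rnorm(6), 3, 2) + 0i
  expect_equal(unwind(Xr), cbind(Re(Xr), matrix(0, 3, 2)))
  expect_equal(ncol(unwind(matrix(0i, 5, 64))), 128)
})

test_that("the convolution layer reduces correctly in degenerate settings", {
  set.seed(31)
  X <- abs(matrix(rnorm(8), 4, 2)) + 0i
  W_id <- list(diag(2) + 0i, matrix(0i, 2, 2))
  # L_tilde = 0: neighbor term vanishes
  out <- conv_layer(X, matrix(0i, 4, 4), W_id)
  expect_equal(out, X)
  # identity pass-through for nonnegative real input
  Lt <- magnetic_laplacian(random_adjacency(4, 0.5), 0.25)$L_tilde
  expect_equal(conv_layer(X, Lt, W_id), X)
  # worked 2-node case: Wself = 0, Wneigh = I, X = I
  g <- gene_graph(data.frame(from = "A", to = "B"))
  op <- magnetic_laplacian(g, 0.25)
  out2 <- conv_layer(diag(2), op$L_tilde, list(matrix(0i, 2, 2), diag(2) + 0i))
  # L~ = [[0,-i],[i,0]]; entries have Re = 0 so the complex ReLU keeps them
  expect_equal(out2, matrix(c(0, 1i, -1i, 0), 2, 2))
})

test_that("channel attention pools, squeezes and bounds its map in (0,1)", {
  set.seed(32)
  X <- matrix(rnorm(40), 10, 4)
  X <- sweep(X, 2, colMeans(X))  # zero column means
  ca <- channel_attention(X, diag(4), rep(0, 4), diag(4), rep(0, 4))
  expect_equal(ca$Mc, rep(0.5, 4))  # sigmoid(0) with identity MLP
  expect_equal(ca$X_out, X * 0.5)
  W1 <- matrix(rnorm(8), 2, 4); W2 <- matrix(rnorm(8), 4, 2)
  ca2 <- channel_attention(matrix(rnorm(80, sd = 5), 20, 4), W1, rnorm(2),
                           W2, rnorm(4))
  expect_true(all(ca2$Mc > 0 & ca2$Mc < 1))
})

test_that("spatial attention is a width-7 convolution over nodes", {
  set.seed(33)
  X <- matrix(rnorm(24), 8, 3)
  sa <- spatial_attention(X, matrix(0, 2, 7), 0)
  expect_equal(sa$Ms, rep(0.5, 8))  # zero kernel -> sigmoid(0)
  expect_equal(dim(sa$X_out), dim(X))  # padding preserves shape
  sa1 <- spatial_attention(matrix(rnorm(3), 1, 3), matrix(rnorm(14), 2, 7), 1)
  expect_equal(length(sa1$Ms), 1)  # N = 1 works under zero padding
  expect_true(all(sa1$Ms > 0 & sa1$Ms < 1))
  # kernel centered on the avg channel only: score = bias + k * mean
  k <- matrix(0, 2, 7); k[1, 4] <- 2
  sa2 <- spatial_attention(X, k, 0.5)
  expect_equal(sa2$Ms, plogis(0.5 + 2 * rowMeans(X)))
})

test_that("forward produces probabilities with the expected degeneracies", {
  set.seed(34)
  ds <- toy_dataset(n = 30, f = 4)
  cfg <- run_config(num_filters = 8, seed = 2, attention_reduction = 4)
  params <- init_model_params(cfg, 4)
  op <- magnetic_laplacian(edge_adjacency <- {
    A <- matrix(0, 30, 30); A[edge_index(ds$graph)] <- 1; A
  }, cfg$q)
  fw <- mdignn_forward(params, ds$features$values, op$L_tilde, cfg)
  expect_length(fw$prob, 30)
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # zero head -> all probabilities exactly 0.5
  params0 <- params
  params0$head_w[] <- 0; params0$head_b <- 0
  fw0 <- mdignn_forward(params0, ds$features$values, op$L_tilde, cfg)
  expect_equal(fw0$prob, rep(0.5, 30))
  # eval mode is deterministic
  fw2 <- mdignn_forward(params, ds$features$values, op$L_tilde, cfg)
  expect_identical(fw$prob, fw2$prob)
})

test_that("disabling attention feeds the unwound features to the head", {
  set.seed(35)
  ds <- toy_dataset(n = 20, f = 3)
  cfg <- run_config(num_filters = 4, seed = 5, use_channel_attention = FALSE,
                    use_spatial_attention = FALSE, attention_reduction = 2)
  params <- init_model_params(cfg, 3)
  A <- matrix(0, 20, 20); A[edge_index(ds$graph)] <- 1
  op <- magnetic_laplacian(A, cfg$q)
  fw <- mdignn_forward(params, ds$features$values, op$L_tilde, cfg)
  manual <- plogis(as.vector(fw$cache$U %*% params$head_w) + params$head_b)
  expect_equal(fw$prob, manual, tolerance = 1e-12)
})

test_that("with q = 0 the complex pipeline equals a real GCN to 1e-8", {
  set.seed(36)
  for (K in c(1, 2)) {
    n <- 18; f <- 5
    A <- random_adjacency(n, 0.2)
    cfg <- run_config(num_filters = 6, cheb_order = K, gcn_mode = TRUE,
                      seed = 8, attention_reduction = 3)
    params <- init_model_params(cfg, f)   # imaginary parts are zero
    X <- matrix(rnorm(n * f), n, f)
    op <- magnetic_laplacian(A, 0)
    fw <- mdignn_forward(params, X, op$L_tilde, cfg)
    # complex path stays exactly real in GCN mode
    expect_equal(max(abs(Im(fw$cache$Xc))), 0)
    ref <- real_gcn_reference(params, X, Re(op$L_tilde), cfg)
    expect_lt(max(abs(fw$prob - ref)), 1e-8)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(37)
  n <- 7; f <- 4
  A <- random_adjacency(n, 0.3)
  op <- magnetic_laplacian(A, 0.25)
  cfg <- run_config(num_filters = 3, num_layers = 2, cheb_order = 2,
                    dropout = 0, edge_dropout = 0, seed = 3,
                    attention_reduction = 2)
  params <- init_model_params(cfg, f)
  X <- matrix(rnorm(n * f), n, f)
  y <- c(1, 0, 1, NA, 0, 1, 0)
  ids <- which(!is.na(y))
  lossfn <- function(p) {
    fw <- mdignn_forward(p, X, op$L_tilde, cfg)
    mdignn:::weighted_bce(fw$prob, y, ids, 2)
  }
  fw <- mdignn_forward(params, X, op$L_tilde, cfg)
  gl <- mdignn:::bce_grad_logits(fw$prob, y, ids, 2, n)
  gr <- mdignn:::mdignn_backward(params, fw$cache, gl, cfg, op$L_tilde)
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-5,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("attention maps stay strictly inside (0, 1) through the forward pass", {
  set.seed(38)
  ds <- toy_dataset(n = 25, f = 4, shift = 2)
  cfg <- run_config(num_filters = 8, seed = 4, attention_reduction = 4)
  params <- init_model_params(cfg, 4)
  A <- matrix(0, 25, 25); A[edge_index(ds$graph)] <- 1
  op <- magnetic_laplacian(A, cfg$q)
  fw <- mdignn_forward(params, ds$features$values, op$L_tilde, cfg)
  expect_true(all(fw$cache$ca$Mc > 0 & fw$cache$ca$Mc < 1))
  expect_true(all(fw$cache$sa$Ms > 0 & fw$cache$sa$Ms < 1))
})

test_that("channel attention is invariant to node permutation; spatial is not", {
  set.seed(39)
  X <- matrix(rnorm(60), 12, 5)
  W1 <- matrix(rnorm(10), 2, 5); W2 <- matrix(rnorm(10), 5, 2)
  perm <- sample(12)
  b1 <- rnorm(2); b2 <- rnorm(5)
  ca1 <- channel_attention(X, W1, b1, W2, b2)
  ca2 <- channel_attention(X[perm, ], W1, b1, W2, b2)
  expect_equal(ca2$Mc, ca1$Mc)                      # same channel map
  expect_equal(ca2$X_out[order(perm), ], ca1$X_out) # rows permute back
})
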